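# Independent oracles used across the suite. These deliberately take the
# slow, literal route (loops, direct enumeration) so they share no code
# path with the package internals they check.

# --- dense 3D convolution with a truncated Gaussian kernel, reflective
#     boundaries, computed voxel by voxel ---
oracle_blur_3d <- function(x, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  refl <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  d <- dim(x)
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (xx in seq_len(d[3])) {
    acc <- 0
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      acc <- acc + k1[dz + r + 1] * k1[dy + r + 1] * k1[dx + r + 1] *
        x[refl(z + dz, d[1]), refl(y + dy, d[2]), refl(xx + dx, d[3])]
    }
    out[z, y, xx] <- acc
  }
  out
}

# --- queue-based flood fill labeling; returns per-voxel component sizes ---
oracle_component_sizes <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  sizes <- integer(0)
  if (connectivity == 26L) {
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- off[rowSums(abs(off)) > 0, ]
  } else {
    off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  }
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    n_here <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      n_here <- n_here + 1L
      co <- arrayInd(v, d)
      for (i in seq_len(nrow(off))) {
        p <- co + off[i, ]
        if (any(p < 1L) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- cur
          queue <- c(queue, p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2])
        }
      }
    }
    sizes <- c(sizes, n_here)
  }
  list(labels = lab, sizes = sizes)
}

# --- exhaustive scan of the minimum cross-entropy objective, straight from
#     the pixel values ---
oracle_li_scan <- function(plane) {
  v <- as.numeric(plane)
  cuts <- sort(unique(v))
  best <- Inf; best_cut <- NA_real_
  for (t in cuts[-1]) {
    lo <- v[v < t]; hi <- v[v >= t]
    obj <- 0
    if (sum(lo) > 0) obj <- obj - sum(lo) * log(mean(lo))
    if (sum(hi) > 0) obj <- obj - sum(hi) * log(mean(hi))
    if (obj < best) { best <- obj; best_cut <- t }
  }
  best_cut
}

# --- explicit geometric construction for the triangle threshold: build the
#     256-bin histogram, mirror if the long tail is on the left, and scan
#     true perpendicular point-to-line distances ---
oracle_triangle_geom <- function(plane, n_bins = 256L) {
  v <- as.numeric(plane)
  rng <- range(v)
  w <- diff(rng) / n_bins
  h <- integer(n_bins)
  for (x in v) {
    b <- min(floor((x - rng[1]) / w) + 1, n_bins)
    h[b] <- h[b] + 1L
  }
  peak <- which.max(h)
  lo <- min(which(h > 0)); hi <- max(which(h > 0))
  flipped <- (peak - lo) > (hi - peak)
  if (flipped) {
    h <- rev(h)
    tmp <- n_bins + 1L - peak
    hi <- n_bins + 1L - lo
    peak <- tmp
  }
  if (hi - peak < 2L) {
    star <- hi
  } else {
    # distance from (i, h[i]) to the line through (peak, h[peak]), (hi, h[hi])
    len <- sqrt((hi - peak)^2 + (h[hi] - h[peak])^2)
    best <- -Inf; star <- NA_integer_
    for (i in (peak + 1L):(hi - 1L)) {
      dist <- abs((h[hi] - h[peak]) * i - (hi - peak) * h[i] +
                    hi * h[peak] - h[hi] * peak) / len
      if (dist > best + 1e-12) { best <- dist; star <- i }
    }
  }
  if (flipped) star <- n_bins + 1L - star
  rng[1] + (star - 0.5) * w
}

# --- local-maximum dot detection on a noise-free composite (matched-filter
#     stand-in): a voxel is a detected center if it is strictly greater than
#     all 26 neighbours (missing neighbours beyond the border count as -Inf)
#     and clearly above background ---
oracle_count_dot_maxima <- function(volume, background) {
  d <- dim(volume)
  shift <- function(a, s) {
    out <- array(-Inf, d)
    src <- lapply(1:3, function(i) max(1, 1 - s[i]):min(d[i], d[i] - s[i]))
    dst <- lapply(1:3, function(i) src[[i]] + s[i])
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  is_max <- volume > background + 1
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    is_max <- is_max & (volume > shift(volume, c(dz, dy, dx)))
  }
  sum(is_max)
}

# --- small deterministic 8-bit test planes with varied histogram shapes ---
fixture_plane_8bit <- function(seed) {
  set.seed(seed)
  kind <- seed %% 4
  n <- 48L
  if (kind == 0) {
    # background spike + bright blob
    p <- matrix(pmin(pmax(round(rnorm(n * n, 30, 6)), 0), 255), n, n)
    p[15:30, 10:25] <- pmin(pmax(round(rnorm(16 * 16, 180, 12)), 0), 255)
  } else if (kind == 1) {
    # geometric-tail histogram
    p <- matrix(pmin(round(rexp(n * n, rate = 0.08)), 255), n, n)
  } else if (kind == 2) {
    # two Gaussian modes, unequal weights
    n1 <- round(n * n * 0.85)
    z <- c(rnorm(n1, 40, 8), rnorm(n * n - n1, 160, 20))
    p <- matrix(pmin(pmax(round(z), 0), 255), n, n)
  } else {
    # uniform plus saturated speckles
    p <- matrix(round(runif(n * n, 10, 120)), n, n)
    p[sample.int(n * n, 60)] <- 255L
  }
  storage.mode(p) <- "integer"
  p
}

# --- compact scene specs reused across tests; any field can be overridden ---
tiny_spec <- function(..., seed = 1L) {
  args <- list(shape = c(9L, 40L, 40L), n_nuclei = 1L,
               nucleus_radii = c(5, 9, 9), n_pla_dots = 5L, n_organelles = 4L,
               organelle_radius = 3, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

power_spec <- function(n_dots, seed) {
  scene_spec(shape = c(11L, 64L, 64L), n_nuclei = 1L, nucleus_radii = c(6, 12, 12),
             n_pla_dots = n_dots, n_organelles = 0L,
             fraction_dots_in_organelle = 0, seed = seed)
}
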