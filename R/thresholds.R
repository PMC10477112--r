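#' Intensity band defining foreground
#'
#' Auto-threshold methods yield a single lower cut; because the signal of
#' interest (DAPI nuclei, PLA dots, GFP organelles) is bright on a dark
#' background, the upper bound is the top of the representable range and is
#' non-binding. A voxel is foreground iff `lower <= v <= upper`, inclusive
#' on both ends.
#'
#' @param lower,upper intensity bounds, `0 <= lower <= upper`.
#' @param method `"li"` or `"triangle"`.
#' @param source_plane 1-based z index of the plane the band was computed on.
#' @return An object of class `threshold_band`.
#' @export
threshold_band <- function(lower, upper, method = c("li", "triangle"),
                           source_plane = NA_integer_) {
  method <- match.arg(method)
  if (!is.finite(lower) || !is.finite(upper) || lower < 0 || lower > upper)
    stop("need 0 <= lower <= upper")
  structure(list(lower = lower, upper = upper, method = method,
                 source_plane = as.integer(source_plane)),
            class = "threshold_band")
}

#' @export
print.threshold_band <- function(x, ...) {
  cat(sprintf("<threshold_band %s> [%g, %g], computed on plane %s\n",
              x$method, x$lower, x$upper,
              ifelse(is.na(x$source_plane), "?", x$source_plane)))
  invisible(x)
}

#' Best-focus plane of a stack
#'
#' The z index (1-based) whose plane has the highest mean intensity; ties go
#' to the smallest z. Computed on the blurred working copy in the pipelines.
#'
#' @param x a [volume_channel()] or 3D array (z, y, x).
#' @return Integer z index.
#' @export
best_focus_index <- function(x) {
  vol <- if (inherits(x, "volume_channel")) x$voxels else x
  if (!is.array(vol) || length(dim(vol)) != 3L || dim(vol)[1] < 1L)
    stop("'x' must be a 3D array with at least one plane")
  means <- rowMeans(matrix(vol, dim(vol)[1], prod(dim(vol)[-1])))
  which.max(means)  # which.max returns the first (smallest z) maximum
}

# A plane whose spread is at the level of floating-point noise (e.g. the
# blur of a perfectly flat channel) has no threshold.
.check_not_constant <- function(vals) {
  rng <- range(vals)
  if (diff(rng) <= 1e-9 * max(1, abs(rng[2])))
    stop("degenerate input: constant plane has no threshold")
  invisible(NULL)
}

# value/count summary used by li_threshold: exact levels for discrete data,
# 256 bin centers for continuous data.
.intensity_levels <- function(vals, max_levels = 4096L, n_bins = 256L) {
  u <- sort(unique(vals))
  if (length(u) <= max_levels) {
    list(levels = u, counts = tabulate(match(vals, u), length(u)))
  } else {
    rng <- range(vals)
    w <- diff(rng) / n_bins
    idx <- pmin(floor((vals - rng[1]) / w) + 1, n_bins)
    list(levels = rng[1] + (seq_len(n_bins) - 0.5) * w,
         counts = tabulate(idx, n_bins))
  }
}

#' Li minimum cross-entropy threshold
#'
#' Selects the lower cut minimizing the cross-entropy between the image and
#' its two-class mean reconstruction: with below-class mass `M1`, count `N1`
#' and mean `mu1 = M1/N1` (and likewise `M2`, `N2`, `mu2` above), the
#' objective `-(M1*log(mu1) + M2*log(mu2))` is minimized over every candidate
#' cut; a class whose intensity mass is zero contributes nothing. Candidates
#' are all distinct intensity levels (binned to 256 levels when the plane is
#' continuous-valued); the below class is `v < lower`, the foreground class
#' `v >= lower`. Ties go to the smallest cut.
#'
#' @param plane 2D numeric matrix (typically the best-focus plane of a
#'   blurred stack); must contain at least two distinct non-negative values.
#' @param max_intensity upper end of the representable range, used as the
#'   band's (non-binding) upper bound; defaults to the plane maximum.
#' @param source_plane recorded in the returned band.
#' @return A [threshold_band()] with `method = "li"`.
#' @export
li_threshold <- function(plane, max_intensity = NULL, source_plane = NA_integer_) {
  vals <- as.numeric(plane)
  if (anyNA(vals) || any(vals < 0)) stop("plane must be non-negative and complete")
  .check_not_constant(vals)
  lv <- .intensity_levels(vals)
  m <- length(lv$levels)
  if (m < 2L)
    stop("degenerate input: constant plane has no threshold")
  cnt <- lv$counts
  mass <- cnt * lv$levels
  N1 <- cumsum(cnt)[-m]
  M1 <- cumsum(mass)[-m]
  N <- sum(cnt); M <- sum(mass)
  term <- function(mm, nn) ifelse(mm > 0, -mm * log(mm / nn), 0)
  obj <- term(M1, N1) + term(M - M1, N - N1)
  j <- which.min(obj)  # first minimum: smallest cut
  threshold_band(lower = lv$levels[j + 1L],
                 upper = if (is.null(max_intensity)) max(vals) else max_intensity,
                 method = "li", source_plane = source_plane)
}

#' Triangle threshold
#'
#' A 256-bin histogram is built over the observed min-max range. A line is
#' drawn from the histogram peak to the farthest non-empty tail bin (the
#' longer tail side; the histogram is mirrored first when that tail lies
#' below the peak, so the rule is symmetric under intensity flips). The
#' threshold is the bin strictly between peak and tail whose point
#' `(bin, count)` has maximal perpendicular distance from that line, ties
#' going to the bin nearest the peak; the returned lower bound is that bin's
#' center intensity.
#'
#' @inheritParams li_threshold
#' @param n_bins histogram bin count (256).
#' @return A [threshold_band()] with `method = "triangle"`.
#' @export
triangle_threshold <- function(plane, max_intensity = NULL,
                               source_plane = NA_integer_, n_bins = 256L) {
  vals <- as.numeric(plane)
  if (anyNA(vals) || any(vals < 0)) stop("plane must be non-negative and complete")
  .check_not_constant(vals)
  rng <- range(vals)
  w <- diff(rng) / n_bins
  idx <- pmin(floor((vals - rng[1]) / w) + 1, n_bins)
  h <- tabulate(idx, n_bins)
  peak <- which.max(h)
  lo <- which(h > 0)[1]
  hi <- max(which(h > 0))
  flipped <- (peak - lo) > (hi - peak)  # long tail on the left: mirror
  if (flipped) {
    h <- rev(h)
    peak <- n_bins + 1L - peak
    hi <- n_bins + 1L - lo
  }
  if (hi - peak < 2L) {
    star <- hi  # no interior bin between peak and tail
  } else {
    i <- (peak + 1L):(hi - 1L)
    d <- abs((i - peak) * (h[hi] - h[peak]) - (hi - peak) * (h[i] - h[peak]))
    star <- i[which.max(d)]  # first maximum: nearest the peak
  }
  if (flipped) star <- n_bins + 1L - star
  threshold_band(lower = rng[1] + (star - 0.5) * w,
                 upper = if (is.null(max_intensity)) rng[2] else max_intensity,
                 method = "triangle", source_plane = source_plane)
}
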