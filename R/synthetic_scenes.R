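#' Specify a synthetic two-channel acquisition
#'
#' Parameters of one simulated confocal z-stack: DAPI-like nuclear blobs
#' (filled ellipsoids, mutually non-overlapping), diffraction-limited PLA
#' dots (3D Gaussian spots truncated at 3 sigma), and a vesicular organelle
#' field (filled spheres, free to overlap), composited over a uniform
#' background and degraded with Poisson-plus-Gaussian noise. Defaults
#' emulate the acquisition regime the quantification targets: 21 planes at
#' 0.5 um z spacing, ~0.2 um lateral sampling (so a ~12 um nucleus has
#' semi-axes of roughly 12 planes by 30 pixels and is cropped by the
#' stack, as adherent-culture nuclei are in practice), sparse bright
#' diffraction-limited dots on a dark background,
#' ~0.5 um vesicles, 8-bit range, and a raw dot signal-to-noise ratio of
#' about 12 (see [scene_snr()]).
#'
#' @param shape (z, y, x) voxel counts.
#' @param n_nuclei,nucleus_radii nucleus count and ellipsoid semi-axes
#'   (z, y, x) in voxels.
#' @param n_pla_dots,dot_sigma dot count and Gaussian spot sigma in voxels
#'   (1.5: diffraction-limited).
#' @param n_organelles,organelle_radius vesicle count and radius in voxels.
#' @param background,nucleus_level,dot_peak,organelle_level intensity levels
#'   on the bit-depth scale (`nucleus_level`/`organelle_level`/`dot_peak`
#'   are amplitudes added to the background).
#' @param poisson_scale photons per intensity unit for shot noise (0 = off).
#' @param gaussian_sd additive read-noise SD in intensity units (0 = off).
#' @param fraction_dots_in_organelle proportion of dot centers placed
#'   uniformly on organelle foreground voxels; the rest are uniform over the
#'   volume.
#' @param bit_depth 8 or 16.
#' @param z_spacing microns between planes.
#' @param xy_spacing lateral pixel size in microns (metadata only, never
#'   enters any result).
#' @param seed integer seed; a scene is bit-reproducible given its spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(21L, 256L, 256L), n_nuclei = 3L,
                       nucleus_radii = c(12, 30, 30), n_pla_dots = 150L,
                       dot_sigma = 1.5, n_organelles = 60L,
                       organelle_radius = 4, background = 20,
                       nucleus_level = 170, dot_peak = 200,
                       organelle_level = 160, poisson_scale = 1,
                       gaussian_sd = 8, fraction_dots_in_organelle = 0.3,
                       bit_depth = 8L, z_spacing = 0.5, xy_spacing = 0.2,
                       seed = 1L) {
  spec <- list(shape = as.integer(shape), n_nuclei = as.integer(n_nuclei),
               nucleus_radii = nucleus_radii, n_pla_dots = as.integer(n_pla_dots),
               dot_sigma = dot_sigma, n_organelles = as.integer(n_organelles),
               organelle_radius = organelle_radius, background = background,
               nucleus_level = nucleus_level, dot_peak = dot_peak,
               organelle_level = organelle_level, poisson_scale = poisson_scale,
               gaussian_sd = gaussian_sd,
               fraction_dots_in_organelle = fraction_dots_in_organelle,
               bit_depth = as.integer(bit_depth), z_spacing = z_spacing,
               xy_spacing = xy_spacing,
               seed = as.integer(seed))
  if (length(spec$shape) != 3L || any(spec$shape < 1L))
    stop("'shape' must be three positive voxel counts (z, y, x)")
  if (any(c(spec$n_nuclei, spec$n_pla_dots, spec$n_organelles) < 0L))
    stop("object counts must be >= 0")
  if (spec$fraction_dots_in_organelle < 0 || spec$fraction_dots_in_organelle > 1)
    stop("'fraction_dots_in_organelle' must be in [0, 1]")
  if (!spec$bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  mx <- 2^spec$bit_depth - 1
  lv <- c(spec$background, spec$background + spec$nucleus_level,
          spec$background + spec$dot_peak, spec$background + spec$organelle_level)
  if (any(lv < 0) || any(lv > mx))
    stop(sprintf("intensity levels must stay within [0, %d]", mx))
  if (spec$dot_sigma <= 0) stop("'dot_sigma' must be positive")
  if (spec$poisson_scale < 0 || spec$gaussian_sd < 0)
    stop("noise parameters must be >= 0")
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %s voxels, %d nuclei, %d dots (sigma %g), %d organelles, seed %d\n",
              paste(x$shape, collapse = "x"), x$n_nuclei, x$n_pla_dots,
              x$dot_sigma, x$n_organelles, x$seed))
  invisible(x)
}

#' Approximate raw signal-to-noise ratio of a scene's PLA dots
#'
#' Dot peak amplitude over the noise SD at a dot peak (additive Gaussian
#' plus Poisson shot noise at the peak intensity). Defaults give ~12.
#'
#' @param spec a [scene_spec()].
#' @return A single number (Inf for noise-free specs).
#' @export
scene_snr <- function(spec) {
  v <- spec$gaussian_sd^2 +
    if (spec$poisson_scale > 0)
      (spec$background + spec$dot_peak) / spec$poisson_scale else 0
  if (v == 0) Inf else spec$dot_peak / sqrt(v)
}

#' Generate one synthetic scene with exact ground truth
#'
#' Deterministic for a fixed spec: one generator is seeded per scene and
#' draws are consumed in a fixed, documented order (nucleus centers,
#' organelle centers, in-organelle dot centers, free dot centers, then
#' noise for the nucleus, PLA and organelle channels in that order), so
#' determinism survives refactoring of unrelated stages. Nuclei are placed
#' with bounded retries and may not overlap each other; dots and organelles
#' may overlap anything. Dots are additive Gaussian spots truncated at
#' 3 sigma; noise is applied after compositing and intensities are rounded
#' and clipped to the bit depth.
#'
#' Ground-truth labels are exact voxel sets: the nucleus and organelle
#' labels are the rendered ellipsoids/spheres, and the PLA label is each
#' dot's rendered support -- the voxels inside the truncation ball where
#' the noise-free dot contribution is at least 0.5 intensity units, i.e.
#' exactly the voxels the generator painted above background.
#'
#' @param spec a [scene_spec()].
#' @return An object of class `synthetic_scene`: `nucleus`, `pla` and
#'   (when `n_organelles > 0`) `organelle` [volume_channel()]s, plus
#'   `truth` (label volumes, exact areas, overlap, dot centers) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(spec$seed)
  d <- spec$shape

  nucleus_centers <- .place_nuclei(spec)
  nucleus_label <- array(FALSE, d)
  for (i in seq_len(nrow(nucleus_centers)))
    nucleus_label <- .paint_ellipsoid(nucleus_label, nucleus_centers[i, ],
                                      spec$nucleus_radii)

  organelle_label <- array(FALSE, d)
  if (spec$n_organelles > 0L) {
    r <- spec$organelle_radius
    if (any(d < 2 * r + 1))
      stop("generation error: organelle radius exceeds the volume")
    for (i in seq_len(spec$n_organelles)) {
      ctr <- vapply(1:3, function(a) stats::runif(1, 1 + r, d[a] - r), numeric(1))
      organelle_label <- .paint_ellipsoid(organelle_label, ctr, rep(r, 3))
    }
  }

  dots <- .place_dots(spec, organelle_label)
  pla_sig <- array(0, d)
  pla_label <- array(FALSE, d)
  if (nrow(dots) > 0) {
    for (i in seq_len(nrow(dots))) {
      painted <- .paint_dot(pla_sig, pla_label, dots[i, ], spec$dot_sigma,
                            spec$dot_peak)
      pla_sig <- painted$signal; pla_label <- painted$label
    }
  }

  mk <- function(clean, name) {
    volume_channel(.apply_noise(clean, spec), channel_name = name,
                   bit_depth = spec$bit_depth, z_spacing = spec$z_spacing,
                   xy_spacing = spec$xy_spacing)
  }
  nucleus <- mk(spec$background + spec$nucleus_level * nucleus_label, "nucleus")
  pla <- mk(spec$background + pla_sig, "pla")
  organelle <- if (spec$n_organelles > 0L)
    mk(spec$background + spec$organelle_level * organelle_label, "organelle")
  else NULL

  truth <- list(nucleus_label = nucleus_label, pla_label = pla_label,
                organelle_label = organelle_label,
                true_nucleus_area = sum(nucleus_label),
                true_pla_area = sum(pla_label),
                true_organelle_area = sum(organelle_label),
                true_overlap_area = sum(pla_label & organelle_label),
                dot_centers = dots)
  structure(list(nucleus = nucleus, pla = pla, organelle = organelle,
                 truth = truth, spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s voxels (seed %d)\n",
              paste(x$spec$shape, collapse = "x"), x$spec$seed))
  cat(sprintf("  truth: nucleus %d vox, pla %d vox, organelle %d vox, overlap %d vox\n",
              x$truth$true_nucleus_area, x$truth$true_pla_area,
              x$truth$true_organelle_area, x$truth$true_overlap_area))
  invisible(x)
}

.place_nuclei <- function(spec, max_tries = 200L) {
  d <- spec$shape; r <- spec$nucleus_radii
  centers <- matrix(numeric(0), 0, 3)
  if (spec$n_nuclei == 0L) return(centers)
  for (i in seq_len(spec$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      # centers keep the nucleus inside the field; along an axis the object
      # spans entirely (e.g. a 12-plane semi-axis in a 21-plane stack) the
      # center sits mid-axis and the ellipsoid is cropped, as a real
      # adherent-culture nucleus is by the acquisition volume
      ctr <- vapply(1:3, function(a) {
        lo <- 1 + r[a]; hi <- d[a] - r[a]
        if (lo > hi) (1 + d[a]) / 2 else stats::runif(1, lo, hi)
      }, numeric(1))
      if (nrow(centers) == 0L ||
          all(rowSums(sweep(centers, 2, ctr)^2 %*% diag(1 / r^2)) >= 4)) {
        centers <- rbind(centers, ctr)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("generation error: could not place nucleus %d without overlap after %d tries",
                   i, max_tries))
  }
  unname(centers)
}

.place_dots <- function(spec, organelle_label) {
  n <- spec$n_pla_dots; d <- spec$shape
  if (n == 0L) return(matrix(integer(0), 0, 3))
  k_in <- round(spec$fraction_dots_in_organelle * n)
  centers <- matrix(0L, 0, 3)
  if (k_in > 0L) {
    fg <- which(organelle_label)
    if (length(fg) == 0L)
      stop("generation error: dots requested inside organelles but the organelle field is empty")
    picks <- fg[sample.int(length(fg), k_in, replace = TRUE)]
    centers <- rbind(centers, arrayInd(picks, d))
  }
  k_free <- n - k_in
  if (k_free > 0L)
    centers <- rbind(centers,
                     cbind(sample.int(d[1], k_free, replace = TRUE),
                           sample.int(d[2], k_free, replace = TRUE),
                           sample.int(d[3], k_free, replace = TRUE)))
  unname(centers)
}

# Fill an ellipsoid (center in continuous voxel coordinates, semi-axes in
# voxels) into a logical volume.
.paint_ellipsoid <- function(mask, center, radii) {
  d <- dim(mask)
  rng <- lapply(1:3, function(a) {
    max(1L, ceiling(center[a] - radii[a])):min(d[a], floor(center[a] + radii[a]))
  })
  q <- lapply(1:3, function(a) ((rng[[a]] - center[a]) / radii[a])^2)
  inside <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
  mask[rng[[1]], rng[[2]], rng[[3]]] <-
    mask[rng[[1]], rng[[2]], rng[[3]]] | inside
  mask
}

# Add one truncated Gaussian spot; the label gets its rendered support
# (contribution >= 0.5 inside the 3-sigma ball).
.paint_dot <- function(signal, label, center, sigma, peak) {
  d <- dim(signal)
  R <- ceiling(3 * sigma)
  rng <- lapply(1:3, function(a) {
    max(1L, center[a] - R):min(d[a], center[a] + R)
  })
  q <- lapply(1:3, function(a) (rng[[a]] - center[a])^2)
  r2 <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+")
  g <- peak * exp(-r2 / (2 * sigma^2))
  g[r2 > (3 * sigma)^2] <- 0
  signal[rng[[1]], rng[[2]], rng[[3]]] <-
    signal[rng[[1]], rng[[2]], rng[[3]]] + g
  label[rng[[1]], rng[[2]], rng[[3]]] <-
    label[rng[[1]], rng[[2]], rng[[3]]] | (g >= 0.5)
  list(signal = signal, label = label)
}

# Poisson shot noise, additive Gaussian read noise, then rounding and
# clipping to the bit depth.
.apply_noise <- function(clean, spec) {
  v <- as.numeric(clean)
  if (spec$poisson_scale > 0)
    v <- stats::rpois(length(v), v * spec$poisson_scale) / spec$poisson_scale
  if (spec$gaussian_sd > 0)
    v <- v + stats::rnorm(length(v), 0, spec$gaussian_sd)
  v <- pmin(pmax(round(v), 0), 2^spec$bit_depth - 1)
  array(v, dim(clean))
}

#' Extract a {primary, PLA} pair from a synthetic scene
#'
#' @param scene a `synthetic_scene`.
#' @param primary `"nucleus"` or `"organelle"`.
#' @param image_id,group_label,organelle_kind metadata for the pair.
#' @return A [stack_pair()].
#' @export
as_stack_pair <- function(scene, primary = c("nucleus", "organelle"),
                          image_id = "scene", group_label = NA_character_,
                          organelle_kind = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  primary <- match.arg(primary)
  ch <- scene[[primary]]
  if (is.null(ch))
    stop(sprintf("scene has no %s channel (n_organelles = 0?)", primary))
  stack_pair(ch, scene$pla, image_id = image_id, group_label = group_label,
             organelle_kind = organelle_kind)
}

#' Generate, write and describe a two-group synthetic experiment
#'
#' Writes paired-channel TIFF stacks plus a manifest for a two-group
#' comparison, with distinct per-image seeds derived reproducibly from
#' `base_seed` (same base seed, same files).
#'
#' @param spec_low,spec_high [scene_spec()]s for the two groups (their own
#'   seeds are ignored; per-image seeds are derived from `base_seed`).
#' @param n_images_per_group images per group, >= 2.
#' @param base_seed master seed.
#' @param dir output directory (created if needed).
#' @param group_labels length-2 labels, low then high.
#' @param primary primary channel written next to the PLA channel.
#' @param organelle_kind optional organelle label recorded in the manifest.
#' @return Invisibly, a list with the manifest data frame, its path and the
#'   output directory.
#' @export
generate_group_experiment <- function(spec_low, spec_high,
                                      n_images_per_group = 5L, base_seed = 1L,
                                      dir = tempfile("plaq_experiment_"),
                                      group_labels = c("low", "high"),
                                      primary = c("nucleus", "organelle"),
                                      organelle_kind = NULL) {
  stopifnot(inherits(spec_low, "scene_spec"), inherits(spec_high, "scene_spec"))
  primary <- match.arg(primary)
  if (n_images_per_group < 2L) stop("need at least 2 images per group")
  if (length(group_labels) != 2L) stop("'group_labels' must have length 2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  img <- 0L
  for (g in 1:2) {
    spec_g <- if (g == 1L) spec_low else spec_high
    for (i in seq_len(n_images_per_group)) {
      img <- img + 1L
      spec_i <- spec_g
      spec_i$seed <- .derive_seed(base_seed, img)
      scene <- generate_scene(spec_i)
      id <- sprintf("img%03d_%s", img, group_labels[g])
      f_prim <- sprintf("%s_%s.tif", id, primary)
      f_pla <- sprintf("%s_pla.tif", id)
      write_tiff_volume(scene[[primary]], file.path(dir, f_prim))
      write_tiff_volume(scene$pla, file.path(dir, f_pla))
      rows[[img]] <- data.frame(
        image_id = id, group_label = group_labels[g], layout = "paired",
        file_primary = f_prim, file_pla = f_pla, primary_channel = primary,
        organelle_kind = if (is.null(organelle_kind)) "" else organelle_kind,
        replicate_id = i, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, manifest_path = manifest_path, dir = dir))
}

# Per-image seed derivation; keeps results in 32-bit integer range.
.derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) %% 1000003) * 1000 + i)
}
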