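#' Quantify one {nucleus, PLA} image: PLA-area / nucleus-area ratio
#'
#' The per-image colocalization score. Each channel is processed
#' independently: 3D Gaussian blur (sigma 3 for the nucleus, 1 for the PLA
#' channel), best-focus plane selection by maximal plane mean, an
#' auto-threshold computed on that single plane (Li minimum cross-entropy
#' for the nucleus, Triangle for the PLA channel), application of the band
#' to the full 3D stack, and a connected-component size filter. The score is
#' the ratio of PLA foreground voxels to nucleus foreground voxels; "area"
#' in a 3D stack is read as the total foreground voxel count summed over z,
#' the only unit-consistent interpretation of an area ratio taken after 3D
#' thresholding (units cancel in the ratio). A switch restricts the nucleus
#' denominator to the best-focus plane only.
#'
#' @param pair a [stack_pair()] whose primary channel is the nucleus.
#' @param sigma_nucleus,sigma_pla blur sigmas in voxels (defaults 3 and 1).
#' @param min_size_nucleus,min_size_pla minimum component sizes in voxels
#'   (defaults 500 and 4; both recorded in the result).
#' @param connectivity component connectivity, 26 or 6.
#' @param nucleus_area_mode `"volume"` (default: all planes) or `"plane"`
#'   (best-focus plane only) for the denominator.
#' @return An object of class `pla_image_result` with areas (voxel counts),
#'   the ratio, best-focus indices, both threshold bands and the parameters
#'   used.
#' @export
quantify_pla_image <- function(pair, sigma_nucleus = 3, sigma_pla = 1,
                               min_size_nucleus = 500L, min_size_pla = 4L,
                               connectivity = 26L,
                               nucleus_area_mode = c("volume", "plane")) {
  stopifnot(inherits(pair, "stack_pair"))
  nucleus_area_mode <- match.arg(nucleus_area_mode)
  if (pair$primary$channel_name != "nucleus")
    stop(sprintf("image '%s': primary channel is '%s', expected 'nucleus'",
                 pair$image_id, pair$primary$channel_name))

  nuc <- .threshold_channel(pair$primary, sigma = sigma_nucleus, method = "li",
                            min_size = min_size_nucleus,
                            connectivity = connectivity, image_id = pair$image_id)
  pla <- .threshold_channel(pair$pla, sigma = sigma_pla, method = "triangle",
                            min_size = min_size_pla,
                            connectivity = connectivity, image_id = pair$image_id)

  nucleus_area <- if (nucleus_area_mode == "plane")
    sum(nuc$mask[nuc$best_focus, , ]) else sum(nuc$mask)
  pla_area <- sum(pla$mask)
  if (nucleus_area == 0L)
    stop(sprintf("image '%s': empty nucleus foreground after filtering; ratio undefined",
                 pair$image_id))

  structure(list(image_id = pair$image_id, group_label = pair$group_label,
                 pla_area = as.integer(pla_area),
                 nucleus_area = as.integer(nucleus_area),
                 ratio = pla_area / nucleus_area,
                 best_focus_nucleus = nuc$best_focus,
                 best_focus_pla = pla$best_focus,
                 band_nucleus = nuc$band, band_pla = pla$band,
                 sigma_nucleus = sigma_nucleus, sigma_pla = sigma_pla,
                 min_size_nucleus = as.integer(min_size_nucleus),
                 min_size_pla = as.integer(min_size_pla),
                 nucleus_area_mode = nucleus_area_mode,
                 nucleus_mask = nuc$mask, pla_mask = pla$mask),
            class = "pla_image_result")
}

# blur -> best focus -> auto-threshold on that plane -> 3D band -> size filter
.threshold_channel <- function(channel, sigma, method, min_size, connectivity,
                               image_id = "?") {
  blurred <- if (sigma > 0) gaussian_blur_3d(channel, sigma)
             else array(as.numeric(channel$voxels), dim(channel$voxels))
  bf <- best_focus_index(blurred)
  plane <- blurred[bf, , ]
  mx <- 2^channel$bit_depth - 1
  band <- tryCatch(
    switch(method,
           li = li_threshold(plane, max_intensity = mx, source_plane = bf),
           triangle = triangle_threshold(plane, max_intensity = mx, source_plane = bf)),
    error = function(e) stop(sprintf("image '%s', %s channel: %s", image_id,
                                     channel$channel_name, conditionMessage(e))))
  mask <- apply_band_3d(blurred, band)
  if (!is.null(min_size) && min_size > 1L)
    mask <- size_filter(mask, min_voxels = min_size, connectivity = connectivity)
  list(best_focus = bf, band = band, mask = mask)
}

#' @export
print.pla_image_result <- function(x, ...) {
  cat(sprintf("<pla_image_result '%s'> group %s\n", x$image_id, x$group_label))
  cat(sprintf("  PLA area %d vox / nucleus area %d vox (%s) -> ratio %.6g\n",
              x$pla_area, x$nucleus_area, x$nucleus_area_mode, x$ratio))
  cat(sprintf("  focus z: nucleus %d, pla %d; thresholds: li %.4g, triangle %.4g\n",
              x$best_focus_nucleus, x$best_focus_pla,
              x$band_nucleus$lower, x$band_pla$lower))
  invisible(x)
}

#' @export
as.data.frame.pla_image_result <- function(x, ...) {
  data.frame(image_id = x$image_id, group_label = x$group_label,
             organelle_kind = NA_character_,
             pla_area = x$pla_area, nucleus_area = x$nucleus_area,
             ratio = x$ratio,
             best_focus_nucleus = x$best_focus_nucleus,
             best_focus_pla = x$best_focus_pla,
             threshold_nucleus = x$band_nucleus$lower,
             threshold_pla = x$band_pla$lower,
             sigma_nucleus = x$sigma_nucleus, sigma_pla = x$sigma_pla,
             min_size_nucleus = x$min_size_nucleus,
             min_size_pla = x$min_size_pla,
             stringsAsFactors = FALSE)
}

#' Quantify a set of {nucleus, PLA} images
#'
#' Applies [quantify_pla_image()] to each pair; images whose ratio is
#' undefined (empty nucleus foreground, degenerate constant channel) are
#' excluded and reported with the failure reason rather than aborting the
#' batch.
#'
#' @param pairs list of [stack_pair()] objects.
#' @param ... passed to [quantify_pla_image()].
#' @return List with `results` (list of `pla_image_result`) and `excluded`
#'   (data frame of image_id + reason).
#' @export
quantify_pla_set <- function(pairs, ...) {
  results <- list(); excl_id <- character(0); excl_why <- character(0)
  for (p in pairs) {
    r <- tryCatch(quantify_pla_image(p, ...), error = function(e) e)
    if (inherits(r, "error")) {
      excl_id <- c(excl_id, p$image_id)
      excl_why <- c(excl_why, conditionMessage(r))
    } else results[[length(results) + 1L]] <- r
  }
  list(results = results,
       excluded = data.frame(image_id = excl_id, reason = excl_why,
                             stringsAsFactors = FALSE))
}
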