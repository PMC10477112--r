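#' Quantify one {organelle, PLA} image: percent of organelle occupied by PLA
#'
#' Each channel independently: 3D Gaussian pre-blur (sigma 1 by default for
#' both channels, 0 disables it and matches a literal no-blur reading of the
#' procedure), best-focus plane, Triangle threshold on that plane, band
#' applied to the whole stack. The binary colocalization (voxelwise AND) of
#' the two masks is then related to the organelle mask:
#' `percent_occupied = 100 * |PLA & ORG| / |ORG|`. No size filter is applied
#' by default (the size criterion belongs to the nucleus-normalized
#' pipeline); `min_size` enables one. The reverse fraction
#' `100 * |PLA & ORG| / |PLA|` is carried as a diagnostic.
#'
#' @param pair a [stack_pair()] whose primary channel is the organelle.
#' @param sigma blur sigma in voxels for both channels (0 = off).
#' @param min_size optional minimum component size applied to both masks.
#' @param connectivity component connectivity if `min_size` is used.
#' @return An object of class `organelle_image_result`.
#' @export
quantify_organelle_image <- function(pair, sigma = 1, min_size = NULL,
                                     connectivity = 26L) {
  stopifnot(inherits(pair, "stack_pair"))
  if (pair$primary$channel_name != "organelle")
    stop(sprintf("image '%s': primary channel is '%s', expected 'organelle'",
                 pair$image_id, pair$primary$channel_name))
  org <- .threshold_channel(pair$primary, sigma = sigma, method = "triangle",
                            min_size = min_size, connectivity = connectivity,
                            image_id = pair$image_id)
  pla <- .threshold_channel(pair$pla, sigma = sigma, method = "triangle",
                            min_size = min_size, connectivity = connectivity,
                            image_id = pair$image_id)
  organelle_area <- sum(org$mask)
  pla_area <- sum(pla$mask)
  if (organelle_area == 0L)
    stop(sprintf("image '%s': empty organelle foreground; percentage undefined",
                 pair$image_id))
  overlap <- sum(binary_colocalization(pla$mask, org$mask))
  structure(list(image_id = pair$image_id, group_label = pair$group_label,
                 organelle_kind = if (is.null(pair$organelle_kind))
                   NA_character_ else pair$organelle_kind,
                 organelle_area = as.integer(organelle_area),
                 pla_area = as.integer(pla_area),
                 overlap_area = as.integer(overlap),
                 percent_occupied = 100 * overlap / organelle_area,
                 percent_of_pla = if (pla_area > 0) 100 * overlap / pla_area
                                  else NA_real_,
                 best_focus_organelle = org$best_focus,
                 best_focus_pla = pla$best_focus,
                 band_organelle = org$band, band_pla = pla$band,
                 sigma = sigma,
                 organelle_mask = org$mask, pla_mask = pla$mask),
            class = "organelle_image_result")
}

#' @export
print.organelle_image_result <- function(x, ...) {
  cat(sprintf("<organelle_image_result '%s'> %s, group %s\n",
              x$image_id, x$organelle_kind, x$group_label))
  cat(sprintf("  overlap %d / organelle %d vox -> %.3f%% occupied\n",
              x$overlap_area, x$organelle_area, x$percent_occupied))
  invisible(x)
}

#' @export
as.data.frame.organelle_image_result <- function(x, ...) {
  data.frame(image_id = x$image_id, group_label = x$group_label,
             organelle_kind = x$organelle_kind,
             organelle_area = x$organelle_area, pla_area = x$pla_area,
             overlap_area = x$overlap_area,
             percent_occupied = x$percent_occupied,
             best_focus_organelle = x$best_focus_organelle,
             best_focus_pla = x$best_focus_pla,
             threshold_organelle = x$band_organelle$lower,
             threshold_pla = x$band_pla$lower,
             sigma = x$sigma,
             stringsAsFactors = FALSE)
}

#' Quantify a set of {organelle, PLA} images
#'
#' @param pairs list of [stack_pair()] objects.
#' @param ... passed to [quantify_organelle_image()].
#' @return List with `results` and `excluded` (images with undefined
#'   percentage, with reasons).
#' @export
quantify_organelle_set <- function(pairs, ...) {
  results <- list(); excl_id <- character(0); excl_why <- character(0)
  for (p in pairs) {
    r <- tryCatch(quantify_organelle_image(p, ...), error = function(e) e)
    if (inherits(r, "error")) {
      excl_id <- c(excl_id, p$image_id)
      excl_why <- c(excl_why, conditionMessage(r))
    } else results[[length(results) + 1L]] <- r
  }
  list(results = results,
       excluded = data.frame(image_id = excl_id, reason = excl_why,
                             stringsAsFactors = FALSE))
}

#' Per-organelle, per-group summary of occupancy percentages
#'
#' The image is the statistical unit; each (organelle, group) cell reports
#' mean, SEM and n and needs at least two images.
#'
#' @param results list of `organelle_image_result` objects (or the data
#'   frame from [results_table()]).
#' @return Data frame with columns organelle_kind, group_label, n, mean_percent,
#'   sem_percent.
#' @export
summarize_by_organelle <- function(results) {
  df <- if (is.data.frame(results)) results else results_table(results)
  if (!"percent_occupied" %in% names(df))
    stop("expected organelle results with a 'percent_occupied' column")
  cells <- split(df, list(df$organelle_kind, df$group_label), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(d) {
    if (nrow(d) < 2L)
      stop(sprintf("group '%s' / organelle '%s' has %d image(s); at least 2 required",
                   d$group_label[1], d$organelle_kind[1], nrow(d)))
    data.frame(organelle_kind = d$organelle_kind[1],
               group_label = d$group_label[1], n = nrow(d),
               mean_percent = mean(d$percent_occupied),
               sem_percent = stats::sd(d$percent_occupied) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$organelle_kind, out$group_label), ]
}
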