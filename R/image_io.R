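#' Construct a single-channel 3D image volume
#'
#' The unit of image I/O: one unsigned-integer intensity grid with axis order
#' (z, y, x) and voxel-spacing metadata. The z spacing of 0.5 um matches the
#' step used when the stacks this workflow targets are acquired; the xy
#' spacing is carried as metadata only and never enters any result (all
#' areas are voxel counts whose units cancel in ratios).
#'
#' @param voxels 3D numeric array, axis order (z, y, x), whole non-negative
#'   values within the bit depth.
#' @param channel_name one of `"nucleus"`, `"pla"`, `"organelle"`.
#' @param bit_depth 8 or 16 (unsigned).
#' @param z_spacing plane spacing in micrometres (default 0.5).
#' @param xy_spacing lateral pixel size in micrometres, informational only.
#' @return An object of class `volume_channel`.
#' @export
volume_channel <- function(voxels, channel_name = c("nucleus", "pla", "organelle"),
                           bit_depth = 8L, z_spacing = 0.5, xy_spacing = NA_real_) {
  channel_name <- match.arg(channel_name)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array with axis order (z, y, x)")
  if (!bit_depth %in% c(8L, 16L))
    stop("'bit_depth' must be 8 or 16 (unsigned integer data only)")
  if (dim(voxels)[1] < 1L) stop("a volume needs at least one z-plane")
  v <- as.numeric(voxels)
  if (anyNA(v)) stop("'voxels' contains missing values")
  if (any(v < 0) || any(v > 2^bit_depth - 1))
    stop(sprintf("intensities must lie in [0, %d]", 2^bit_depth - 1))
  if (any(v != floor(v)))
    stop("intensities must be whole numbers; float data are rejected, not converted")
  structure(list(voxels = voxels, channel_name = channel_name,
                 bit_depth = as.integer(bit_depth),
                 z_spacing = z_spacing, xy_spacing = xy_spacing),
            class = "volume_channel")
}

#' @export
print.volume_channel <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_channel '%s'> %d x %d x %d (z,y,x), %d-bit, dz = %g um\n",
              x$channel_name, d[1], d[2], d[3], x$bit_depth, x$z_spacing))
  invisible(x)
}

#' Pair a primary channel with its PLA channel
#'
#' @param primary `volume_channel` named `"nucleus"` or `"organelle"`.
#' @param pla `volume_channel` named `"pla"`.
#' @param image_id opaque identifier.
#' @param group_label group the image belongs to (e.g. `"NPC"`, `"neuron"`).
#' @param organelle_kind optional, one of `"Rab5a"`, `"Rab7a"`, `"Lamp1"`.
#' @return An object of class `stack_pair`.
#' @export
stack_pair <- function(primary, pla, image_id, group_label = NA_character_,
                       organelle_kind = NULL) {
  stopifnot(inherits(primary, "volume_channel"), inherits(pla, "volume_channel"))
  if (!primary$channel_name %in% c("nucleus", "organelle"))
    stop("primary channel must be the nucleus or organelle channel")
  if (pla$channel_name != "pla") stop("second channel must be the PLA channel")
  if (!identical(dim(primary$voxels), dim(pla$voxels)))
    stop(sprintf("channel shapes differ: %s vs %s",
                 paste(dim(primary$voxels), collapse = "x"),
                 paste(dim(pla$voxels), collapse = "x")))
  if (!isTRUE(all.equal(primary$z_spacing, pla$z_spacing)))
    stop("channels must share the same z spacing")
  if (!is.null(organelle_kind) &&
      !organelle_kind %in% c("Rab5a", "Rab7a", "Lamp1"))
    stop("organelle_kind must be one of Rab5a, Rab7a, Lamp1")
  structure(list(primary = primary, pla = pla, image_id = as.character(image_id),
                 group_label = as.character(group_label),
                 organelle_kind = organelle_kind),
            class = "stack_pair")
}

#' @export
print.stack_pair <- function(x, ...) {
  d <- dim(x$primary$voxels)
  cat(sprintf("<stack_pair '%s'> %s + pla, %d x %d x %d, group = %s%s\n",
              x$image_id, x$primary$channel_name, d[1], d[2], d[3],
              x$group_label,
              if (is.null(x$organelle_kind)) "" else paste0(", ", x$organelle_kind)))
  invisible(x)
}

#' Read a multi-page grayscale TIFF as a 3D volume
#'
#' Page order in the file is ascending z. Only unsigned 8- or 16-bit
#' single-sample grayscale data are accepted; float or multi-sample (RGB)
#' pages are rejected rather than silently converted, so that threshold
#' semantics stay well defined.
#'
#' @param path file path.
#' @param channel_name channel to label the volume with.
#' @param z_spacing,xy_spacing voxel spacing metadata.
#' @param pages optional integer vector selecting a subset of pages (used for
#'   interleaved two-channel files).
#' @return A [volume_channel()].
#' @export
read_tiff_volume <- function(path, channel_name = "pla", z_spacing = 0.5,
                             xy_spacing = NA_real_, pages = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  pg <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pg)) pg <- list(pg)
  if (!is.null(pages)) {
    if (any(pages < 1L) || any(pages > length(pg)))
      stop(sprintf("page selection out of range for '%s'", path))
    pg <- pg[pages]
  }
  bits <- unique(vapply(pg, function(p) {
    b <- attr(p, "bits.per.sample")
    if (is.null(b)) NA_integer_ else as.integer(b)
  }, integer(1)))
  if (length(bits) != 1L || !bits %in% c(8L, 16L))
    stop(sprintf("unsupported sample format in '%s': only 8/16-bit unsigned grayscale is accepted", path))
  bad <- vapply(pg, function(p) !is.matrix(p) || !is.integer(p), logical(1))
  if (any(bad))
    stop(sprintf("unsupported sample format in '%s': float or multi-channel pages rejected", path))
  shp <- vapply(pg, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop(sprintf("pages of '%s' differ in shape", path))
  vol <- array(0L, dim = c(length(pg), shp[1, 1], shp[2, 1]))
  for (z in seq_along(pg)) vol[z, , ] <- pg[[z]]
  volume_channel(vol, channel_name = channel_name, bit_depth = bits,
                 z_spacing = z_spacing, xy_spacing = xy_spacing)
}

#' Write a 3D volume as a multi-page grayscale TIFF
#'
#' The round trip through [read_tiff_volume()] is lossless for every voxel.
#'
#' @param channel a [volume_channel()] (or a whole-valued 3D array).
#' @param path destination file.
#' @param bit_depth used when `channel` is a bare array.
#' @return `path`, invisibly.
#' @export
write_tiff_volume <- function(channel, path, bit_depth = 8L) {
  if (inherits(channel, "volume_channel")) {
    vol <- channel$voxels
    bit_depth <- channel$bit_depth
  } else vol <- channel
  mx <- 2^bit_depth - 1
  planes <- lapply(seq_len(dim(vol)[1]), function(z) vol[z, , ] / mx)
  ok <- tiff::writeTIFF(planes, path, bits.per.sample = as.integer(bit_depth),
                        compression = "LZW")
  if (!isTRUE(ok > 0)) stop(sprintf("could not write '%s'", path))
  invisible(path)
}

.manifest_required <- c("image_id", "group_label", "layout", "file_primary",
                        "file_pla", "primary_channel")

#' Read a dataset manifest
#'
#' The manifest, not filename parsing, is the single source of channel and
#' group metadata. It is a CSV with columns `image_id`, `group_label`,
#' `layout` (`"paired"`: one file per channel; `"interleaved"`: one
#' two-channel file whose pages alternate primary, pla, primary, pla, ...
#' in ascending z), `file_primary`, `file_pla` (equal to `file_primary` for
#' interleaved files), `primary_channel` (`"nucleus"` or `"organelle"`), and
#' optionally `organelle_kind` and `replicate_id`. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest CSV.
#' @return A data frame of class `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.manifest_required, names(m))
  if (length(missing_cols))
    stop("manifest lacks required columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(m$image_id)) stop("manifest image_ids must be unique")
  if (!all(m$layout %in% c("paired", "interleaved")))
    stop("layout must be 'paired' or 'interleaved'")
  if (!all(m$primary_channel %in% c("nucleus", "organelle")))
    stop("primary_channel must be 'nucleus' or 'organelle'")
  base <- dirname(normalizePath(path))
  for (col in c("file_primary", "file_pla")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
    absent <- !file.exists(m[[col]])
    if (any(absent))
      stop("manifest references missing file(s): ",
           paste(unique(m[[col]][absent]), collapse = ", "))
  }
  class(m) <- c("dataset_manifest", class(m))
  m
}

#' Read the stack pair described by one manifest row
#'
#' @param row a one-row slice of a manifest read with [read_manifest()].
#' @param z_spacing plane spacing in micrometres.
#' @return A [stack_pair()].
#' @export
read_stack_pair <- function(row, z_spacing = 0.5) {
  if (nrow(row) != 1L) stop("'row' must be a single manifest row")
  kind <- if (!is.null(row$organelle_kind) && !is.na(row$organelle_kind) &&
              nzchar(row$organelle_kind)) row$organelle_kind else NULL
  if (row$layout == "paired") {
    prim <- read_tiff_volume(row$file_primary, channel_name = row$primary_channel,
                             z_spacing = z_spacing)
    pla <- read_tiff_volume(row$file_pla, channel_name = "pla",
                            z_spacing = z_spacing)
  } else {
    n_pages <- length(tiff::readTIFF(row$file_primary, all = TRUE, as.is = TRUE))
    if (n_pages %% 2L != 0L)
      stop(sprintf("interleaved file '%s' has an odd page count", row$file_primary))
    prim <- read_tiff_volume(row$file_primary, channel_name = row$primary_channel,
                             z_spacing = z_spacing, pages = seq(1L, n_pages, by = 2L))
    pla <- read_tiff_volume(row$file_primary, channel_name = "pla",
                            z_spacing = z_spacing, pages = seq(2L, n_pages, by = 2L))
  }
  stack_pair(prim, pla, image_id = row$image_id, group_label = row$group_label,
             organelle_kind = kind)
}

#' Collect per-image results into a data frame
#'
#' @param results list of `pla_image_result` and/or `organelle_image_result`
#'   objects.
#' @return data frame, one row per image, with all measured areas, the
#'   ratio/percentage, best-focus indices and the thresholds used.
#' @export
results_table <- function(results) {
  if (inherits(results, c("pla_image_result", "organelle_image_result")))
    results <- list(results)
  if (length(results) == 0L) stop("no results to tabulate")
  rows <- lapply(results, as.data.frame)
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}

#' Write per-image results to CSV
#'
#' Numeric columns are serialized with 17 significant digits so that
#' re-parsing the file reproduces every ratio bit-identically.
#'
#' @param results list of per-image result objects, or the data frame from
#'   [results_table()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_table(results)
  if (nrow(df) == 0L) stop("no results to write")
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop(sprintf("could not write '%s': %s",
                                            path, conditionMessage(e))))
  invisible(path)
}
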