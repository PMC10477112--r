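#' Apply a threshold band to a whole stack
#'
#' The single band computed on the best-focus plane is applied to every
#' plane: a voxel is foreground iff `lower <= v <= upper` (inclusive).
#'
#' @param x blurred 3D array or [volume_channel()].
#' @param band a [threshold_band()].
#' @return Logical 3D array.
#' @export
apply_band_3d <- function(x, band) {
  stopifnot(inherits(band, "threshold_band"))
  vol <- if (inherits(x, "volume_channel")) x$voxels else x
  array(vol >= band$lower & vol <= band$upper, dim(vol))
}

.offsets_26 <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  # keep one of each +/- pair (lexicographically positive half)
  as.matrix(g[g$dz > 0 | (g$dz == 0 & (g$dy > 0 | (g$dy == 0 & g$dx > 0))), ])
})

.offsets_6 <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), nrow = 3, byrow = TRUE,
                     dimnames = list(NULL, c("dz", "dy", "dx")))

#' Remove small connected components from a binary volume
#'
#' Mirrors the size criterion of the puncta/nucleus detection: connected
#' components (26-connectivity in 3D by default) with fewer than
#' `min_voxels` voxels are discarded. Components are found by building the
#' voxel adjacency graph of the foreground and labeling its connected
#' components.
#'
#' @param mask logical 3D array.
#' @param min_voxels minimum surviving component size (>= 1); 1 is a no-op.
#' @param connectivity 26 (faces, edges and corners) or 6 (faces only).
#' @return Logical 3D array with small components removed.
#' @export
size_filter <- function(mask, min_voxels = 1L, connectivity = 26L) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("'mask' must be a logical 3D array")
  if (min_voxels < 1L) stop("'min_voxels' must be >= 1")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (min_voxels == 1L || !any(mask)) return(mask)
  d <- dim(mask)
  fg <- which(mask)
  co <- arrayInd(fg, d)  # columns: z, y, x
  off <- if (connectivity == 26L) .offsets_26 else .offsets_6
  from <- integer(0); to <- integer(0)
  vid <- seq_along(fg)
  for (r in seq_len(nrow(off))) {
    z <- co[, 1] + off[r, 1]; y <- co[, 2] + off[r, 2]; x <- co[, 3] + off[r, 3]
    ok <- z >= 1L & z <= d[1] & y >= 1L & y <= d[2] & x >= 1L & x <= d[3]
    if (!any(ok)) next
    lin <- z[ok] + (y[ok] - 1L) * d[1] + (x[ok] - 1L) * d[1] * d[2]
    hit <- mask[lin]
    if (!any(hit)) next
    from <- c(from, vid[ok][hit])
    to <- c(to, match(lin[hit], fg))
  }
  g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$csize[comp$membership] >= min_voxels
  out <- array(FALSE, d)
  out[fg[keep]] <- TRUE
  out
}

#' Binary colocalization of two masks
#'
#' Voxelwise conjunction: foreground where both inputs are foreground.
#'
#' @param a,b logical 3D arrays of identical shape.
#' @return Logical 3D array.
#' @export
binary_colocalization <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  array(a & b, dim(a))
}
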