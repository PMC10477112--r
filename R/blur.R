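#' 3D Gaussian blur with reflective boundaries
#'
#' Separable, isotropic in voxel units. The kernel is a normalized sampled
#' Gaussian truncated at `ceiling(3*sigma)`; boundaries are handled by
#' reflection about the edge voxel (…c b a | a b c…), which conserves total
#' intensity. The output is kept in real arithmetic: thresholds are computed
#' on the blurred values and nothing is re-quantized prematurely.
#'
#' @param x a [volume_channel()] or a 3D numeric array (z, y, x).
#' @param sigma positive blur standard deviation in voxels. The workflow uses
#'   sigma 3 for the nucleus channel and sigma 1 for the PLA channel.
#' @return A real-valued 3D array of the same shape.
#' @export
gaussian_blur_3d <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  vol <- if (inherits(x, "volume_channel")) x$voxels else x
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop("'x' must be a 3D array or volume_channel")
  d <- dim(vol)
  k <- .gauss_kernel(sigma)
  out <- array(as.numeric(vol), d)
  # axis 1 (z)
  out <- array(.conv_mat(d[1], k) %*% matrix(out, d[1], d[2] * d[3]), d)
  # axis 2 (y)
  out <- aperm(out, c(2, 1, 3))
  out <- array(.conv_mat(d[2], k) %*% matrix(out, d[2], d[1] * d[3]),
               c(d[2], d[1], d[3]))
  out <- aperm(out, c(2, 1, 3))
  # axis 3 (x)
  out <- aperm(out, c(3, 1, 2))
  out <- array(.conv_mat(d[3], k) %*% matrix(out, d[3], d[1] * d[2]),
               c(d[3], d[1], d[2]))
  aperm(out, c(2, 3, 1))
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Reflect an out-of-range 1-based index back into [1, n] (edge repeated:
# index 0 -> 1, index n+1 -> n), valid for any overshoot via 2n periodicity.
.reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# n x n matrix applying the 1D kernel with reflective boundaries.
.conv_mat <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  rows <- seq_len(n)
  for (o in seq(-r, r)) {
    cols <- .reflect_index(rows + o, n)
    pos <- cbind(rows, cols)
    K[pos] <- K[pos] + k[o + r + 1L]
  }
  K
}
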