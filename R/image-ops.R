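# Low-level raster operations. All use whole-sample mirror padding
# (neighbour of row 1 beyond the edge is row 2), so constants AND linear
# ramps have an exactly zero Laplacian everywhere, including the boundary.

# indices into 1..n for positions possibly outside [1, n], mirrored
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  i <- ifelse(i >= n, period - i, i)
  i + 1L
}

gaussian_kernel_1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(4 * sigma)
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with mirror padding, kernel must have odd length
convolve_mirror <- function(mat, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(mat * kernel)
  n <- nrow(mat)
  m <- ncol(mat)
  # rows
  pr <- mat[reflect_index(seq(1L - r, n + r), n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * pr[k:(k + n - 1L), , drop = FALSE]
  }
  # columns
  pc <- out[, reflect_index(seq(1L - r, m + r), m), drop = FALSE]
  out <- matrix(0, n, m)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * pc[, k:(k + m - 1L), drop = FALSE]
  }
  out
}

gaussian_smooth <- function(mat, sigma) {
  if (sigma == 0) return(mat)
  convolve_mirror(mat, gaussian_kernel_1d(sigma))
}

# discrete 4-neighbour Laplacian [[0,1,0],[1,-4,1],[0,1,0]], mirror padding
laplacian4 <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  up <- mat[reflect_index(0:(n - 1L), n), , drop = FALSE]
  down <- mat[reflect_index(2:(n + 1L), n), , drop = FALSE]
  left <- mat[, reflect_index(0:(m - 1L), m), drop = FALSE]
  right <- mat[, reflect_index(2:(m + 1L), m), drop = FALSE]
  up + down + left + right - 4 * mat
}

# TRUE where a pixel is >= all of its existing 8 neighbours
local_maxima_mask <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  pad <- matrix(-Inf, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- mat
  res <- matrix(TRUE, n, m)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pad[(2:(n + 1L)) + dr, (2:(m + 1L)) + dc, drop = FALSE]
      res <- res & (mat >= nb)
    }
  }
  res
}

# population (1/n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
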