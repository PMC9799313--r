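#' Image container for 2D fluorescence rasters
#'
#' An `image_grid` wraps a numeric pixel matrix together with acquisition
#' metadata (bit depth, optional physical pixel size). All detection
#' functions accept either an `image_grid` or a bare numeric matrix, which is
#' coerced with [as_image_grid()].
#'
#' @param pixels Numeric matrix of nonnegative, finite intensities, at least
#'   3x3 so the Laplacian stencil fits.
#' @param bit_depth Integer, 8 or 16. Metadata only: pixel values are kept on
#'   their native scale and never rescaled.
#' @param pixel_size_nm Optional physical calibration (nanometres per pixel).
#'
#' @return An object of class `image_grid`: a list with elements `pixels`,
#'   `height`, `width`, `bit_depth`, `pixel_size_nm`.
#' @export
#' @examples
#' img <- image_grid(matrix(runif(64, 0, 255), 8, 8))
#' dim(img$pixels)
image_grid <- function(pixels, bit_depth = 8L, pixel_size_nm = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    rlang::abort("`pixels` must be a numeric matrix.",
                 class = "spotbelief_error_invalid_input")
  }
  if (any(!is.finite(pixels))) {
    rlang::abort("Image contains non-finite pixel values.",
                 class = "spotbelief_error_invalid_input")
  }
  if (any(pixels < 0)) {
    rlang::abort("Image contains negative pixel values.",
                 class = "spotbelief_error_invalid_input")
  }
  if (nrow(pixels) < 3 || ncol(pixels) < 3) {
    rlang::abort("Image must be at least 3x3 pixels.",
                 class = "spotbelief_error_invalid_input")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    rlang::abort("`bit_depth` must be 8 or 16.",
                 class = "spotbelief_error_invalid_input")
  }
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      bit_depth = as.integer(bit_depth),
      pixel_size_nm = pixel_size_nm
    ),
    class = "image_grid"
  )
}

#' Coerce to an image_grid
#'
#' @param x An `image_grid` or a numeric matrix.
#' @param ... Passed to [image_grid()] when coercing a matrix.
#' @return An `image_grid`.
#' @export
as_image_grid <- function(x, ...) {
  if (inherits(x, "image_grid")) return(x)
  image_grid(x, ...)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d, %d-bit, intensity range [%g, %g]\n",
              x$height, x$width, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}
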