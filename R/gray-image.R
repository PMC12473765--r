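#' 8-bit grayscale image container
#'
#' A `gray_image` is an integer matrix of intensities in `[0, 255]`
#' (256 gray levels), indexed `[row, column]` with 0-based pixel
#' coordinates in all documentation. It is the input and output type of
#' every stage of the enhancement pipeline.
#'
#' @param pixels numeric or integer matrix; values must be whole numbers
#'   in `[0, 255]`.
#' @return an integer matrix of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(c(100, 150, 200, 50), 2, 2, byrow = TRUE))
#' range(img)
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels)) {
    stop("`pixels` must be a matrix, got ", class(pixels)[1], call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  p <- as.numeric(pixels)
  if (anyNA(p)) stop("image contains missing values", call. = FALSE)
  if (any(p != floor(p))) {
    stop("pixel intensities must be whole numbers", call. = FALSE)
  }
  if (any(p < 0) || any(p > 255)) {
    stop("pixel intensities must lie in [0, 255]; observed range [",
         min(p), ", ", max(p), "]", call. = FALSE)
  }
  out <- matrix(as.integer(p), nrow(pixels), ncol(pixels))
  class(out) <- c("gray_image", class(out))
  out
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, intensity range [%d, %d]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# Validate-or-coerce helper used at every public entry point.
as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x)
}

is_gray_image <- function(x) {
  is.matrix(x) && !anyNA(x) && all(x >= 0) && all(x <= 255) &&
    all(x == floor(x))
}

# Round half away from zero (base round() is round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Clip, round half away from zero, and rebuild a gray_image.
quantize_gray <- function(x) {
  gray_image(matrix(round_half_away(pmin(pmax(x, 0), 255)),
                    nrow(x), ncol(x)))
}
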