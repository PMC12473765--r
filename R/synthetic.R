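#' Neighborhood-archetype and phantom generators
#'
#' Seeded generators for the three neighborhood archetypes used to
#' exercise the local-contrast features — homogeneous (near-constant),
#' binary (two extreme levels), varied-brightness (smooth ramps) — plus a
#' low-contrast blob phantom emulating soft-tissue structures. All
#' generators are deterministic given their arguments; none touches the
#' global random state.
#'
#' @name synthetic-fixtures
NULL

#' @describeIn synthetic-fixtures constant image of a single gray level.
#' @param size image side length in pixels (square images).
#' @param level gray level in `[0, 255]`.
#' @export
make_homogeneous <- function(size, level = 128L) {
  stopifnot(level >= 0, level <= 255)
  gray_image(matrix(as.integer(level), size, size))
}

#' @describeIn synthetic-fixtures two-valued image, extreme luminance.
#' @param lo,hi the two gray levels, `lo < hi`.
#' @param pattern `"checker"` (alternating) or `"halves"` (left/right).
#' @export
make_binary <- function(size, lo = 0L, hi = 255L,
                        pattern = c("checker", "halves")) {
  pattern <- match.arg(pattern)
  stopifnot(lo < hi, lo >= 0, hi <= 255)
  m <- switch(pattern,
    checker = outer(seq_len(size), seq_len(size),
                    function(i, j) ifelse((i + j) %% 2 == 0, hi, lo)),
    halves = matrix(ifelse(rep(seq_len(size), each = size) <= size / 2,
                           lo, hi), size, size))
  gray_image(m)
}

#' @describeIn synthetic-fixtures linear ramp with smooth transitions.
#' @param start,stop gray levels at the two ends of the ramp.
#' @param axis `"x"` (ramp along columns) or `"y"` (along rows).
#' @export
make_gradient <- function(size, start = 0L, stop = 255L,
                          axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(start >= 0, start <= 255, stop >= 0, stop <= 255)
  t <- if (size == 1) 0 else (seq_len(size) - 1) / (size - 1)
  ramp <- round_half_away(start + t * (stop - start))
  m <- if (axis == "x") matrix(ramp, size, size, byrow = TRUE)
       else matrix(ramp, size, size)
  gray_image(m)
}

#' Low-contrast blob phantom
#'
#' A uniform background with circular blobs of given intensity offsets,
#' optionally degraded by Gaussian or salt-and-pepper noise — the
#' degradations typical of MRI and X-ray acquisition. Blobs falling
#' partly outside the frame are clipped to it (with a warning).
#'
#' @param height,width image dimensions, `>= 8` pixels.
#' @param background background gray level.
#' @param blobs list of `list(center = c(row, col), radius, offset)`
#'   entries; `radius >= 1` pixels, `offset` in gray levels (may be
#'   negative).
#' @param noise `"none"`, `"gaussian"`, or `"salt_pepper"`.
#' @param noise_sd Gaussian noise standard deviation (gray levels).
#' @param noise_fraction fraction of pixels flipped to 0/255 under
#'   salt-and-pepper noise, in `[0, 1]`.
#' @param seed integer seed; the generator uses a private RNG stream.
#' @return a [gray_image()].
#' @export
make_phantom <- function(height = 64L, width = height, background = 100L,
                         blobs = list(list(center = c(height / 2, width / 2),
                                           radius = height / 6,
                                           offset = 40)),
                         noise = c("none", "gaussian", "salt_pepper"),
                         noise_sd = 10, noise_fraction = 0.02,
                         seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(height >= 8, width >= 8, background >= 0, background <= 255,
            noise_sd >= 0, noise_fraction >= 0, noise_fraction <= 1)
  m <- matrix(as.numeric(background), height, width)
  for (b in blobs) {
    stopifnot(b$radius >= 1)
    ctr <- b$center
    if (ctr[1] - b$radius < 1 || ctr[1] + b$radius > height ||
        ctr[2] - b$radius < 1 || ctr[2] + b$radius > width) {
      warning("blob at (", ctr[1], ", ", ctr[2], ") extends beyond the ",
              "image and is clipped")
    }
    d2 <- outer(seq_len(height), seq_len(width),
                function(i, j) (i - ctr[1])^2 + (j - ctr[2])^2)
    m[d2 <= b$radius^2] <- m[d2 <= b$radius^2] + b$offset
  }
  m <- apply_noise(m, noise, noise_sd, noise_fraction, seed)
  quantize_gray(m)
}

# Noise under a private RNG stream so callers' random state is untouched.
apply_noise <- function(m, noise, noise_sd, noise_fraction, seed) {
  if (noise == "none") return(m)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  if (noise == "gaussian") {
    m <- m + stats::rnorm(length(m), 0, noise_sd)
  } else {
    n <- length(m)
    k <- round(noise_fraction * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      m[idx] <- ifelse(stats::runif(k) < 0.5, 0, 255)
    }
  }
  m
}

#' The reference 2x2 worked-example image
#'
#' The 2x2 patch `[[100, 150], [200, 50]]` used throughout the
#' documentation to trace normalization, fuzzification and refinement by
#' hand.
#'
#' @return a 2x2 [gray_image()].
#' @export
make_worked_example <- function() {
  gray_image(matrix(c(100L, 150L, 200L, 50L), 2, 2, byrow = TRUE))
}
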