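#' Fuzzifier specification
#'
#' Bundles the parameters of the fuzzification stage: the membership
#' function that maps normalized intensities `u` in `[0, 1]` to membership
#' degrees, and the refinement applied afterwards.
#'
#' Two membership shapes are supported:
#' \describe{
#'   \item{`sigmoid`}{`mu = 1 / (1 + exp(-gain * (u - center)))`; `gain`
#'     (`a`) controls steepness and `center` (`b`) the midpoint. The
#'     default `a = 10`, `b = 0.5` centres the "bright" fuzzy set on
#'     mid-gray.}
#'   \item{`rational`}{`mu = 1 / (1 + abs(u - class_center) / width)`, a
#'     symmetric peak reaching 1 at `u = class_center`.}
#' }
#'
#' Refinement modes:
#' \describe{
#'   \item{`power`}{`mu' = mu^gamma`; `gamma > 1` darkens low memberships,
#'     emphasising edge transitions (default `gamma = 1.2`, a setting
#'     suited to CT).}
#'   \item{`intensify`}{the classical S-shaped intensification
#'     `mu' = 2 mu^2` for `mu <= 0.5`, `1 - 2 (1 - mu)^2` otherwise.}
#'   \item{`none`}{identity.}
#' }
#'
#' @param shape `"sigmoid"` or `"rational"`.
#' @param gain sigmoid steepness `a > 0`.
#' @param center sigmoid midpoint `b` in `[0, 1]`.
#' @param class_center peak location `c` in `[0, 1]` (rational shape).
#' @param width spread `sigma_f > 0` (rational shape).
#' @param refinement `"power"`, `"intensify"`, or `"none"`.
#' @param gamma power-refinement exponent, `> 0`.
#' @return a classed list of validated parameters.
#' @export
fuzzifier_spec <- function(shape = c("sigmoid", "rational"),
                           gain = 10, center = 0.5,
                           class_center = 0.5, width = 0.25,
                           refinement = c("power", "intensify", "none"),
                           gamma = 1.2) {
  shape <- match.arg(shape)
  refinement <- match.arg(refinement)
  stopifnot(is.numeric(gain), length(gain) == 1, gain > 0,
            is.numeric(center), length(center) == 1,
            center >= 0, center <= 1,
            is.numeric(class_center), length(class_center) == 1,
            class_center >= 0, class_center <= 1,
            is.numeric(width), length(width) == 1, width > 0,
            is.numeric(gamma), length(gamma) == 1, gamma > 0)
  structure(list(shape = shape, gain = gain, center = center,
                 class_center = class_center, width = width,
                 refinement = refinement, gamma = gamma),
            class = "fuzzifier_spec")
}

#' Normalize an 8-bit image to the unit interval
#'
#' Step 1 of the pipeline. Two modes:
#' \describe{
#'   \item{`fullrange`}{`u = f / 255`, the fixed 8-bit scale (default;
#'     required to reproduce the worked 2x2 example).}
#'   \item{`minmax`}{`u = (f - f_min) / (f_max - f_min)` with the image's
#'     own extremes; errors on a constant image.}
#' }
#'
#' @param image a [gray_image()] (or coercible matrix).
#' @param mode `"fullrange"` or `"minmax"`.
#' @return a `unit_image`: a numeric matrix in `[0, 1]` with attributes
#'   `source_min`, `source_max`, `mode`.
#' @examples
#' normalize_gray(gray_image(matrix(c(100, 150, 200, 50), 2, 2)))
#' @export
normalize_gray <- function(image, mode = c("fullrange", "minmax")) {
  image <- as_gray_image(image)
  mode <- match.arg(mode)
  if (mode == "fullrange") {
    lo <- 0L; hi <- 255L
  } else {
    lo <- min(image); hi <- max(image)
    if (lo == hi) {
      stop("min-max normalization is undefined on a constant image ",
           "(all pixels = ", lo, ")", call. = FALSE)
    }
  }
  u <- (unclass(image) - lo) / (hi - lo)
  structure(u, source_min = lo, source_max = hi, mode = mode,
            class = c("unit_image", "matrix", "array"))
}

#' Fuzzify normalized intensities into membership degrees
#'
#' Step 2. Applies the spec's membership function elementwise; see
#' [fuzzifier_spec()] for the two shapes. Outputs lie in `(0, 1]`.
#'
#' @param u a unit image from [normalize_gray()] (or numeric matrix in
#'   `[0, 1]`).
#' @param spec a [fuzzifier_spec()].
#' @return a numeric matrix of membership degrees, same shape as `u`.
#' @examples
#' fuzzify(matrix(0.392), fuzzifier_spec())  # ~0.253
#' @export
fuzzify <- function(u, spec = fuzzifier_spec()) {
  stopifnot(inherits(spec, "fuzzifier_spec"), is.numeric(u))
  if (any(u < 0) || any(u > 1)) {
    stop("normalized intensities must lie in [0, 1]", call. = FALSE)
  }
  mu <- switch(spec$shape,
    sigmoid  = 1 / (1 + exp(-spec$gain * (u - spec$center))),
    rational = 1 / (1 + abs(u - spec$class_center) / spec$width))
  m <- matrix(as.numeric(mu), nrow(u), ncol(u))
  class(m) <- c("membership_map", class(m))
  m
}

#' Refine membership degrees
#'
#' Step 3. Sharpens the membership map according to `spec$refinement`:
#' power-law `mu^gamma`, the piecewise S-shaped intensification, or the
#' identity. Fixed points 0 and 1 are preserved by all modes.
#'
#' @param mu membership matrix in `[0, 1]`.
#' @param spec a [fuzzifier_spec()].
#' @return refined membership matrix, same shape.
#' @export
refine <- function(mu, spec = fuzzifier_spec()) {
  stopifnot(inherits(spec, "fuzzifier_spec"), is.numeric(mu))
  if (any(mu < 0) || any(mu > 1)) {
    stop("membership degrees must lie in [0, 1]", call. = FALSE)
  }
  out <- switch(spec$refinement,
    power = mu^spec$gamma,
    intensify = ifelse(mu <= 0.5, 2 * mu^2, 1 - 2 * (1 - mu)^2),
    none = mu)
  m <- matrix(as.numeric(out), nrow(mu), ncol(mu))
  class(m) <- c("membership_map", class(m))
  m
}

# Inverse of refine() for the invertible modes; used by defuzzification.
unrefine <- function(mu, spec) {
  switch(spec$refinement,
    power = mu^(1 / spec$gamma),
    intensify = ifelse(mu <= 0.5, sqrt(mu / 2), 1 - sqrt((1 - mu) / 2)),
    none = mu)
}

#' Trace the 2x2 worked example through Steps 1-3
#'
#' Runs full-range normalization, the sigmoid fuzzifier (`a = 10`,
#' `b = 0.5`) and power refinement (`gamma = 1.2`) on the reference 2x2
#' image `[[100, 150], [200, 50]]` and returns the per-pixel trace, for
#' documentation and regression tests.
#'
#' @return a data frame with columns `row`, `col`, `original`,
#'   `normalized`, `membership`, `refined` (one row per pixel, row-major).
#' @examples
#' worked_example_trace()
#' @export
worked_example_trace <- function() {
  img <- make_worked_example()
  spec <- fuzzifier_spec()
  u <- normalize_gray(img, "fullrange")
  mu <- fuzzify(u, spec)
  mur <- refine(mu, spec)
  idx <- expand.grid(col = seq_len(ncol(img)), row = seq_len(nrow(img)))
  data.frame(row = idx$row, col = idx$col,
             original = as.integer(t(unclass(img))),
             normalized = as.numeric(t(unclass(u))),
             membership = as.numeric(t(unclass(mu))),
             refined = as.numeric(t(unclass(mur))))
}
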