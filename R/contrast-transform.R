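#' Adaptive-exponent specification
#'
#' Parameters bounding and shaping the per-pixel enhancement exponent
#' `alpha(x, y)`. Exponents below 1 amplify local contrast, above 1
#' compress it; `[0.5, 2]` is a conventional range for power-law
#' contrast laws.
#'
#' @param alpha_min lower bound, `> 0`.
#' @param alpha_max upper bound, `>= alpha_min`.
#' @param s sensitivity exponent `> 0` controlling enhancement strength.
#'   Field practice pairs `s = 1.5` with the histogram-spread variant,
#'   `s = 2` with fuzzy entropy (noise-sensitive MRI) and `s = 1.2` with
#'   fuzzy standard deviation (X-ray opacity detection).
#' @param a0 reference feature value for the histogram variant (the
#'   Gaussian response is minimal at `h = a0`).
#' @param spread Gaussian width of the histogram response, `> 0`
#'   (default `pi`).
#' @return a classed list.
#' @export
alpha_spec <- function(alpha_min = 0.5, alpha_max = 2.0, s = 1.5,
                       a0 = 0, spread = pi) {
  stopifnot(is.numeric(alpha_min), alpha_min > 0,
            is.numeric(alpha_max), alpha_max >= alpha_min,
            is.numeric(s), s > 0,
            is.numeric(a0), length(a0) == 1,
            is.numeric(spread), spread > 0)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max, s = s,
                 a0 = a0, spread = spread),
            class = "alpha_spec")
}

alpha_map <- function(values, spec) {
  structure(values, alpha_min = spec$alpha_min, alpha_max = spec$alpha_max,
            class = c("alpha_map", "matrix", "array"))
}

#' Adaptive exponent from histogram spread
#'
#' `alpha = alpha_min + (alpha_max - alpha_min) *
#'   (1 - exp(-(h - a0)^2 / (2 spread^2)))^s`:
#' minimal (`alpha_min`) where the spread equals the reference `a0`,
#' rising towards `alpha_max` as the spread departs from it.
#'
#' @param h a `feature_map` of kind `histogram_spread`.
#' @param spec an [alpha_spec()].
#' @return an `alpha_map` bounded by `[alpha_min, alpha_max]`.
#' @export
alpha_from_histogram <- function(h, spec = alpha_spec(s = 1.5)) {
  stopifnot(inherits(spec, "alpha_spec"))
  g <- (1 - exp(-(unclass(h) - spec$a0)^2 / (2 * spec$spread^2)))^spec$s
  alpha_map(spec$alpha_min + (spec$alpha_max - spec$alpha_min) * g, spec)
}

#' Adaptive exponent from fuzzy entropy
#'
#' `alpha = alpha_min + (alpha_max - alpha_min) *
#'   ((eps - eps_min) / (eps_max - eps_min))^s`, with the extremes taken
#' over the whole entropy map; monotone nondecreasing in the entropy.
#' On a flat entropy map (no spread) the fallback is `alpha_min`
#' everywhere, reported via a warning.
#'
#' @param eps a `feature_map` of kind `fuzzy_entropy`.
#' @param spec an [alpha_spec()].
#' @return an `alpha_map` bounded by `[alpha_min, alpha_max]`.
#' @export
alpha_from_entropy <- function(eps, spec = alpha_spec(s = 2)) {
  stopifnot(inherits(spec, "alpha_spec"))
  e <- unclass(eps)
  lo <- min(e); hi <- max(e)
  if (hi <= lo) {
    warning("entropy map is constant; using alpha_min everywhere")
    return(alpha_map(matrix(spec$alpha_min, nrow(e), ncol(e)), spec))
  }
  g <- ((e - lo) / (hi - lo))^spec$s
  alpha_map(spec$alpha_min + (spec$alpha_max - spec$alpha_min) * g, spec)
}

#' Adaptive exponent from fuzzy standard deviation
#'
#' With `w = clip(sigma / 255, 0, 1)`:
#' `alpha = alpha_min * w^s + alpha_max * (1 - w^s)`; monotone
#' nonincreasing in the deviation, so homogeneous regions receive the
#' largest exponent.
#'
#' @param sigma a `feature_map` of kind `fuzzy_std` (gray levels).
#' @param spec an [alpha_spec()].
#' @return an `alpha_map` bounded by `[alpha_min, alpha_max]`.
#' @export
alpha_from_std <- function(sigma, spec = alpha_spec(s = 1.2)) {
  stopifnot(inherits(spec, "alpha_spec"))
  w <- pmin(pmax(unclass(sigma) / 255, 0), 1)^spec$s
  alpha_map(spec$alpha_min * w + spec$alpha_max * (1 - w), spec)
}

#' Contrast transformation specification
#'
#' Constants of the nonlinear local-contrast transformation: `R` is the
#' maximum feasible local contrast (fixed at 1), `A0` and `B0` are bias
#' coefficients (both 0 by default), and the pivot `C^` is the arithmetic
#' mean of the local-contrast map.
#'
#' @param A0,B0 nonnegative bias coefficients; `B0 + (R/2 - A0)` must lie
#'   in `[0, R]`.
#' @param R maximum feasible local contrast (fixed 1).
#' @return a classed list.
#' @export
contrast_transform_spec <- function(A0 = 0, B0 = 0, R = 1) {
  stopifnot(is.numeric(A0), A0 >= 0, is.numeric(B0), B0 >= 0,
            isTRUE(all.equal(R, 1)))
  mid <- B0 + (R / 2 - A0)
  if (mid < 0 || mid > R) {
    stop("B0 + (R/2 - A0) = ", mid, " falls outside [0, R]", call. = FALSE)
  }
  structure(list(A0 = A0, B0 = B0, R = R),
            class = "contrast_transform_spec")
}

#' Nonlinear local-contrast transformation
#'
#' Rescales the local-contrast map `C` through a two-branch power law
#' pivoted at the map's mean `C^`:
#' below the pivot,
#' `C* = B0 + (R/2 - A0) * ((C - C_min) / (C^ - C_min))^alpha`;
#' above it,
#' `C* = R - A0 - (R/2 - A0) * ((C_max - C) / (C_max - C^))^alpha`.
#' The branches agree at the pivot; with the default biases the map sends
#' `C_min -> 0`, `C^ -> 1/2`, `C_max -> 1`. `alpha` is taken per pixel
#' from the alpha map. Outputs are clipped to `[0, R]`.
#'
#' Degenerate guards: a constant `C` map is returned unchanged (with a
#' warning); if the pivot coincides with `C_min`, the lower branch
#' returns the midpoint value.
#'
#' @param C a `feature_map` of kind `local_contrast`.
#' @param alpha an `alpha_map`, same shape.
#' @param spec a [contrast_transform_spec()].
#' @return a `feature_map` of kind `local_contrast` holding `C*`.
#' @export
transform_contrast <- function(C, alpha, spec = contrast_transform_spec()) {
  stopifnot(inherits(spec, "contrast_transform_spec"),
            all(dim(alpha) == dim(C)))
  cm <- unclass(C); am <- unclass(alpha)
  cmin <- min(cm); cmax <- max(cm)
  nb <- attr(C, "neighborhood")
  if (cmax <= cmin) {
    warning("local-contrast map is constant; transformation is identity")
    return(feature_map(cm, "local_contrast", nb))
  }
  chat <- mean(cm)
  R <- spec$R; A0 <- spec$A0; B0 <- spec$B0
  half <- R / 2 - A0
  lower <- if (chat > cmin) {
    B0 + half * ((cm - cmin) / (chat - cmin))^am
  } else {
    matrix(B0 + half, nrow(cm), ncol(cm))
  }
  out <- lower
  if (cmax > chat) {
    up <- cm > chat
    upper <- R - A0 - half * ((cmax - cm) / (cmax - chat))^am
    out[up] <- upper[up]
  }
  feature_map(pmin(pmax(out, 0), R), "local_contrast", nb)
}

#' Reconstruct an image from enhanced local contrast
#'
#' The final defuzzification stage: each pixel is moved away from (or
#' towards) its window mean by the contrast gain,
#' `f' = M_W + g * (f - M_W)` with `g = C* / max(C, 1/255)` and `M_W`
#' the `n x n` window mean of the input image. The minimum denominator of
#' one gray level (1/255) guards division where the original contrast
#' vanishes. When `C* = C` the gain is 1 and the image passes through
#' unchanged up to quantization. Results are clipped to `[0, 255]` and
#' rounded half away from zero.
#'
#' @param image the [gray_image()] being enhanced.
#' @param C its local-contrast `feature_map`.
#' @param Cstar the transformed contrast map.
#' @param nb the [neighborhood_spec()] used for the window mean.
#' @return a [gray_image()].
#' @export
reconstruct <- function(image, C, Cstar, nb = neighborhood_spec()) {
  image <- as_gray_image(image)
  stopifnot(all(dim(C) == dim(image)), all(dim(Cstar) == dim(image)))
  st <- window_stack(image, nb)
  mw <- apply(st, c(1, 2), mean)
  g <- unclass(Cstar) / pmax(unclass(C), 1 / 255)
  quantize_gray(mw + g * (unclass(image) - mw))
}

#' Defuzzify a membership map back to gray levels
#'
#' Materializes the fuzzy-enhanced base image by inverting the refinement
#' (power: `mu^(1/gamma)`; intensification: its piecewise inverse) and
#' the sigmoid membership function
#' (`u = b - ln(1/mu - 1) / a`), then rescaling to `[0, 255]`, clipping
#' and rounding half away from zero. Monotone in `mu`; degenerate
#' memberships 0 and 1 map to gray 0 and 255.
#'
#' @param mu a refined membership map produced with a sigmoid fuzzifier.
#' @param spec the [fuzzifier_spec()] that produced it (`shape` must be
#'   `"sigmoid"`).
#' @return a [gray_image()].
#' @export
defuzzify_membership <- function(mu, spec = fuzzifier_spec()) {
  stopifnot(inherits(spec, "fuzzifier_spec"), is.numeric(mu))
  if (spec$shape != "sigmoid") {
    stop("defuzzification requires the invertible sigmoid fuzzifier",
         call. = FALSE)
  }
  m <- unrefine(pmin(pmax(unclass(mu), 0), 1), spec)
  u <- matrix(NA_real_, nrow(m), ncol(m))
  interior <- m > 0 & m < 1
  u[interior] <- spec$center - log(1 / m[interior] - 1) / spec$gain
  u[m <= 0] <- 0
  u[m >= 1] <- 1
  quantize_gray(pmin(pmax(u, 0), 1) * 255)
}
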