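#' Sliding-window neighborhood specification
#'
#' @param size odd window side length `n >= 3`, in pixels; the window is
#'   `n x n` centered on each pixel.
#' @param border how the image is padded so edge windows are full-sized:
#'   `"reflect"` mirrors across the edge, `"replicate"` repeats the edge
#'   pixel. Map shape therefore always equals image shape.
#' @return a classed list.
#' @export
neighborhood_spec <- function(size = 3L, border = c("reflect", "replicate")) {
  border <- match.arg(border)
  stopifnot(is.numeric(size), length(size) == 1, size >= 3,
            size == floor(size), size %% 2 == 1)
  structure(list(size = as.integer(size), border = border),
            class = "neighborhood_spec")
}

# Pad a matrix by r rows/cols on every side. reflect = symmetric mirror
# (edge pixel included), so it works down to 1x1 inputs when r <= dim.
pad_matrix <- function(m, r, border = "reflect") {
  h <- nrow(m); w <- ncol(m)
  idx <- function(n) {
    i <- seq.int(1 - r, n + r)
    if (border == "replicate") {
      pmin(pmax(i, 1L), n)
    } else {
      # reflect indices into [1, n] by repeated folding at the mirrors
      j <- i - 1L
      p <- 2L * n
      j <- j %% p
      j <- ifelse(j < 0, j + p, j)
      ifelse(j < n, j + 1L, p - j)
    }
  }
  m[idx(h), idx(w), drop = FALSE]
}

# Stack every window offset of a padded image into an H x W x n^2 array.
window_stack <- function(m, nb) {
  r <- (nb$size - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  p <- pad_matrix(unclass(m), r, nb$border)
  k <- nb$size
  st <- array(0, c(h, w, k * k))
  s <- 1L
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      st[, , s] <- p[di:(di + h - 1L), dj:(dj + w - 1L)]
      s <- s + 1L
    }
  }
  st
}

feature_map <- function(values, kind, nb) {
  structure(values, kind = kind, neighborhood = nb,
            class = c("feature_map", "matrix", "array"))
}

#' Local contrast map
#'
#' At each pixel, `(max - min) / 255` over the `n x n` neighborhood of
#' the (border-padded) image: 0 on homogeneous windows, 1 when the window
#' spans the full 8-bit range.
#'
#' @param image a [gray_image()].
#' @param nb a [neighborhood_spec()].
#' @return a `feature_map` matrix in `[0, 1]`, `kind = "local_contrast"`.
#' @export
local_contrast_map <- function(image, nb = neighborhood_spec()) {
  image <- as_gray_image(image)
  st <- window_stack(image, nb)
  cmax <- apply(st, c(1, 2), max)
  cmin <- apply(st, c(1, 2), min)
  feature_map((cmax - cmin) / 255, "local_contrast", nb)
}

#' Membership-weighted global contrast
#'
#' A single whole-image statistic:
#' `2 * sqrt( sum((f - M)^2 * mu) / sum(mu) ) / 255`, where `M` is the
#' membership-weighted mean intensity; clipped to `[0, 1]`. Zero on a
#' constant image, 1 for a balanced black/white image under uniform
#' weights.
#'
#' @param image a [gray_image()].
#' @param mu membership weights, same shape as `image`.
#' @return a scalar in `[0, 1]`.
#' @export
global_contrast <- function(image, mu) {
  image <- as_gray_image(image)
  stopifnot(is.numeric(mu), all(dim(mu) == dim(image)))
  f <- as.numeric(image); w <- as.numeric(mu)
  sw <- sum(w)
  if (sw <= 0) {
    stop("all membership weights are zero; global contrast undefined",
         call. = FALSE)
  }
  m <- sum(f * w) / sw
  rms <- sqrt(sum((f - m)^2 * w) / sw)
  min(max(2 * rms / 255, 0), 1)
}

#' Histogram spread map
#'
#' At each pixel, `(f_max - f_min) / h_max` over the window, where
#' `h_max` is the count of the window's most frequent intensity. Zero in
#' homogeneous regions; maximal in binary regions where the range is wide
#' and no single level dominates. Units: gray levels per count.
#'
#' @inheritParams local_contrast_map
#' @return a `feature_map` of nonnegative values, `kind = "histogram_spread"`.
#' @export
histogram_spread_map <- function(image, nb = neighborhood_spec()) {
  image <- as_gray_image(image)
  st <- window_stack(image, nb)
  k2 <- dim(st)[3]
  fmax <- apply(st, c(1, 2), max)
  fmin <- apply(st, c(1, 2), min)
  # modal count: for each element, how many window entries equal it;
  # the max over elements is the tallest histogram bin.
  hmax <- matrix(0, nrow(st), ncol(st))
  for (i in seq_len(k2)) {
    ci <- matrix(0, nrow(st), ncol(st))
    for (j in seq_len(k2)) ci <- ci + (st[, , j] == st[, , i])
    hmax <- pmax(hmax, ci)
  }
  feature_map((fmax - fmin) / hmax, "histogram_spread", nb)
}

#' Fuzzy entropy map
#'
#' Frequency-based fuzzy entropy over each `n x n` window. Each window
#' element's membership is its intensity's relative frequency in the
#' window, `mu_i = h(f_i) / n^2`; the entropy is
#' `-(1 / (n^2 ln n^2)) * sum_i [mu_i ln mu_i + (1 - mu_i) ln(1 - mu_i)]`
#' with the convention `0 ln 0 = 0`. Values lie in `[0, 1]`: 0 on
#' homogeneous windows (every `mu_i = 1`), maximal among two-valued
#' windows at a 50/50 split.
#'
#' @inheritParams local_contrast_map
#' @return a `feature_map` in `[0, 1]`, `kind = "fuzzy_entropy"`.
#' @export
fuzzy_entropy_map <- function(image, nb = neighborhood_spec()) {
  image <- as_gray_image(image)
  st <- window_stack(image, nb)
  k2 <- dim(st)[3]
  acc <- matrix(0, nrow(st), ncol(st))
  for (i in seq_len(k2)) {
    ci <- matrix(0, nrow(st), ncol(st))
    for (j in seq_len(k2)) ci <- ci + (st[, , j] == st[, , i])
    mu <- ci / k2
    acc <- acc + xlogx(mu) + xlogx(1 - mu)
  }
  feature_map(-acc / (k2 * log(k2)), "fuzzy_entropy", nb)
}

# x * log(x) with 0 log 0 = 0, elementwise.
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Fuzzy standard deviation map
#'
#' At each pixel, the membership-weighted standard deviation of window
#' intensities about the window's plain arithmetic mean:
#' `sigma = sqrt( sum((f_j - mean)^2 * mu_j) / sum(mu_j) )`, in gray
#' levels. Zero on homogeneous windows. A window whose weights all vanish
#' yields 0 (reported once per image via a warning).
#'
#' @inheritParams local_contrast_map
#' @param mu membership weights, same shape as `image`.
#' @return a nonnegative `feature_map`, `kind = "fuzzy_std"`.
#' @export
fuzzy_std_map <- function(image, mu, nb = neighborhood_spec()) {
  image <- as_gray_image(image)
  stopifnot(is.numeric(mu), all(dim(mu) == dim(image)))
  stf <- window_stack(image, nb)
  stw <- window_stack(matrix(as.numeric(mu), nrow(mu), ncol(mu)), nb)
  k2 <- dim(stf)[3]
  wmean <- apply(stf, c(1, 2), mean)
  num <- matrix(0, nrow(stf), ncol(stf))
  den <- matrix(0, nrow(stf), ncol(stf))
  for (i in seq_len(k2)) {
    num <- num + (stf[, , i] - wmean)^2 * stw[, , i]
    den <- den + stw[, , i]
  }
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad), " window(s) had zero total membership weight; ",
            "their fuzzy standard deviation is reported as 0")
    den[bad] <- 1
    num[bad] <- 0
  }
  feature_map(sqrt(num / den), "fuzzy_std", nb)
}

# ---- single-window statistics (shared closed-form building blocks) ----

# Modal-count histogram spread of one window's values.
window_histogram_spread <- function(v) {
  (max(v) - min(v)) / max(table(v))
}

# Frequency-based fuzzy entropy of one window's values.
window_fuzzy_entropy <- function(v) {
  n <- length(v)
  counts <- table(v)
  mu <- as.numeric(counts[match(as.character(v), names(counts))]) / n
  -sum(xlogx(mu) + xlogx(1 - mu)) / (n * log(n))
}

# Weighted std of one window about its plain mean.
window_fuzzy_std <- function(v, w) {
  if (sum(w) <= 0) return(0)
  m <- mean(v)
  sqrt(sum((v - m)^2 * w) / sum(w))
}

#' Naive per-pixel sliding-window oracle
#'
#' Recomputes any of the four feature maps by explicit per-pixel
#' iteration over extracted windows, with no vectorized shortcuts. Used
#' as an independent cross-check of the optimized maps on small images.
#'
#' @inheritParams fuzzy_std_map
#' @param kind one of `"local_contrast"`, `"histogram_spread"`,
#'   `"fuzzy_entropy"`, `"fuzzy_std"`.
#' @param mu membership weights (required for `"fuzzy_std"` only).
#' @return a `feature_map` with the same contract as the optimized map.
#' @export
sliding_window_oracle <- function(image, nb = neighborhood_spec(),
                                  kind = c("local_contrast",
                                           "histogram_spread",
                                           "fuzzy_entropy", "fuzzy_std"),
                                  mu = NULL) {
  image <- as_gray_image(image)
  kind <- match.arg(kind)
  if (nrow(image) > 64 || ncol(image) > 64) {
    stop("oracle is restricted to images of at most 64 x 64", call. = FALSE)
  }
  r <- (nb$size - 1L) %/% 2L
  p <- pad_matrix(unclass(image), r, nb$border)
  pw <- if (!is.null(mu)) pad_matrix(matrix(as.numeric(mu), nrow(mu), ncol(mu)),
                                     r, nb$border)
  out <- matrix(0, nrow(image), ncol(image))
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      win <- as.numeric(p[i:(i + 2L * r), j:(j + 2L * r)])
      out[i, j] <- switch(kind,
        local_contrast = (max(win) - min(win)) / 255,
        histogram_spread = window_histogram_spread(win),
        fuzzy_entropy = window_fuzzy_entropy(win),
        fuzzy_std = {
          if (is.null(pw)) stop("`mu` is required for kind = 'fuzzy_std'",
                                call. = FALSE)
          window_fuzzy_std(win, as.numeric(pw[i:(i + 2L * r),
                                              j:(j + 2L * r)]))
        })
    }
  }
  feature_map(out, kind, nb)
}
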