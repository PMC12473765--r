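# Steps 6, 8, 10, 11, 12: adaptive exponents, the nonlinear transform,
# and reconstruction/defuzzification.

fm <- function(values, kind = "local_contrast", nb = neighborhood_spec()) {
  structure(values, kind = kind, neighborhood = nb,
            class = c("feature_map", "matrix", "array"))
}

test_that("histogram-spread alpha follows the Gaussian response", {
  spec <- alpha_spec(0.5, 2.0, s = 1, a0 = 10, spread = 4)
  h <- fm(matrix(10, 3, 3), "histogram_spread")
  expect_equal(unclass(alpha_from_histogram(h, spec)),
               matrix(0.5, 3, 3), ignore_attr = TRUE)
  far <- fm(matrix(1e6, 1, 1), "histogram_spread")
  expect_equal(as.numeric(alpha_from_histogram(far, spec)), 2.0)
  # half-maximum point: |h - a0| = spread * sqrt(2 ln 2) gives the midpoint
  half <- fm(matrix(10 + 4 * sqrt(2 * log(2)), 1, 1), "histogram_spread")
  expect_equal(as.numeric(alpha_from_histogram(half, spec)), 1.25,
               tolerance = 1e-12)
})

test_that("entropy alpha spans [alpha_min, alpha_max] over the map's range", {
  spec <- alpha_spec(0.5, 2.0, s = 2)
  eps <- fm(matrix(c(0.2, 0.4, 0.6, 0.3), 2, 2), "fuzzy_entropy")
  a <- alpha_from_entropy(eps, spec)
  expect_equal(as.numeric(a)[1], 0.5)   # map minimum
  expect_equal(as.numeric(a)[3], 2.0)   # map maximum
  # midrange with s = 2: alpha_min + (alpha_max - alpha_min) * 0.25
  expect_equal(as.numeric(a)[2], 0.875, tolerance = 1e-12)
  expect_warning(flat <- alpha_from_entropy(fm(matrix(0.3, 2, 2),
                                               "fuzzy_entropy"), spec),
                 "constant")
  expect_true(all(flat == 0.5))
})

test_that("std alpha interpolates from alpha_max (flat) to alpha_min (busy)", {
  spec <- alpha_spec(0.5, 2.0, s = 1.2)
  sig <- fm(matrix(c(0, 255, 255 * 0.5^(1 / 1.2)), 1, 3), "fuzzy_std")
  a <- as.numeric(alpha_from_std(sig, spec))
  expect_equal(a[1], 2.0)
  expect_equal(a[2], 0.5)
  expect_equal(a[3], 1.25, tolerance = 1e-12)  # w^s = 0.5 -> midpoint
})

test_that("alpha maps are always bounded and suitably monotone", {
  spec <- alpha_spec(0.7, 1.8, s = 1.4)
  for (seed in 1:5) {
    e <- sort(as.numeric(rand_membership(5, 5, seed)))
    ae <- as.numeric(alpha_from_entropy(fm(matrix(e, 5, 5), "fuzzy_entropy"),
                                        spec))
    expect_true(all(ae >= 0.7 - 1e-12 & ae <= 1.8 + 1e-12))
    expect_true(all(diff(ae) >= -1e-12))  # nondecreasing in entropy
    s <- matrix(sort(runif_det(25, 0, 300, seed)), 5, 5)
    as_ <- as.numeric(alpha_from_std(fm(s, "fuzzy_std"), spec))
    expect_true(all(as_ >= 0.7 - 1e-12 & as_ <= 1.8 + 1e-12))
    expect_true(all(diff(as_) <= 1e-12))  # nonincreasing in sigma
    h <- matrix(sort(abs(runif_det(25, -50, 50, seed + 7))), 5, 5)
    ah <- as.numeric(alpha_from_histogram(fm(h, "histogram_spread"),
                                          alpha_spec(0.7, 1.8, s = 1.4,
                                                     a0 = 0, spread = 20)))
    expect_true(all(diff(ah) >= -1e-12))  # monotone in |h - a0|
  }
})

test_that("the contrast transform hits its endpoints and is continuous", {
  nb <- neighborhood_spec()
  C <- fm(matrix(seq(0.1, 0.9, length.out = 25), 5, 5))
  chat <- mean(unclass(C))
  for (seed in 1:100) {
    alpha <- structure(matrix(runif_det(25, 0.5, 2, seed), 5, 5),
                       class = c("alpha_map", "matrix", "array"))
    cs <- transform_contrast(C, alpha)
    expect_equal(as.numeric(cs)[which.min(C)], 0)
    expect_equal(as.numeric(cs)[which.max(C)], 1)
    expect_true(all(cs >= 0 & cs <= 1))
    # continuity at the pivot: a symmetric map keeps its mean at `chat`,
    # and the values straddling it from either branch agree
    eps <- 1e-9
    Cpm <- fm(matrix(c(chat - eps, chat + eps,
                       chat - 0.05, chat + 0.05), 2, 2))
    a2 <- structure(matrix(alpha[1], 2, 2),
                    class = c("alpha_map", "matrix", "array"))
    expect_lt(abs(diff(as.numeric(transform_contrast(Cpm, a2))[1:2])), 1e-5)
  }
})

test_that("with alpha = 1 the transform is the known piecewise-linear map", {
  C <- fm(matrix(c(0.0, 0.2, 0.4, 0.8, 0.6, 0.1, 0.3, 0.5, 0.7), 3, 3))
  cm <- unclass(C)
  chat <- mean(cm); cmin <- min(cm); cmax <- max(cm)
  ones <- structure(matrix(1, 3, 3),
                    class = c("alpha_map", "matrix", "array"))
  got <- unclass(transform_contrast(C, ones))
  expected <- ifelse(cm <= chat,
                     0.5 * (cm - cmin) / (chat - cmin),
                     1 - 0.5 * (cmax - cm) / (cmax - chat))
  expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)
  # slope below the pivot is (R/2)/(chat - cmin)
  expect_equal((got[cm == 0.2] - got[cm == 0.0]) / 0.2,
               0.5 / (chat - cmin), tolerance = 1e-12)
})

test_that("the transform is monotone within each branch", {
  for (seed in 1:5) {
    v <- sort(runif_det(30, 0, 1, seed))
    C <- fm(matrix(v, 5, 6))
    alpha <- structure(matrix(runif_det(1, 0.5, 2, seed + 50), 5, 6),
                       class = c("alpha_map", "matrix", "array"))
    cs <- as.numeric(transform_contrast(C, alpha))
    chat <- mean(v)
    expect_true(all(diff(cs[v <= chat]) >= -1e-12))
    expect_true(all(diff(cs[v > chat]) >= -1e-12))
  }
})

test_that("degenerate contrast maps pass through the transform unchanged", {
  C <- fm(matrix(0.3, 4, 4))
  a <- structure(matrix(1.5, 4, 4),
                 class = c("alpha_map", "matrix", "array"))
  expect_warning(out <- transform_contrast(C, a), "identity")
  expect_equal(unclass(out), unclass(C), ignore_attr = TRUE)
})

test_that("reconstruction matches an independent per-pixel oracle", {
  nb <- neighborhood_spec()
  for (seed in 1:5) {
    img <- rand_gray(9, 9, seed)
    C <- local_contrast_map(img, nb)
    g <- if (seed == 1) 2 else runif_det(1, 0, 2, seed)  # includes gain 2
    Cstar <- fm(pmin(unclass(C) * g, 1))
    got <- reconstruct(img, C, Cstar, nb)
    # naive reconstruction: per-pixel window mean and gain
    p <- fuzzimg:::pad_matrix(unclass(img), 1, "reflect")
    exp_out <- matrix(0, 9, 9)
    for (i in 1:9) for (j in 1:9) {
      mw <- mean(p[i:(i + 2), j:(j + 2)])
      gain <- Cstar[i, j] / max(C[i, j], 1 / 255)
      exp_out[i, j] <- min(max(mw + gain * (img[i, j] - mw), 0), 255)
    }
    expect_equal(unclass(got),
                 matrix(as.integer(sign(exp_out) * floor(abs(exp_out) + 0.5)),
                        9, 9),
                 ignore_attr = TRUE)
  }
})

test_that("reconstruction with unit gain is the identity up to quantization", {
  for (seed in 1:20) {
    img <- rand_gray(12, 12, seed)
    C <- local_contrast_map(img)
    out <- reconstruct(img, C, C)
    expect_true(max(abs(unclass(out) - unclass(img))) <= 1)
  }
})

test_that("zero enhanced contrast collapses pixels to their window means", {
  img <- rand_gray(7, 7, 3)
  C <- local_contrast_map(img)
  zero <- fm(matrix(0, 7, 7))
  out <- reconstruct(img, C, zero)
  st_mean <- apply(fuzzimg:::window_stack(img, neighborhood_spec()),
                   c(1, 2), mean)
  expect_equal(unclass(out),
               matrix(as.integer(floor(st_mean + 0.5)), 7, 7),
               ignore_attr = TRUE)
})

test_that("defuzzification inverts fuzzification within one gray level", {
  spec <- fuzzifier_spec()
  # sigmoid midpoint with no refinement maps back to mid-gray
  plain <- fuzzifier_spec(refinement = "none")
  expect_equal(as.integer(defuzzify_membership(matrix(0.5), plain)), 128L)
  expect_equal(as.integer(defuzzify_membership(matrix(1), spec)), 255L)
  expect_equal(as.integer(defuzzify_membership(matrix(0), spec)), 0L)
  for (seed in 1:10) {
    img <- rand_gray(10, 10, seed)
    mu <- refine(fuzzify(normalize_gray(img), spec), spec)
    back <- defuzzify_membership(mu, spec)
    expect_true(max(abs(unclass(back) - unclass(img))) <= 1)
  }
  # the intensification refinement is inverted exactly as well
  its <- fuzzifier_spec(refinement = "intensify")
  img <- rand_gray(8, 8, 77)
  mu <- refine(fuzzify(normalize_gray(img), its), its)
  expect_true(max(abs(unclass(defuzzify_membership(mu, its)) -
                      unclass(img))) <= 1)
  expect_error(defuzzify_membership(matrix(0.5),
                                    fuzzifier_spec(shape = "rational")),
               "sigmoid")
})
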