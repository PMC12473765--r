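#' Pipeline configuration
#'
#' Aggregates the parameters of the full 12-step enhancement pipeline:
#' normalization mode, fuzzifier, neighborhood, one adaptive-exponent
#' spec per variant, and the contrast-transformation constants. The
#' defaults are the reference setting: full-range normalization, sigmoid
#' fuzzifier (`a = 10`, `b = 0.5`), power refinement (`gamma = 1.2`),
#' 3x3 reflect-padded windows, and sensitivity exponents `s = 1.5`
#' (histogram spread), `s = 2` (fuzzy entropy), `s = 1.2` (fuzzy
#' standard deviation).
#'
#' @param normalization `"fullrange"` or `"minmax"`.
#' @param fuzzifier a [fuzzifier_spec()].
#' @param neighborhood a [neighborhood_spec()].
#' @param alpha_histogram,alpha_entropy,alpha_std per-variant
#'   [alpha_spec()]s.
#' @param contrast a [contrast_transform_spec()].
#' @param variants nonempty subset of `c("histogram", "entropy", "std")`.
#' @param emit_base also write the shared fuzzy-enhanced base image
#'   during corpus runs (debug aid).
#' @return a classed list.
#' @export
pipeline_config <- function(normalization = c("fullrange", "minmax"),
                            fuzzifier = fuzzifier_spec(),
                            neighborhood = neighborhood_spec(),
                            alpha_histogram = alpha_spec(s = 1.5),
                            alpha_entropy = alpha_spec(s = 2),
                            alpha_std = alpha_spec(s = 1.2),
                            contrast = contrast_transform_spec(),
                            variants = c("histogram", "entropy", "std"),
                            emit_base = FALSE) {
  normalization <- match.arg(normalization)
  variants <- match.arg(variants, c("histogram", "entropy", "std"),
                        several.ok = TRUE)
  if (length(variants) == 0) stop("`variants` must be nonempty")
  stopifnot(inherits(fuzzifier, "fuzzifier_spec"),
            inherits(neighborhood, "neighborhood_spec"),
            inherits(alpha_histogram, "alpha_spec"),
            inherits(alpha_entropy, "alpha_spec"),
            inherits(alpha_std, "alpha_spec"),
            inherits(contrast, "contrast_transform_spec"))
  structure(list(normalization = normalization, fuzzifier = fuzzifier,
                 neighborhood = neighborhood,
                 alpha_histogram = alpha_histogram,
                 alpha_entropy = alpha_entropy, alpha_std = alpha_std,
                 contrast = contrast, variants = variants,
                 emit_base = isTRUE(emit_base)),
            class = "pipeline_config")
}

#' Stable digest of a pipeline configuration
#'
#' MD5 of the canonical JSON serialization of the configuration, so
#' identical configurations always share a digest across sessions.
#'
#' @param config a [pipeline_config()].
#' @return a hex digest string.
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  js <- jsonlite::toJSON(lapply(unclass(config), unclass),
                         auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Enhance one image into its three variants
#'
#' Runs the full pipeline on a single image. Steps 1-3 build the shared
#' fuzzy-enhanced base (normalize, fuzzify, refine, defuzzify). For each
#' requested variant, its local-contrast characteristic is computed on
#' the base — histogram spread, fuzzy entropy, or fuzzy standard
#' deviation (the last weighted by the refined membership map) — mapped
#' to an adaptive exponent field, used to transform the base's
#' local-contrast map, and the enhanced image is reconstructed.
#' Deterministic: identical input and configuration give bit-identical
#' output.
#'
#' @param image a [gray_image()].
#' @param config a [pipeline_config()].
#' @return an `enhanced_triplet`: list with `base`, one [gray_image()]
#'   per requested variant under `$variants`, and `provenance`.
#' @examples
#' tr <- enhance_image(make_phantom(height = 16, width = 16))
#' names(tr$variants)
#' @export
enhance_image <- function(image, config = pipeline_config()) {
  image <- as_gray_image(image)
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$fuzzifier
  nb <- config$neighborhood

  u <- normalize_gray(image, config$normalization)
  mu <- fuzzify(u, spec)
  mur <- refine(mu, spec)
  base <- defuzzify_membership(mur, spec)

  C <- local_contrast_map(base, nb)
  flat <- max(C) <= min(C)

  out <- list()
  for (v in config$variants) {
    if (flat) {
      # no contrast to transform: every variant passes the base through
      out[[v]] <- base
      next
    }
    alpha <- switch(v,
      histogram = alpha_from_histogram(histogram_spread_map(base, nb),
                                       config$alpha_histogram),
      entropy = alpha_from_entropy(fuzzy_entropy_map(base, nb),
                                   config$alpha_entropy),
      std = alpha_from_std(fuzzy_std_map(base, mur, nb),
                           config$alpha_std))
    cstar <- transform_contrast(C, alpha, config$contrast)
    out[[v]] <- reconstruct(base, C, cstar, nb)
  }
  structure(list(base = base, variants = out,
                 provenance = list(digest = config_digest(config),
                                   shape = dim(image))),
            class = "enhanced_triplet")
}

#' @export
print.enhanced_triplet <- function(x, ...) {
  cat(sprintf("<enhanced_triplet> %d x %d; variants: %s\n",
              x$provenance$shape[1], x$provenance$shape[2],
              paste(names(x$variants), collapse = ", ")))
  invisible(x)
}

variant_suffix <- c(histogram = "hist", entropy = "ent", std = "fsd")

#' Enhance a corpus of images
#'
#' Applies [enhance_image()] to every input, writing one output image per
#' (input x variant) — so a corpus of 300 images with all three variants
#' yields 900 outputs — plus a JSON manifest recording counts, the
#' configuration digest, and any per-file failures. A failing input is
#' recorded and processing continues.
#'
#' @param inputs character vector of image paths, or a list of
#'   [gray_image()]s (named or not).
#' @param output_dir directory for outputs and `manifest.json`; `NULL`
#'   keeps results in memory only (the manifest is still returned).
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly when writing to disk: a list with
#'   `config_digest`, `n_inputs`, `n_variants`, `n_outputs`, `outputs`,
#'   `failures`.
#' @export
enhance_corpus <- function(inputs, output_dir = NULL,
                           config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  digest <- config_digest(config)
  if (!is.null(output_dir) &&
      !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  outputs <- list(); failures <- list()
  n_ok <- 0L
  for (i in seq_along(inputs)) {
    src <- if (is.character(inputs)) inputs[[i]] else
      if (!is.null(names(inputs)) && nzchar(names(inputs)[i]))
        names(inputs)[i] else sprintf("image_%04d", i)
    res <- tryCatch({
      img <- if (is.character(inputs)) read_image(inputs[[i]]) else
        as_gray_image(inputs[[i]])
      enhance_image(img, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(path = src, reason = conditionMessage(res))
      next
    }
    n_ok <- n_ok + 1L
    stem <- tools::file_path_sans_ext(basename(src))
    for (v in names(res$variants)) {
      fname <- sprintf("%s_%s.png", stem, variant_suffix[[v]])
      if (!is.null(output_dir)) {
        write_image(res$variants[[v]], file.path(output_dir, fname))
      }
      outputs[[length(outputs) + 1L]] <-
        list(source = src, variant = v, path = fname)
    }
    if (config$emit_base && !is.null(output_dir)) {
      write_image(res$base, file.path(output_dir,
                                      sprintf("%s_base.png", stem)))
    }
  }
  manifest <- list(config_digest = digest,
                   n_inputs = length(inputs),
                   n_variants = length(config$variants),
                   n_outputs = n_ok * length(config$variants),
                   outputs = outputs, failures = failures)
  if (!is.null(output_dir)) {
    write_json_atomic(manifest, file.path(output_dir, "manifest.json"))
  }
  if (length(failures) > 0) {
    warning(length(failures), " input(s) failed; see manifest failures")
  }
  manifest
}

#' Slice a 3D volume into 8-bit axial images
#'
#' Rescales the volume to `[0, 255]` by its own global minimum and
#' maximum, quantizes, and returns the 2D slices along the chosen axis
#' in order. A constant volume yields all-zero slices (with a warning).
#'
#' @param volume a 3D numeric array.
#' @param axis slicing axis, 1-3; the default 3 is the axial
#'   (superior-inferior) axis under the usual NIfTI x/y/z layout.
#' @return a list of [gray_image()]s, one per slice, with a
#'   `slice_index` attribute preserving order.
#' @export
slice_volume <- function(volume, axis = 3L) {
  stopifnot(is.array(volume), length(dim(volume)) == 3,
            axis %in% 1:3, dim(volume)[axis] >= 1)
  lo <- min(volume); hi <- max(volume)
  if (hi <= lo) {
    warning("constant volume; all slices are zero")
    scaled <- array(0, dim(volume))
  } else {
    scaled <- (volume - lo) / (hi - lo) * 255
  }
  n <- dim(volume)[axis]
  slices <- vector("list", n)
  for (k in seq_len(n)) {
    sl <- switch(axis,
                 `1` = scaled[k, , ],
                 `2` = scaled[, k, ],
                 `3` = scaled[, , k])
    slices[[k]] <- quantize_gray(as.matrix(sl))
  }
  attr(slices, "slice_index") <- seq_len(n)
  slices
}
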