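#' Read an 8-bit grayscale image
#'
#' Reads PNG or TIFF (by extension). Multi-channel inputs are collapsed
#' by the channel average; inputs with more than 8 bits of precision are
#' min-max rescaled to `[0, 255]` (noted via a message), 8-bit inputs
#' are mapped through the exact `[0,1] -> [0,255]` scale.
#'
#' @param path file path ending in `.png`, `.tif`, or `.tiff`.
#' @return a [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("no such image file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = try(png::readPNG(path), silent = TRUE),
    tif = ,
    tiff = try(tiff::readTIFF(path), silent = TRUE),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE))
  if (inherits(arr, "try-error")) {
    stop("could not decode image file: ", path, call. = FALSE)
  }
  if (length(dim(arr)) == 3) {
    # luminance average over channels (alpha, if present, is dropped)
    nc <- min(dim(arr)[3], 3L)
    arr <- apply(arr[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  v <- arr * 255
  if (max(abs(v - round(v))) > 1e-6) {
    # finer-than-8-bit quantization: rescale by the observed range
    message("rescaling >8-bit image to 8 bits by min-max: ", path)
    lo <- min(arr); hi <- max(arr)
    v <- if (hi > lo) (arr - lo) / (hi - lo) * 255 else arr * 0
  }
  quantize_gray(v)
}

#' Write an 8-bit grayscale PNG or TIFF
#'
#' Writes atomically (temp file in the target directory, then rename) so
#' an interrupted run never leaves a truncated image.
#'
#' @param image a [gray_image()].
#' @param path destination ending in `.png`, `.tif`, or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", ext))
  arr <- unclass(image) / 255
  switch(ext,
    png = png::writePNG(arr, tmp),
    tif = ,
    tiff = tiff::writeTIFF(arr, tmp, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE))
  file.rename(tmp, path)
  invisible(path)
}

# Atomic JSON writer shared by manifests and fixture sidecars.
write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` volume; only the intensity array and enough
#' axis metadata for axial slicing are retained.
#'
#' @param path NIfTI file path.
#' @return a list with `data` (3D array), `dim`, and `pixdim` (voxel
#'   spacing, if present).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop("no such volume file: ", path, call. = FALSE)
  }
  vol <- try(RNifti::readNifti(path), silent = TRUE)
  if (inherits(vol, "try-error")) {
    stop("could not read NIfTI volume: ", path, call. = FALSE)
  }
  arr <- as.array(vol)
  if (length(dim(arr)) > 3) {
    # drop trailing singleton dimensions (e.g. single-timepoint 4D)
    arr <- array(arr, dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3) {
    stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  }
  list(data = arr, dim = dim(arr), pixdim = RNifti::pixdim(vol))
}

#' No-reference image quality metrics
#'
#' Simple per-image quality scores for before/after comparisons:
#' \describe{
#'   \item{`rms_contrast`}{standard deviation of intensities on the unit
#'     scale (population form); 0 for a constant image.}
#'   \item{`entropy`}{Shannon entropy of the 256-bin intensity histogram,
#'     in bits; 0 for a constant image.}
#'   \item{`brisque`}{not bundled: requires an external BRISQUE
#'     implementation, so requesting it raises a capability error rather
#'     than a score.}
#' }
#'
#' @param images a list of [gray_image()]s (or a single image).
#' @param metric one of `"rms_contrast"`, `"entropy"`, `"brisque"`.
#' @return a data frame with columns `image` and `score`.
#' @export
evaluate_quality <- function(images,
                             metric = c("rms_contrast", "entropy",
                                        "brisque")) {
  metric <- match.arg(metric)
  if (metric == "brisque") {
    stop(structure(class = c("capability_error", "error", "condition"),
                   list(message = paste(
                     "BRISQUE scoring needs an external BRISQUE",
                     "implementation, which is not bundled with this",
                     "package; use metric = 'rms_contrast' or 'entropy'"),
                     call = NULL)))
  }
  if (is.matrix(images)) images <- list(images)
  scores <- vapply(images, function(img) {
    img <- as_gray_image(img)
    v <- as.numeric(img)
    switch(metric,
      rms_contrast = sqrt(mean((v / 255 - mean(v / 255))^2)),
      entropy = {
        p <- tabulate(v + 1L, nbins = 256L) / length(v)
        -sum(xlogx(p)) / log(2)
      })
  }, numeric(1))
  nm <- names(images)
  if (is.null(nm)) nm <- sprintf("image_%04d", seq_along(images))
  data.frame(image = nm, score = scores, row.names = NULL)
}
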