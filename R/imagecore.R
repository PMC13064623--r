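#' A single-channel microscopy image
#'
#' The universal currency of the pipeline: a 2-D intensity matrix plus
#' modality and quality metadata. Intensities are stored as doubles
#' throughout; integer TIFF data are converted on read, never truncated.
#'
#' @param pixels Numeric matrix (height x width), finite-valued.
#' @param modality One of `"confocal"`, `"sted"`, `"dsted"`, `"generated"`,
#'   `"unknown"`.
#' @param quality One of `"high"`, `"low"`, `"unknown"`.
#' @param id Identifier string.
#' @param pixel_size_nm Optional physical pixel size in nanometres.
#' @return An object of class `micro_image`.
#' @export
micro_image <- function(pixels, modality = "unknown", quality = "unknown",
                        id = "", pixel_size_nm = NULL) {
  pixels <- as_pixels(pixels)
  modality <- match.arg(modality,
                        c("confocal", "sted", "dsted", "generated", "unknown"))
  quality <- match.arg(quality, c("high", "low", "unknown"))
  if (!is.null(pixel_size_nm)) stopifnot(pixel_size_nm > 0)
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 modality = modality, quality = quality, id = as.character(id)),
            class = "micro_image")
}

as_pixels <- function(x) {
  if (inherits(x, "micro_image")) return(x$pixels)
  if (!is.matrix(x)) stop("pixels must be a matrix")
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("pixels must be finite (no NA/NaN/Inf)")
  x
}

#' @export
print.micro_image <- function(x, ...) {
  cat(sprintf("<micro_image %s: %d x %d, %s/%s, range [%.4g, %.4g]>\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$modality, x$quality,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

with_pixels <- function(img, pixels, modality = img$modality,
                        quality = img$quality, id = img$id) {
  micro_image(pixels, modality = modality, quality = quality, id = id,
              pixel_size_nm = img$pixel_size_nm)
}

#' A co-registered source/target image pair
#'
#' @param source,target [micro_image()]s of identical size (source is the
#'   confocal image, target the STED or deconvolved-STED image).
#' @param sample_id Identifier.
#' @param registered Logical; synthetic pairs are born registered.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(source, target, sample_id = "", registered = TRUE) {
  stopifnot(inherits(source, "micro_image"), inherits(target, "micro_image"))
  if (!identical(dim(source$pixels), dim(target$pixels)))
    stop("source and target must have identical dimensions")
  structure(list(source = source, target = target, registered = registered,
                 sample_id = as.character(sample_id)),
            class = "paired_sample")
}

#' An ordered collection of paired samples
#'
#' @param samples List of [paired_sample()]s with unique ids.
#' @param fold_of Optional named integer vector mapping sample_id to a fold
#'   index (0-based), as produced by [kfold_split()].
#' @return An object of class `image_dataset`.
#' @export
image_dataset <- function(samples, fold_of = NULL) {
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (!is.null(fold_of) && !all(names(fold_of) %in% ids))
    stop("fold_of refers to unknown sample ids")
  structure(list(samples = samples, fold_of = fold_of),
            class = "image_dataset")
}

#' @export
length.image_dataset <- function(x) length(x$samples)

#' Read a single-channel grayscale TIFF
#'
#' Integer data (8- or 16-bit) are read losslessly: a 16-bit pixel of 65535
#' becomes 65535.0, with no silent rescale. Multi-channel images are
#' rejected.
#'
#' @param path Path to the TIFF file.
#' @param modality,quality Metadata to attach, see [micro_image()].
#' @return A [micro_image()] whose id is the file name without extension.
#' @export
read_image <- function(path, modality = "unknown", quality = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  probe <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(probe, "bits.per.sample") %||% 8L
  # 8/16-bit files hold unsigned integers (read losslessly as stored);
  # 32-bit files hold IEEE floats, which the default read returns as-is.
  px <- if (bits >= 32) probe else tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 1) px <- px[, , 1] else
      stop("single-channel required: ", path, " has ", dim(px)[3], " channels")
  }
  if (all(is.na(px))) stop("all-NaN image: ", path)
  px <- matrix(as.double(px), nrow = nrow(px))
  micro_image(px, modality = modality, quality = quality,
              id = tools::file_path_sans_ext(basename(path)))
}

#' Write an image as a 32-bit float TIFF
#'
#' @param img A [micro_image()] or matrix with values in \[0, 1\] (the float
#'   TIFF dialect used for all intermediate products).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- as_pixels(img)
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}

#' Percentile normalization to the unit interval
#'
#' Linearly rescales so that the `p_lo` percentile maps to 0 and `p_hi` to
#' 1, clipping outside; the defaults give a plain min-max normalization.
#' Constant images map to all zeros so degenerate tiles never crash a batch
#' pipeline.
#'
#' @param img [micro_image()] or matrix.
#' @param p_lo,p_hi Percentiles in \[0, 100\] with `p_lo < p_hi`.
#' @return Image of the same type with values in \[0, 1\].
#' @export
normalize_unit <- function(img, p_lo = 0, p_hi = 100) {
  stopifnot(p_lo >= 0, p_hi <= 100, p_lo < p_hi)
  px <- as_pixels(img)
  if (length(px) == 0) stop("empty image")
  lo <- as.numeric(quantile(px, p_lo / 100, type = 7))
  hi <- as.numeric(quantile(px, p_hi / 100, type = 7))
  out <- if (hi > lo) pmin(pmax((px - lo) / (hi - lo), 0), 1) else px * 0
  if (inherits(img, "micro_image")) with_pixels(img, out) else out
}

#' Map unit-range intensities to the network range and back
#'
#' The generators end in tanh, so they operate on \[-1, 1\]; metrics operate
#' on \[0, 1\]. `to_net_range` applies v -> 2v - 1 and `from_net_range` its
#' inverse; the round trip is the identity.
#'
#' @param img [micro_image()] or matrix in \[0, 1\] (resp. \[-1, 1\]).
#' @param tol Tolerance for the range check.
#' @return Image of the same type in the other range.
#' @export
to_net_range <- function(img, tol = 1e-6) {
  px <- as_pixels(img)
  if (min(px) < -tol || max(px) > 1 + tol)
    stop("input outside [0, 1] beyond tolerance")
  out <- 2 * px - 1
  if (inherits(img, "micro_image")) with_pixels(img, out) else out
}

#' @rdname to_net_range
#' @export
from_net_range <- function(img, tol = 1e-6) {
  px <- as_pixels(img)
  if (min(px) < -1 - tol || max(px) > 1 + tol)
    stop("input outside [-1, 1] beyond tolerance")
  out <- (px + 1) / 2
  if (inherits(img, "micro_image")) with_pixels(img, out) else out
}
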