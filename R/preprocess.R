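#' Preprocessing configuration
#'
#' @param saturation_fraction Fraction of pixels saturated by the contrast
#'   stretch (default 0.0035, the ImageJ "Enhance Contrast" default of
#'   0.35%).
#' @param pad_size Standardized output size (default 128; even, >= 16).
#' @param crop_margin_px Margin added around the segmented object.
#' @param smooth_sigma_px Gaussian smoothing before thresholding.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(saturation_fraction = 0.0035, pad_size = 128L,
                              crop_margin_px = 8L, smooth_sigma_px = 1.0) {
  stopifnot(saturation_fraction >= 0, saturation_fraction < 0.5,
            pad_size >= 16, pad_size %% 2 == 0, crop_margin_px >= 0,
            smooth_sigma_px >= 0)
  structure(list(saturation_fraction = saturation_fraction,
                 pad_size = as.integer(pad_size),
                 crop_margin_px = as.integer(crop_margin_px),
                 smooth_sigma_px = smooth_sigma_px),
            class = "preprocess_config")
}

#' Saturated-quantile contrast stretch
#'
#' ImageJ-style "Enhance Contrast": a linear stretch mapping the
#' `saturation_fraction / 2` lower and upper intensity quantiles to 0 and 1
#' with clipping, so that fraction of pixels saturates. A constant image is
#' returned as all zeros.
#'
#' @param img [micro_image()] or matrix.
#' @param saturation_fraction Fraction of pixels allowed to saturate.
#' @return Image with values in \[0, 1\].
#' @export
enhance_contrast <- function(img, saturation_fraction = 0.0035) {
  stopifnot(saturation_fraction >= 0, saturation_fraction < 0.5)
  normalize_unit(img, p_lo = 100 * saturation_fraction / 2,
                 p_hi = 100 * (1 - saturation_fraction / 2))
}

#' A crop box (0-based, half-open)
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels.
#' @return An object of class `crop_box`.
#' @export
crop_box <- function(row0, col0, height, width) {
  stopifnot(row0 >= 0, col0 >= 0, height >= 1, width >= 1)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "crop_box")
}

apply_crop <- function(px, box) {
  px[(box$row0 + 1):(box$row0 + box$height),
     (box$col0 + 1):(box$col0 + box$width), drop = FALSE]
}

#' Segment the target structure and crop both images of a pair
#'
#' Gaussian-smooth the target, threshold with Otsu's criterion, keep the
#' largest connected component, and crop both images with that component's
#' bounding box plus a margin (clipped to the image). Registration is
#' preserved because one box is applied to both.
#'
#' @param pair A registered [paired_sample()] with nonzero target signal.
#' @param config A [preprocess_config()].
#' @return List with `box` (a [crop_box()]) and `pair` (the cropped pair).
#' @export
segment_crop <- function(pair, config = preprocess_config()) {
  stopifnot(inherits(pair, "paired_sample"))
  if (!pair$registered) stop("segment_crop requires a registered pair")
  tgt <- pair$target$pixels
  rng <- range(tgt)
  if (rng[2] <= rng[1]) stop("no object found: target image is constant")
  sm <- if (config$smooth_sigma_px > 0)
    blur_gaussian(tgt, config$smooth_sigma_px) else tgt
  smn <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- otsu_threshold(smn)
  mask <- smn > thr
  if (!any(mask)) stop("no object found: all pixels below threshold")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  counts <- tabulate(labm[labm > 0])
  keep <- which.max(counts)
  obj <- labm == keep
  rows <- which(apply(obj, 1, any))
  cols <- which(apply(obj, 2, any))
  r0 <- max(min(rows) - 1L - config$crop_margin_px, 0L)
  c0 <- max(min(cols) - 1L - config$crop_margin_px, 0L)
  r1 <- min(max(rows) - 1L + config$crop_margin_px, nrow(tgt) - 1L)
  c1 <- min(max(cols) - 1L + config$crop_margin_px, ncol(tgt) - 1L)
  box <- crop_box(r0, c0, r1 - r0 + 1L, c1 - c0 + 1L)
  if (box$height > config$pad_size || box$width > config$pad_size)
    stop(sprintf(paste0("object bounding box %dx%d exceeds pad size %d; ",
                        "increase pad_size or use a center-crop override"),
                 box$height, box$width, config$pad_size))
  cropped <- paired_sample(
    with_pixels(pair$source, apply_crop(pair$source$pixels, box)),
    with_pixels(pair$target, apply_crop(pair$target$pixels, box)),
    sample_id = pair$sample_id, registered = pair$registered)
  list(box = box, pair = cropped)
}

# Otsu's threshold on a [0, 1] image (maximizes between-class variance).
otsu_threshold <- function(px, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(px * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Pad an image to a standardized square size
#'
#' Centers the image on a zero background with offset
#' `floor((pad - h) / 2)`; intensities are never rescaled, so total mass is
#' conserved.
#'
#' @param img [micro_image()] or matrix with height and width <= `pad_size`.
#' @param pad_size Output side length.
#' @return Padded image of size `pad_size` x `pad_size`.
#' @export
pad_to <- function(img, pad_size = 128L) {
  px <- as_pixels(img)
  h <- nrow(px); w <- ncol(px)
  if (h > pad_size || w > pad_size)
    stop(sprintf("input %dx%d exceeds pad size %d", h, w, pad_size))
  out <- matrix(0, pad_size, pad_size)
  r0 <- floor((pad_size - h) / 2)
  c0 <- floor((pad_size - w) / 2)
  out[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- px
  if (inherits(img, "micro_image")) with_pixels(img, out) else out
}

dihedral_transforms <- list(
  function(m) m,
  function(m) t(m)[, nrow(m):1, drop = FALSE],                 # rot90 ccw -> use consistent def
  function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],           # rot180
  function(m) t(m)[ncol(m):1, , drop = FALSE],                 # rot270
  function(m) m[, ncol(m):1, drop = FALSE],                    # h-flip
  function(m) t(m),                                            # rot90 + hflip
  function(m) m[nrow(m):1, , drop = FALSE],                    # v-flip
  function(m) t(m)[nrow(m):1, ncol(m):1, drop = FALSE]         # rot270 + hflip
)

#' Apply one dihedral transform to a square matrix
#'
#' @param m Square matrix.
#' @param k Element index 1..8 (identity; rotations by 90/180/270; each
#'   optionally composed with a horizontal flip).
#' @return Transformed matrix.
#' @export
dihedral_apply <- function(m, k) {
  stopifnot(k %in% 1:8)
  if (nrow(m) != ncol(m)) stop("dihedral augmentation requires square images")
  dihedral_transforms[[k]](m)
}

#' Random dihedral augmentation of a pair
#'
#' Draws one of the 8 symmetry transforms of the square uniformly and
#' applies it identically to source and target; intensities are untouched.
#'
#' @param pair A [paired_sample()] of square images.
#' @param seed Optional seed; if `NULL` the current RNG state is used (the
#'   training loader samples one element per iteration).
#' @return The augmented [paired_sample()].
#' @export
augment <- function(pair, seed = NULL) {
  if (!is.null(seed)) seed_all(seed)
  k <- sample.int(8L, 1L)
  paired_sample(
    with_pixels(pair$source, dihedral_apply(pair$source$pixels, k)),
    with_pixels(pair$target, dihedral_apply(pair$target$pixels, k)),
    sample_id = pair$sample_id, registered = pair$registered)
}

#' Run the full preprocessing pipeline on a pair
#'
#' Composition contrast stretch -> segment/crop -> pad -> unit
#' normalization, with identical geometry applied to source and target.
#' Augmentation is sampled per training iteration, not here.
#'
#' @param pair A registered [paired_sample()].
#' @param config A [preprocess_config()].
#' @return The processed [paired_sample()] with the crop box attached as
#'   attribute `"crop_box"`.
#' @export
run_preprocess <- function(pair, config = preprocess_config()) {
  enh <- paired_sample(
    with_pixels(pair$source,
                enhance_contrast(pair$source$pixels,
                                 config$saturation_fraction)),
    with_pixels(pair$target,
                enhance_contrast(pair$target$pixels,
                                 config$saturation_fraction)),
    sample_id = pair$sample_id, registered = pair$registered)
  sc <- segment_crop(enh, config)
  out <- paired_sample(
    with_pixels(sc$pair$source,
                normalize_unit(pad_to(sc$pair$source$pixels,
                                      config$pad_size))),
    with_pixels(sc$pair$target,
                normalize_unit(pad_to(sc$pair$target$pixels,
                                      config$pad_size))),
    sample_id = pair$sample_id, registered = pair$registered)
  attr(out, "crop_box") <- sc$box
  out
}
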