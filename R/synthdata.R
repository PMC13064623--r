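#' Configuration of the synthetic cilium phantom generator
#'
#' The phantom generator emulates the statistical structure of co-registered
#' confocal / STED / deconvolved-STED acquisitions of ciliary-membrane
#' labels: thin curvilinear emitters imaged through point-spread functions
#' of decreasing width (confocal widest, deconvolved STED narrowest) with
#' scaled-Poisson shot noise and Gaussian read noise. Degraded low-quality
#' variants add scan-order photobleaching, labeling gaps and extra noise.
#'
#' @param size_px Image side length in pixels (default 128).
#' @param n_structures Integer range (length-2) of curves per phantom.
#' @param curve_thickness_px Cross-section FWHM of the emitter curves.
#' @param sigma_sted_px,sigma_conf_px,sigma_dsted_px Gaussian PSF sigmas per
#'   modality; must order dsted < sted < confocal.
#' @param photon_scale_sted,photon_scale_conf,photon_scale_dsted Photons per
#'   unit intensity; lower means stronger shot noise. `Inf` disables it.
#' @param read_noise_sd Gaussian read noise (intensity units).
#' @param bleach_rate Per-scan-line bleaching rate for low-quality variants.
#' @param gap_fraction Fraction of emitter support lost to labeling gaps.
#' @param extra_noise_sd Extra noise for low-quality variants.
#' @param seed Master seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(size_px = 128L, n_structures = c(1L, 3L),
                           curve_thickness_px = 2.5, sigma_sted_px = 1.0,
                           sigma_conf_px = 4.0, sigma_dsted_px = 0.7,
                           photon_scale_sted = 300, photon_scale_conf = 100,
                           photon_scale_dsted = 800, read_noise_sd = 0.01,
                           bleach_rate = 0.01, gap_fraction = 0.2,
                           extra_noise_sd = 0.05, seed = 1L) {
  if (length(n_structures) == 1) n_structures <- rep(n_structures, 2)
  stopifnot(size_px >= 16, curve_thickness_px > 0,
            sigma_dsted_px < sigma_sted_px, sigma_sted_px < sigma_conf_px,
            photon_scale_sted > 0, photon_scale_conf > 0,
            photon_scale_dsted > 0, read_noise_sd >= 0, bleach_rate >= 0,
            gap_fraction >= 0, gap_fraction < 1)
  structure(list(size_px = as.integer(size_px),
                 n_structures = as.integer(n_structures),
                 curve_thickness_px = curve_thickness_px,
                 sigma_sted_px = sigma_sted_px, sigma_conf_px = sigma_conf_px,
                 sigma_dsted_px = sigma_dsted_px,
                 photon_scale_sted = photon_scale_sted,
                 photon_scale_conf = photon_scale_conf,
                 photon_scale_dsted = photon_scale_dsted,
                 read_noise_sd = read_noise_sd, bleach_rate = bleach_rate,
                 gap_fraction = gap_fraction,
                 extra_noise_sd = extra_noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

reflect_pad <- function(m, r) {
  top <- m[r:1, , drop = FALSE]
  bot <- m[nrow(m):(nrow(m) - r + 1), , drop = FALSE]
  m <- rbind(top, m, bot)
  left <- m[, r:1, drop = FALSE]
  right <- m[, ncol(m):(ncol(m) - r + 1), drop = FALSE]
  cbind(left, m, right)
}

# Separable Gaussian blur with reflective boundary (no dark frame at tile
# edges); conserves total intensity up to boundary reflection.
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  p <- reflect_pad(m, r)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W + 2 * r)
  for (i in seq_along(k))
    out <- out + k[i] * p[(i):(i + H - 1L), , drop = FALSE]
  res <- matrix(0, H, W)
  for (i in seq_along(k))
    res <- res + k[i] * out[, (i):(i + W - 1L), drop = FALSE]
  res
}

#' Generate a ground-truth emitter map of curvilinear structures
#'
#' Draws `n_structures` smooth random tracks (spline interpolation through
#' random control points), rasterizes them at constant linear density and
#' applies a Gaussian cross-section, so total emitter mass grows linearly
#' with total curve length. Deterministic given `seed`.
#'
#' @param config A [phantom_config()].
#' @param seed Seed for this map (defaults to `config$seed`).
#' @return A nonnegative `size_px` x `size_px` matrix with attribute
#'   `"curve_length_px"`.
#' @export
generate_emitters <- function(config, seed = config$seed) {
  seed_all(seed)
  n <- config$size_px
  grid <- matrix(0, n, n)
  ns <- if (config$n_structures[1] == config$n_structures[2])
    config$n_structures[1]
  else sample(config$n_structures[1]:config$n_structures[2], 1)
  total_len <- 0
  if (ns > 0) {
    for (s in seq_len(ns)) {
      m <- sample(4:6, 1)
      cr <- runif(m, 0.15 * n, 0.85 * n)
      cc <- runif(m, 0.15 * n, 0.85 * n)
      t0 <- seq_len(m)
      fr <- splinefun(t0, cr, method = "natural")
      fc <- splinefun(t0, cc, method = "natural")
      tt <- seq(1, m, length.out = 40 * m)
      r <- fr(tt); c <- fc(tt)
      seg <- sqrt(diff(r)^2 + diff(c)^2)
      total_len <- total_len + sum(seg)
      # resample to constant arc-length spacing for uniform linear density
      arc <- c(0, cumsum(seg))
      step <- 0.25
      si <- seq(0, arc[length(arc)], by = step)
      rr <- approx(arc, r, xout = si)$y
      cc2 <- approx(arc, c, xout = si)$y
      ri <- round(rr) + 1L
      ci <- round(cc2) + 1L
      ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
      for (j in which(ok)) grid[ri[j], ci[j]] <- grid[ri[j], ci[j]] + step
    }
    sigma_cross <- config$curve_thickness_px / 2.355  # FWHM -> sigma
    grid <- blur_gaussian(grid, sigma_cross)
  }
  structure(grid, curve_length_px = total_len)
}

#' Render an emitter map through a microscope forward model
#'
#' Image = Poisson(photon_scale x (emitters convolved with a unit-sum
#' Gaussian PSF)) / photon_scale + Gaussian read noise, with reflective
#' boundary handling. `photon_scale = Inf` with zero read noise gives the
#' noiseless render, which conserves total intensity.
#'
#' @param emitters Nonnegative matrix.
#' @param psf_sigma_px PSF standard deviation in pixels (> 0).
#' @param photon_scale Photons per intensity unit (`Inf` = no shot noise).
#' @param read_noise_sd Gaussian read noise sd (0 = none).
#' @param seed Seed for the noise draw.
#' @param modality,quality Metadata for the returned [micro_image()].
#' @return A [micro_image()].
#' @export
render_modality <- function(emitters, psf_sigma_px, photon_scale = Inf,
                            read_noise_sd = 0, seed = 1L,
                            modality = "unknown", quality = "high") {
  stopifnot(psf_sigma_px > 0)
  if (photon_scale <= 0) stop("photon_scale must be positive")
  blurred <- blur_gaussian(unclass_mat(emitters), psf_sigma_px)
  seed_all(seed)
  px <- if (is.finite(photon_scale)) {
    matrix(rpois(length(blurred), photon_scale * pmax(blurred, 0)),
           nrow(blurred)) / photon_scale
  } else blurred
  if (read_noise_sd > 0)
    px <- px + matrix(rnorm(length(px), sd = read_noise_sd), nrow(px))
  micro_image(px, modality = modality, quality = quality)
}

unclass_mat <- function(x) {
  x <- if (inherits(x, "micro_image")) x$pixels else x
  attributes(x) <- list(dim = dim(x))
  x
}

#' Degrade an image to emulate sub-optimal acquisition
#'
#' Row r is attenuated by exp(-bleach_rate * r) (scan-order
#' photobleaching), a random fraction of the emitter support is masked
#' (labeling gaps), extra Gaussian noise is added, and the result is
#' clipped back to \[0, 1\] and tagged low quality. With all three
#' magnitudes zero this is the identity.
#'
#' @param img [micro_image()] or matrix in \[0, 1\].
#' @param bleach_rate Per-line bleaching rate (>= 0).
#' @param gap_fraction Fraction in \[0, 1) of support pixels masked.
#' @param extra_noise_sd Gaussian noise sd (>= 0).
#' @param seed Seed.
#' @return A low-quality [micro_image()].
#' @export
degrade_low_quality <- function(img, bleach_rate = 0.01, gap_fraction = 0.2,
                                extra_noise_sd = 0.05, seed = 1L) {
  if (gap_fraction >= 1) stop("gap_fraction must be < 1")
  px <- as_pixels(img)
  if (min(px) < -1e-9 || max(px) > 1 + 1e-9)
    stop("degrade_low_quality expects an image normalized to [0, 1]")
  seed_all(seed)
  if (bleach_rate > 0)
    px <- px * exp(-bleach_rate * (seq_len(nrow(px)) - 1))
  if (gap_fraction > 0) {
    support <- which(px > 0.1 * max(px))
    if (length(support) > 0) {
      drop <- sample(support, floor(gap_fraction * length(support)))
      px[drop] <- 0
    }
  }
  if (extra_noise_sd > 0) {
    px <- px + matrix(rnorm(length(px), sd = extra_noise_sd), nrow(px))
    px <- pmin(pmax(px, 0), 1)
  }
  out <- micro_image(px, quality = "low",
                     modality = if (inherits(img, "micro_image"))
                       img$modality else "unknown",
                     id = if (inherits(img, "micro_image")) img$id else "")
  out
}

#' Generate a full phantom: one emitter map, all renderings
#'
#' @param config A [phantom_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @param low_quality Also render degraded low-quality STED/dSTED variants.
#' @return An object of class `phantom` with `emitters`, `renderings`
#'   (named list of [micro_image()]s) and `config_echo`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = config$seed,
                             low_quality = FALSE) {
  em <- generate_emitters(config, seed)
  rend <- list(
    confocal = render_modality(em, config$sigma_conf_px,
                               config$photon_scale_conf,
                               config$read_noise_sd, seed + 1L, "confocal"),
    sted = render_modality(em, config$sigma_sted_px,
                           config$photon_scale_sted,
                           config$read_noise_sd, seed + 2L, "sted"),
    dsted = render_modality(em, config$sigma_dsted_px,
                            config$photon_scale_dsted,
                            config$read_noise_sd, seed + 3L, "dsted"))
  if (low_quality) {
    rend$sted_low <- degrade_low_quality(normalize_unit(rend$sted),
                                         config$bleach_rate,
                                         config$gap_fraction,
                                         config$extra_noise_sd, seed + 4L)
    rend$dsted_low <- degrade_low_quality(normalize_unit(rend$dsted),
                                          config$bleach_rate,
                                          config$gap_fraction,
                                          config$extra_noise_sd, seed + 5L)
  }
  structure(list(emitters = em, renderings = rend, config_echo = config),
            class = "phantom")
}

#' Generate a dataset of co-registered phantom pairs
#'
#' Each sample is one emitter map rendered as confocal (source) and as
#' `target` (STED or deconvolved STED). Per-sample seeds are derived from
#' the master seed, so the whole dataset reproduces from `config$seed`.
#'
#' @param n_samples Number of pairs (>= 1).
#' @param config A [phantom_config()].
#' @param target `"sted"` or `"dsted"`.
#' @param normalize Normalize both images of each pair to \[0, 1\]
#'   (default TRUE; the training loaders expect unit range).
#' @return An [image_dataset()].
#' @export
generate_dataset <- function(n_samples, config = phantom_config(),
                             target = c("sted", "dsted"), normalize = TRUE) {
  target <- match.arg(target)
  stopifnot(n_samples >= 1)
  samples <- lapply(seq_len(n_samples), function(i) {
    s <- (config$seed * 1000L + i * 7L) %% .Machine$integer.max
    ph <- generate_phantom(config, seed = s)
    src <- ph$renderings$confocal
    tgt <- ph$renderings[[target]]
    if (normalize) {
      src <- normalize_unit(src)
      tgt <- normalize_unit(tgt)
    }
    id <- sprintf("sample_%04d", i)
    src$id <- paste0(id, "_confocal")
    tgt$id <- paste0(id, "_", target)
    p <- paired_sample(src, tgt, sample_id = id)
    attr(p, "seed") <- s
    p
  })
  image_dataset(samples)
}

#' Write a dataset as TIFFs plus a JSON manifest
#'
#' @param dataset An [image_dataset()].
#' @param dir Output directory (created if needed).
#' @param config Optional [phantom_config()] echoed into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(dataset$samples, function(p) {
    sf <- paste0(p$source$id, ".tif")
    tf <- paste0(p$target$id, ".tif")
    write_image(p$source, file.path(dir, sf))
    write_image(p$target, file.path(dir, tf))
    list(sample_id = p$sample_id, source = sf, target = tf,
         source_modality = p$source$modality,
         target_modality = p$target$modality, registered = p$registered,
         seed = attr(p, "seed"))
  })
  manifest <- list(n_samples = length(dataset$samples), samples = entries,
                   config = if (!is.null(config)) unclass(config))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing TIFFs and `manifest.json`.
#' @return An [image_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  samples <- lapply(manifest$samples, function(e) {
    src <- read_image(file.path(dir, e$source), modality = e$source_modality)
    tgt <- read_image(file.path(dir, e$target), modality = e$target_modality)
    paired_sample(src, tgt, sample_id = e$sample_id,
                  registered = isTRUE(e$registered))
  })
  image_dataset(samples)
}
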