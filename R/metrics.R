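# Reference and non-reference image-quality metrics. All reference metrics
# take images on a common intensity scale (normally [0, 1]); FRC operates
# in the Fourier domain on square images.

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03, sample-covariance normalization and the mean taken over the
#' valid (fully-windowed) region.
#'
#' @param a,b Matrices or [micro_image()]s of identical shape.
#' @param data_range Dynamic range of the data (1 for unit-normalized
#'   images).
#' @return Scalar in \[-1, 1\]; exactly 1 for identical images.
#' @export
ssim <- function(a, b, data_range = 1) {
  a <- as_pixels(a); b <- as_pixels(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch in ssim")
  stopifnot(data_range > 0)
  win <- 11L
  g <- gaussian_kernel_1d(1.5, radius = 5L)
  kern <- outer(g, g)
  filt <- function(m) conv_valid(m, kern)
  np <- win^2
  cov_norm <- np / (np - 1)
  ux <- filt(a); uy <- filt(b)
  uxx <- filt(a * a); uyy <- filt(b * b); uxy <- filt(a * b)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

conv_valid <- function(m, kern) {
  x <- array(m, dim = c(dim(m), 1L))
  W <- matrix(as.numeric(kern), nrow = 1)
  y <- conv2d_fwd(x, W, nrow(kern), 1L, 0L)
  matrix(y[, , 1], nrow = dim(y)[1])
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(data_range^2 / MSE)`; identical images give `+Inf`.
#'
#' @inheritParams ssim
#' @return Scalar PSNR in dB (possibly `Inf`).
#' @export
psnr_db <- function(a, b, data_range = 1) {
  a <- as_pixels(a); b <- as_pixels(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch in psnr_db")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Normalized PSNR
#'
#' Maps PSNR into \[0, 1\] as `min(psnr / cap_db, 1)`, with the identity
#' comparison (infinite PSNR) at 1 by convention, so a self-comparison
#' plots at the (1.0, 1.0) reference point alongside SSIM.
#'
#' @param psnr PSNR in dB (may be `Inf`).
#' @param cap_db Cap in dB (default 40).
#' @return Scalar in \[0, 1\].
#' @export
npsnr <- function(psnr, cap_db = 40) {
  stopifnot(cap_db > 0)
  if (is.infinite(psnr)) return(1)
  min(max(psnr / cap_db, 0), 1)
}

#' Fourier ring correlation between two images
#'
#' Per-ring normalized cross-correlation of the two Fourier transforms over
#' 1-pixel-wide frequency rings up to Nyquist (0.5 cycles/pixel). A Hann
#' window (default on) suppresses spectral leakage from the tile edges.
#'
#' @param a,b Square matrices or [micro_image()]s of identical shape.
#' @param apodize Apply a Hann window before transforming.
#' @return An object of class `frc_curve` with `ring_freqs`,
#'   `correlations` and `ring_counts`.
#' @export
frc <- function(a, b, apodize = TRUE) {
  a <- as_pixels(a); b <- as_pixels(b)
  if (!identical(dim(a), dim(b))) stop("frc requires identical shapes")
  n <- nrow(a)
  if (n != ncol(a)) stop("frc requires square images")
  if (apodize) {
    h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    w <- outer(h, h)
    a <- a * w
    b <- b * w
  }
  fa <- fft(a)
  fb <- fft(b)
  ki <- ifelse(seq_len(n) - 1 <= n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  kr <- sqrt(outer(ki^2, ki^2, "+"))
  ring <- round(kr)
  rmax <- floor(n / 2)
  num <- Re(fa * Conj(fb))
  d1 <- Mod(fa)^2
  d2 <- Mod(fb)^2
  idx <- ring >= 1 & ring <= rmax
  rr <- factor(ring[idx], levels = seq_len(rmax))
  s_num <- tapply(num[idx], rr, sum, default = 0)
  s_d1 <- tapply(d1[idx], rr, sum, default = 0)
  s_d2 <- tapply(d2[idx], rr, sum, default = 0)
  cnt <- tabulate(ring[idx], rmax)
  corr <- as.numeric(s_num) / sqrt(pmax(as.numeric(s_d1) * as.numeric(s_d2),
                                        .Machine$double.xmin))
  corr <- pmin(pmax(corr, -1), 1)
  structure(list(ring_freqs = seq_len(rmax) / n, correlations = corr,
                 ring_counts = cnt), class = "frc_curve")
}

#' High-frequency disagreement (1 - FRC) over the upper band
#'
#' One minus the mean ring correlation over frequencies at or above
#' `band_lo_frac` of Nyquist, clipped to \[0, 1\]. Identical images give 0
#' (the ground-truth convention).
#'
#' @param curve An [frc()] curve.
#' @param band_lo_frac Lower edge of the band as a fraction of Nyquist
#'   (default 0.5: the upper half).
#' @return Scalar in \[0, 1\].
#' @export
hf_disagreement <- function(curve, band_lo_frac = 0.5) {
  stopifnot(inherits(curve, "frc_curve"), band_lo_frac > 0, band_lo_frac < 1)
  band <- curve$ring_freqs >= band_lo_frac * 0.5
  if (!any(band)) stop("empty high-frequency band")
  min(max(1 - mean(curve$correlations[band]), 0), 1)
}

#' FRC-based resolution estimate
#'
#' First frequency where the (lightly smoothed) curve crosses below the
#' fixed threshold (default 1/7), linearly interpolated between rings;
#' resolution is its reciprocal in pixels. A curve that never crosses is
#' Nyquist-limited: resolution 2 px with attribute `"nyquist_limited"`.
#'
#' @param curve An [frc()] curve.
#' @param threshold Fixed threshold (default 1/7).
#' @param smooth_k Running-mean window in rings (1 = no smoothing).
#' @return Resolution in pixels (>= 2).
#' @export
frc_resolution <- function(curve, threshold = 1 / 7, smooth_k = 3L) {
  stopifnot(inherits(curve, "frc_curve"))
  co <- curve$correlations
  f <- curve$ring_freqs
  if (length(co) < 2) stop("degenerate FRC curve")
  if (smooth_k > 1) {
    half <- (smooth_k - 1) %/% 2
    co <- vapply(seq_along(co), function(i) {
      mean(co[max(1, i - half):min(length(co), i + half)])
    }, numeric(1))
  }
  below <- which(co < threshold)
  if (length(below) == 0)
    return(structure(2, nyquist_limited = TRUE))
  i <- below[1]
  if (i == 1) return(structure(1 / f[1], nyquist_limited = FALSE))
  fstar <- f[i - 1] + (co[i - 1] - threshold) / (co[i - 1] - co[i]) *
    (f[i] - f[i - 1])
  structure(max(1 / fstar, 2), nyquist_limited = FALSE)
}

#' Sample an intensity profile along a line
#'
#' Bilinear interpolation at `n_samples` equispaced points between two
#' (row, col) endpoints in 0-based pixel coordinates.
#'
#' @param img [micro_image()] or matrix.
#' @param p0,p1 Numeric (row, col) endpoints inside the image.
#' @param n_samples Number of samples.
#' @return An object of class `line_profile` with `endpoints`, `n_samples`
#'   and `intensities`.
#' @export
line_profile <- function(img, p0, p1, n_samples = 100L) {
  px <- as_pixels(img)
  H <- nrow(px); W <- ncol(px)
  chk <- function(p) {
    if (p[1] < 0 || p[1] > H - 1 || p[2] < 0 || p[2] > W - 1)
      stop("line endpoints must lie inside the image")
  }
  chk(p0); chk(p1)
  t <- seq(0, 1, length.out = n_samples)
  r <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  r0 <- pmin(floor(r), H - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(cc), W - 2); c0 <- pmax(c0, 0)
  fr <- r - r0
  fc <- cc - c0
  v <- (1 - fr) * (1 - fc) * px[cbind(r0 + 1, c0 + 1)] +
    fr * (1 - fc) * px[cbind(r0 + 2, c0 + 1)] +
    (1 - fr) * fc * px[cbind(r0 + 1, c0 + 2)] +
    fr * fc * px[cbind(r0 + 2, c0 + 2)]
  structure(list(endpoints = list(p0 = p0, p1 = p1),
                 n_samples = as.integer(n_samples), intensities = v),
            class = "line_profile")
}

#' Pearson correlation of two sequences
#'
#' @param a,b Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Pearson r.
#' @export
pearson <- function(a, b) {
  if (inherits(a, "line_profile")) a <- a$intensities
  if (inherits(b, "line_profile")) b <- b$intensities
  if (length(a) != length(b) || length(a) < 3)
    stop("pearson requires equal lengths >= 3")
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance in pearson input")
  cor(a, b)
}

#' Non-reference signal-to-noise ratio
#'
#' Otsu split into foreground/background;
#' SNR = (mean_fg - mean_bg) / sd_bg.
#'
#' @param img [micro_image()] or matrix in \[0, 1\].
#' @return Scalar SNR.
#' @export
snr_nonref <- function(img) {
  px <- as_pixels(img)
  thr <- otsu_threshold(pmin(pmax(px, 0), 1))
  fg <- px > thr
  if (!any(fg) || all(fg)) stop("degenerate Otsu split: no foreground")
  sb <- sd(px[!fg])
  if (sb == 0) stop("zero background variance")
  (mean(px[fg]) - mean(px[!fg])) / sb
}

#' Edge-preservation (sharpness) score
#'
#' Variance of the Laplacian response on the image rescaled to \[0, 255\]
#' (the variance-of-Laplacian sharpness proxy); `"tenengrad"` uses Sobel
#' gradient energy instead.
#'
#' @param img [micro_image()] or matrix in \[0, 1\].
#' @param method `"laplacian"` (default) or `"tenengrad"`.
#' @return Nonnegative scalar; 0 for a constant image.
#' @export
edge_preservation <- function(img, method = c("laplacian", "tenengrad")) {
  method <- match.arg(method)
  px <- as_pixels(img) * 255
  if (method == "laplacian") {
    kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
    r <- conv_valid(px, kern)
    v <- mean((r - mean(r))^2)
  } else {
    sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
    gx <- conv_valid(px, sx)
    gy <- conv_valid(px, t(sx))
    v <- mean(gx^2 + gy^2)
  }
  v
}

#' Deviation map between a generated and an observed image
#'
#' Pixel-wise absolute difference plus its mean as a scalar anomaly score;
#' large scores flag acquisitions that deviate from what a generator
#' trained on high-quality data predicts.
#'
#' @param generated,observed Images in \[0, 1\] of identical shape.
#' @return List with `map` (matrix) and `score` (mean absolute deviation).
#' @export
deviation_map <- function(generated, observed) {
  a <- as_pixels(generated); b <- as_pixels(observed)
  if (!identical(dim(a), dim(b))) stop("shape mismatch in deviation_map")
  m <- abs(a - b)
  list(map = m, score = mean(m))
}

#' Full per-image metric report
#'
#' @param candidate,reference Images in \[0, 1\] of identical square shape.
#' @param cap_db Normalized-PSNR cap.
#' @return A one-row tibble: ssim, psnr_db, npsnr, frc_resolution_px,
#'   hf_disagreement.
#' @export
metric_report <- function(candidate, reference, cap_db = 40) {
  p <- psnr_db(candidate, reference)
  curve <- frc(candidate, reference)
  tibble::tibble(ssim = ssim(candidate, reference),
                 psnr_db = p, npsnr = npsnr(p, cap_db),
                 frc_resolution_px = as.numeric(frc_resolution(curve)),
                 hf_disagreement = hf_disagreement(curve))
}
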