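test_that("ssim matches identity, constants and a reference implementation", {
  a <- sinusoid_image()
  b <- sinusoid_image(shift = 1)
  cc <- sinusoid_variant()
  expect_equal(ssim(a, a), 1.0)
  # constants 0 vs 1 on unit range: closed form C1 / (1 + C1)
  C1 <- 0.01^2
  expect_lt(abs(ssim(matrix(0, 32, 32), matrix(1, 32, 32)) - C1 / (1 + C1)),
            1e-12)
  # frozen values from an independent reference implementation
  # (scikit-image structural_similarity, Gaussian weights, sigma 1.5,
  # win_size 11, sample covariance) on the deterministic sinusoid fixtures
  expect_lt(abs(ssim(a, b) - 0.979249921322), 1e-6)
  expect_lt(abs(ssim(a, cc) - 0.895600334256), 1e-6)
  expect_lt(abs(ssim(b, cc) - 0.879739907509), 1e-6)
  expect_error(ssim(a, matrix(0, 2, 2)), "mismatch")
})

test_that("psnr matches its closed form and degrades with noise", {
  a <- sinusoid_image()
  expect_identical(psnr_db(a, a), Inf)
  # MSE of 0.01 on unit range is exactly 20 dB
  b <- a * 0
  b[] <- 0.1
  expect_lt(abs(psnr_db(matrix(0, 10, 10), matrix(0.1, 10, 10)) - 20), 1e-10)
  # frozen reference values (skimage peak_signal_noise_ratio)
  expect_lt(abs(psnr_db(a, sinusoid_image(shift = 1)) - 29.001496419793),
            1e-6)
  set.seed(6)
  ps <- vapply(c(0.01, 0.05, 0.1), function(s) {
    psnr_db(pmin(pmax(a + matrix(rnorm(length(a), sd = s), nrow(a)), 0), 1), a)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("normalized psnr caps, clips and honours the identity convention", {
  expect_equal(npsnr(Inf), 1)
  expect_equal(npsnr(20, 40), 0.5)
  expect_equal(npsnr(60, 40), 1)
  expect_error(npsnr(20, 0), "cap_db")
})

test_that("frc is 1 on identity, symmetric, and near zero for noise", {
  a <- sinusoid_image()
  cv <- frc(a, a)
  expect_lt(max(abs(cv$correlations - 1)), 1e-10)
  expect_equal(length(cv$ring_freqs), 32)
  expect_lte(max(cv$ring_freqs), 0.5)
  expect_true(all(diff(cv$ring_freqs) > 0))
  b <- sinusoid_variant()
  expect_equal(frc(a, b)$correlations, frc(b, a)$correlations,
               tolerance = 1e-12)
  seed_all(77)
  n1 <- matrix(rnorm(128 * 128), 128)
  n2 <- matrix(rnorm(128 * 128), 128)
  nc <- frc(n1, n2)$correlations
  expect_lt(abs(mean(nc)), 0.05)
  expect_error(frc(a, matrix(0, 64, 63)), "identical|square")
})

test_that("high-frequency disagreement averages the upper band", {
  a <- sinusoid_image()
  expect_equal(hf_disagreement(frc(a, a)), 0)
  fake <- structure(list(ring_freqs = seq(0.05, 0.5, by = 0.05),
                         correlations = rep(0, 10),
                         ring_counts = rep(10L, 10)), class = "frc_curve")
  expect_equal(hf_disagreement(fake), 1)
  fake$correlations <- seq(1, 0.1, length.out = 10)
  band <- fake$ring_freqs >= 0.25
  expect_equal(hf_disagreement(fake), 1 - mean(fake$correlations[band]))
})

test_that("frc resolution interpolates the threshold crossing", {
  a <- sinusoid_image()
  r <- frc_resolution(frc(a, a))
  expect_equal(as.numeric(r), 2)
  expect_true(attr(r, "nyquist_limited"))
  # hand-interpolated crossing between rings (0.20, 0.18) and (0.22, 0.12)
  curve <- structure(list(ring_freqs = c(0.18, 0.20, 0.22),
                          correlations = c(0.30, 0.18, 0.12),
                          ring_counts = rep(20L, 3)), class = "frc_curve")
  r2 <- frc_resolution(curve, threshold = 1 / 7, smooth_k = 1L)
  fstar <- 0.20 + (0.18 - 1 / 7) / (0.18 - 0.12) * 0.02
  expect_lt(abs(as.numeric(r2) - 1 / fstar), 1e-10)
  expect_lt(abs(as.numeric(r2) - 4.71), 0.01)
})

test_that("noisier, blurrier renders give coarser FRC resolution", {
  cfg <- phantom_config(size_px = 64, seed = 42)
  em <- generate_emitters(cfg, seed = 42)
  truth <- render_modality(em, cfg$sigma_dsted_px, Inf, 0)$pixels
  res_at <- function(sigma) {
    img <- render_modality(em, sigma, photon_scale = 150,
                           read_noise_sd = 0.01, seed = 7)$pixels
    as.numeric(frc_resolution(frc(normalize_unit(img),
                                  normalize_unit(truth))))
  }
  expect_lt(res_at(1), res_at(4))
})

test_that("line profiles interpolate bilinearly", {
  px <- matrix(runif(400), 20)
  lp <- line_profile(px, c(10, 0), c(10, 19), n_samples = 20)
  expect_equal(lp$intensities, px[11, ])
  cst <- line_profile(matrix(3, 10, 10), c(0, 0), c(9, 9), 15)
  expect_all_close(cst$intensities, rep(3, 15), 1e-12)
  ramp <- outer(0:19, 0:19, function(i, j) 2 * i + 3 * j)
  diag <- line_profile(ramp, c(0, 0), c(19, 19), 10)
  tt <- seq(0, 19, length.out = 10)
  expect_all_close(diag$intensities, 2 * tt + 3 * tt, 1e-10)
  expect_error(line_profile(px, c(-1, 0), c(5, 5)), "inside")
})

test_that("pearson matches the manual formula and guards degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 7)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), manual)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(x, rep(1, 5)), "variance")
  expect_error(pearson(1:2, 1:2), "lengths")
})

test_that("non-reference SNR recovers a constructed ratio", {
  seed_all(33)
  img <- matrix(rnorm(64 * 64, mean = 0.1, sd = 0.02), 64)
  img[20:40, 20:40] <- rnorm(21 * 21, mean = 0.3, sd = 0.02)
  img <- pmin(pmax(img, 0), 1)
  snr <- snr_nonref(img)
  expect_gt(snr, 7)
  expect_lt(snr, 13)
  noisier <- pmin(pmax(img + matrix(rnorm(64 * 64, sd = 0.04), 64), 0), 1)
  expect_lt(snr_nonref(noisier), snr)
  expect_error(snr_nonref(matrix(0.5, 8, 8)), "foreground|variance")
})

test_that("edge preservation decreases monotonically with blur", {
  expect_equal(edge_preservation(matrix(0.4, 32, 32)), 0)
  cfg <- phantom_config(size_px = 64, seed = 12)
  em <- generate_emitters(cfg, seed = 12)
  base <- normalize_unit(render_modality(em, 0.5, Inf, 0)$pixels)
  scores <- vapply(c(0.5, 1, 2, 4), function(s)
    edge_preservation(normalize_unit(render_modality(em, s, Inf, 0)$pixels)),
    numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("deviation maps flag disagreement", {
  a <- sinusoid_image()
  d0 <- deviation_map(a, a)
  expect_equal(d0$score, 0)
  expect_true(all(d0$map == 0))
  d1 <- deviation_map(matrix(0, 8, 8), matrix(1, 8, 8))
  expect_equal(d1$score, 1)
  expect_error(deviation_map(a, matrix(0, 2, 2)), "mismatch")
})

test_that("tidiers expose curves and reports as tibbles", {
  a <- sinusoid_image()
  cv <- frc(a, sinusoid_variant())
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("freq", "correlation", "n_samples"))
  expect_s3_class(autoplot(cv), "ggplot")
  rep1 <- metric_report(a, sinusoid_variant())
  expect_s3_class(rep1, "tbl_df")
  expect_named(rep1, c("ssim", "psnr_db", "npsnr", "frc_resolution_px",
                       "hf_disagreement"))
})
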