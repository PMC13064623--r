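test_that("k-fold splits partition with balanced sizes", {
  f <- kfold_split(256, 5, seed = 1)
  expect_length(f, 256)
  expect_equal(sort(unique(f)), 0:4)
  expect_setequal(as.vector(table(f)), c(52, 51, 51, 51, 51))
  # leave-one-out
  f5 <- kfold_split(5, 5, seed = 2)
  expect_setequal(f5, 0:4)
  expect_error(kfold_split(3, 5), "at least")
  # deterministic given seed
  expect_identical(kfold_split(50, 5, seed = 9), kfold_split(50, 5, seed = 9))
  ds <- tiny_dataset(5, 32, seed = 21)
  dsf <- assign_folds(ds, k = 5, seed = 3)
  expect_setequal(names(dsf$fold_of),
                  vapply(ds$samples, function(s) s$sample_id, character(1)))
})

test_that("evaluation scores the identity translator at the reference point", {
  px <- normalize_unit(sinusoid_image())
  pairs <- lapply(1:3, function(i)
    paired_sample(micro_image(px), micro_image(px), paste0("s", i)))
  fr <- evaluate_model(identity, pairs, fold_index = 2L)
  expect_equal(nrow(fr$per_image), 3)
  expect_true(all(fr$per_image$ssim == 1))
  expect_true(all(fr$per_image$npsnr == 1))
  expect_true(all(fr$per_image$fold == 2L))
  # baseline columns reproduce direct metric calls
  ds <- tiny_dataset(3, 32, seed = 41)
  fr2 <- evaluate_model(NULL, ds$samples)
  p <- ds$samples[[2]]
  expect_equal(fr2$per_image$baseline_ssim[2],
               ssim(p$source$pixels, p$target$pixels))
  expect_equal(fr2$per_image$baseline_psnr_db[2],
               psnr_db(p$source$pixels, p$target$pixels))
  expect_error(evaluate_model(NULL, list()), "empty")
})

test_that("rm_anova matches aov and handles degenerate designs", {
  # identical columns: degenerate, F = 0, p = 1
  m0 <- matrix(rep(rnorm(10), 4), 10, 4)
  r0 <- rm_anova(m0)
  expect_true(r0$degenerate)
  expect_equal(r0$f_stat, 0)
  expect_equal(r0$p_value, 1)
  # perfectly consistent offset: F -> Inf, p -> 0
  m1 <- m0
  m1[, 2] <- m1[, 2] + 1
  r1 <- rm_anova(m1)
  expect_equal(r1$f_stat, Inf)
  expect_equal(r1$p_value, 0)
  # random designs against the base-R within-subjects ANOVA
  set.seed(14)
  for (rep in 1:10) {
    mat <- matrix(rnorm(8 * 4), 8, 4) + rnorm(8)
    r <- rm_anova(mat)
    df <- data.frame(y = as.vector(mat),
                     subj = factor(rep(1:8, 4)),
                     model = factor(rep(1:4, each = 8)))
    fit <- summary(stats::aov(y ~ model + Error(subj / model), data = df))
    tab <- fit[["Error: subj:model"]][[1]]
    expect_lt(abs(r$f_stat - tab["model", "F value"]), 1e-8)
    expect_lt(abs(r$p_value - tab["model", "Pr(>F)"]), 1e-10)
  }
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2)), "complete|subjects")
})

test_that("holm adjustment reproduces hand-computed examples", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.02, 0.03, 0.04)), c(0.06, 0.06, 0.06))
  expect_equal(holm_adjust(0.03), 0.03)
  set.seed(5)
  p <- runif(12)
  expect_equal(holm_adjust(p), stats::p.adjust(p, "holm"))
  expect_true(all(holm_adjust(p) >= p))
})

test_that("pairwise tests are paired, Holm-corrected and degenerate-safe", {
  set.seed(30)
  mat <- matrix(rnorm(12 * 3), 12, 3)
  colnames(mat) <- c("a", "b", "c")
  mat[, 2] <- mat[, 2] + 2   # strong true difference
  hp <- holm_pairwise(mat)
  expect_equal(dim(hp$p_matrix), c(3L, 3L))
  expect_true(isSymmetric(hp$p_matrix))
  expect_true(all(hp$table$p_holm >= hp$table$p_raw))
  raw_ab <- t.test(mat[, 1] - mat[, 2])$p.value
  expect_equal(hp$raw_matrix["a", "b"], raw_ab)
  # two literally identical models give p = 1
  mat2 <- cbind(m1 = rnorm(10), m2 = 0)
  mat2[, 2] <- mat2[, 1]
  hp2 <- holm_pairwise(mat2)
  expect_equal(hp2$p_matrix[1, 2], 1)
  # model_comparison plumbing
  per <- tibble::tibble(sample_id = rep(paste0("s", 1:10), 2),
                        model = rep(c("m1", "m2"), each = 10),
                        ssim = c(mat2[, 1], mat2[, 2]),
                        psnr_db = rep(rnorm(10), 2))
  cmp <- compare_models(per)
  expect_named(cmp, c("ssim", "psnr_db"))
  expect_equal(cmp$ssim$pairwise$p_matrix[1, 2], 1)
  expect_s3_class(tidy(cmp$ssim), "tbl_df")
  expect_s3_class(glance(cmp$ssim), "tbl_df")
})

test_that("cross-validation visits every sample exactly once", {
  ds <- tiny_dataset(6, 32, seed = 61)
  cfg <- train_config(epochs = 2, checkpoint_every = 2, batch_size = 3,
                      seed = 4)
  cv <- cross_validate(ds, list(tiny = tiny_gen_spec()), cfg,
                       framework = "cyclegan",
                       disc_spec = tiny_disc_spec(), k = 2L)
  expect_equal(sort(unique(cv$pooled$sample_id)),
               sort(vapply(ds$samples, function(s) s$sample_id,
                           character(1))))
  expect_equal(nrow(cv$pooled), 6)
  expect_equal(sum(table(cv$pooled$sample_id) == 1), 6)
  # aggregate mean equals mean of pooled per-image values
  fr <- cv$fold_results$tiny[[1]]
  expect_equal(fr$summary$mean[fr$summary$metric == "ssim"],
               mean(fr$per_image$ssim))
})
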