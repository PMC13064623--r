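test_that("L1 loss matches an element-wise loop oracle", {
  expect_equal(l1_loss(matrix(1, 4, 4), matrix(1, 4, 4)), 0)
  expect_equal(l1_loss(matrix(0, 4, 4), matrix(1, 4, 4)), 1)
  set.seed(4)
  a <- matrix(rnorm(16), 4)
  b <- matrix(rnorm(16), 4)
  acc <- 0
  for (i in 1:4) for (j in 1:4) acc <- acc + abs(a[i, j] - b[i, j])
  expect_lt(abs(l1_loss(a, b) - acc / 16), 1e-12)
  expect_error(l1_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("adversarial losses reproduce their closed forms", {
  half <- matrix(0.5, 4, 4)
  out <- adversarial_loss(half, half, mode = "bce")
  # the two-term log objective at D = 0.5 equals 2 log 0.5 = -1.3863;
  # the discriminator minimizes its negation
  expect_lt(abs(out[["loss_D"]] - (-2 * log(0.5))), 1e-10)
  expect_lt(abs(out[["loss_G"]] - (-log(0.5))), 1e-10)
  # lsgan with perfect discrimination
  perfect <- adversarial_loss(matrix(1, 4, 4), matrix(0, 4, 4),
                              mode = "lsgan")
  expect_equal(perfect[["loss_D"]], 0)
  # patch-size invariance for constant maps
  big <- adversarial_loss(matrix(0.5, 16, 16), matrix(0.5, 16, 16), "bce")
  expect_equal(out, big)
  expect_error(adversarial_loss(matrix(2, 2, 2), matrix(0.5, 2, 2), "bce"),
               "probabilities")
  expect_error(adversarial_loss(half, matrix(0.5, 2, 2)), "shape")
})

test_that("the internal GAN gradients match their losses", {
  set.seed(8)
  s <- array(rnorm(9), dim = c(3, 3, 1))
  for (mode in c("bce", "lsgan")) for (role in c("D", "G")) {
    r <- stedgan:::gan_loss_grad(s, TRUE, role, mode)
    num <- vapply(seq_along(s), function(i) {
      sp <- s; sp[i] <- sp[i] + 1e-6
      sm <- s; sm[i] <- sm[i] - 1e-6
      (stedgan:::gan_loss_grad(sp, TRUE, role, mode)$loss -
         stedgan:::gan_loss_grad(sm, TRUE, role, mode)$loss) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(r$grad - num)), 1e-7)
  }
})

test_that("pix2pix objective composes its terms linearly", {
  seed_all(15)
  G <- zeroed_generator(tiny_gen_spec(), input_size = 32L)
  D <- build_discriminator(discriminator_spec(widths = c(4L, 8L),
                                              conditional = TRUE))
  # targets equal to the generator output make the L1 term exactly zero
  zeros_net <- micro_image(matrix(0, 32, 32))   # net range: tanh(0)
  batch_net <- list(paired_sample(zeros_net, zeros_net, "p1"))
  res <- pix2pix_objective(G, D, batch_net, loss_weights(lambda_l1 = 100))
  expect_equal(res$l1, 0)
  expect_equal(res$total, res$adv_G)
  # lambda scaling: l1 = 0.01 contributes exactly 1.0 at lambda = 100
  batch2 <- list(paired_sample(micro_image(matrix(0, 32, 32)),
                               micro_image(matrix(0.01, 32, 32)), "p2"))
  res2 <- pix2pix_objective(G, D, batch2, loss_weights(lambda_l1 = 100))
  expect_lt(abs(res2$l1 - 0.01), 1e-12)
  expect_lt(abs(res2$total - (res2$adv_G + 1.0)), 1e-12)
  res0 <- pix2pix_objective(G, D, batch2, loss_weights(lambda_l1 = 0))
  expect_equal(res0$total, res0$adv_G)
  expect_error(pix2pix_objective(G, D, list(matrix(0, 32, 32))), "paired")
})

test_that("cycle and identity losses follow their compositions", {
  seed_all(21)
  G <- zeroed_generator()
  F_ <- zeroed_generator()
  zero_batch <- list(array(0, dim = c(32, 32, 1)))
  expect_equal(cycle_loss(G, F_, zero_batch, zero_batch), 0)
  expect_equal(identity_loss(G, F_, zero_batch, zero_batch), 0)
  # random nets vs a direct hand-computed composition
  seed_all(22)
  G2 <- build_generator(tiny_gen_spec(), input_size = 32L)
  F2 <- build_generator(tiny_gen_spec(), input_size = 32L)
  xs <- lapply(1:2, function(i) array(runif(32 * 32) * 2 - 1,
                                      dim = c(32, 32, 1)))
  ys <- lapply(1:2, function(i) array(runif(32 * 32) * 2 - 1,
                                      dim = c(32, 32, 1)))
  direct <- mean(vapply(xs, function(x)
    mean(abs(stedgan:::gen_forward(F2, stedgan:::gen_forward(G2, x)) - x)),
    numeric(1))) +
    mean(vapply(ys, function(y)
      mean(abs(stedgan:::gen_forward(G2, stedgan:::gen_forward(F2, y)) - y)),
      numeric(1)))
  expect_lt(abs(cycle_loss(G2, F2, xs, ys) - direct), 1e-10)
  direct_id <- mean(vapply(ys, function(y)
    mean(abs(stedgan:::gen_forward(G2, y) - y)), numeric(1))) +
    mean(vapply(xs, function(x)
      mean(abs(stedgan:::gen_forward(F2, x) - x)), numeric(1)))
  expect_lt(abs(identity_loss(G2, F2, xs, ys) - direct_id), 1e-10)
})

test_that("the CycleGAN objective is linear in its weights and unpaired", {
  seed_all(23)
  G <- build_generator(tiny_gen_spec(), input_size = 32L)
  F_ <- build_generator(tiny_gen_spec(), input_size = 32L)
  DX <- build_discriminator(tiny_disc_spec())
  DY <- build_discriminator(tiny_disc_spec())
  xs <- lapply(1:3, function(i) array(runif(32 * 32) * 2 - 1,
                                      dim = c(32, 32, 1)))
  ys <- lapply(1:3, function(i) array(runif(32 * 32) * 2 - 1,
                                      dim = c(32, 32, 1)))
  res <- cyclegan_objective(G, F_, DX, DY, xs, ys,
                            loss_weights(lambda_cyc = 10, lambda_id = 5))
  expect_lt(abs(res$total - (res$adv_G + res$adv_F + 10 * res$cycle +
                               5 * res$identity)), 1e-10)
  res0 <- cyclegan_objective(G, F_, DX, DY, xs, ys,
                             loss_weights(lambda_cyc = 0, lambda_id = 0))
  expect_equal(res0$total, res0$adv_G + res0$adv_F)
  # adversarial terms are invariant to shuffling one collection
  shuf <- cyclegan_objective(G, F_, DX, DY, xs, ys[c(3, 1, 2)],
                             loss_weights())
  expect_equal(shuf$adv_G, res$adv_G)
  expect_equal(shuf$adv_F, res$adv_F)
})

test_that("checkpoint cadence follows the epochs/every contract", {
  expect_length(stedgan:::checkpoint_epochs(200, 5), 40)
  expect_length(stedgan:::checkpoint_epochs(10, 5), 2)
  expect_equal(stedgan:::checkpoint_epochs(7, 3), c(3, 6, 7))
  expect_equal(stedgan:::checkpoint_epochs(4, 10), 4)
})

test_that("seed_all makes phantoms and initializations reproducible", {
  cfg <- phantom_config(size_px = 32)
  seed_all(101)
  a <- generate_phantom(cfg, seed = 101)$renderings$sted$pixels
  seed_all(101)
  b <- generate_phantom(cfg, seed = 101)$renderings$sted$pixels
  expect_identical(a, b)
  seed_all(55)
  w1 <- get_weights(build_generator(tiny_gen_spec()))
  seed_all(55)
  w2 <- get_weights(build_generator(tiny_gen_spec()))
  expect_identical(w1, w2)
  seed_all(56)
  w3 <- get_weights(build_generator(tiny_gen_spec()))
  v1 <- unlist(w1)
  v3 <- unlist(w3)
  expect_gte(length(v1), 1000)
  expect_gt(mean(v1 != v3), 0.999)
})

test_that("pix2pix training runs, checkpoints and learns at toy scale", {
  ds <- tiny_dataset(6, 32, seed = 301)
  cfg <- train_config(epochs = 10, checkpoint_every = 5, batch_size = 3,
                      seed = 9, lr_decay_start = 5)
  fit <- train_pix2pix(ds, tiny_gen_spec(), tiny_disc_spec(), cfg)
  expect_length(fit$checkpoints, 2)
  expect_equal(nrow(fit$history), 10)
  expect_true(all(is.finite(fit$history$l1)))
  expect_lt(fit$history$l1[10], fit$history$l1[1])
  # learning-rate decay reached the schedule
  expect_lt(fit$history$lr[10], fit$history$lr[1])
  # determinism: an identical run reproduces the history bit for bit
  fit2 <- train_pix2pix(ds, tiny_gen_spec(), tiny_disc_spec(), cfg)
  expect_identical(fit$history, fit2$history)
  expect_error(train_pix2pix(list(), tiny_gen_spec(), tiny_disc_spec(), cfg),
               "empty")
})

test_that("cyclegan training is deterministic and ignores pairing", {
  ds <- tiny_dataset(6, 32, seed = 302)
  cfg <- train_config(epochs = 6, checkpoint_every = 3, batch_size = 3,
                      seed = 17)
  fit <- train_cyclegan(ds, gen_spec = tiny_gen_spec(),
                        disc_spec = tiny_disc_spec(), config = cfg)
  expect_equal(nrow(fit$history), 6)
  expect_length(fit$checkpoints, 2)
  fit2 <- train_cyclegan(ds, gen_spec = tiny_gen_spec(),
                         disc_spec = tiny_disc_spec(), config = cfg)
  expect_identical(fit$history, fit2$history)
  # unpaired path: shuffled target collection still trains
  xs <- lapply(ds$samples, function(p) p$source)
  ys <- lapply(ds$samples, function(p) p$target)[c(4, 5, 6, 1, 2, 3)]
  fit3 <- train_cyclegan(xs, ys, gen_spec = tiny_gen_spec(),
                         disc_spec = tiny_disc_spec(), config = cfg)
  expect_true(all(is.finite(fit3$history$cycle)))
  expect_lt(fit3$history$cycle[6], fit3$history$cycle[1])
})

test_that("checkpoints written to disk restore into a working network", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(4, 32, seed = 303)
  cfg <- train_config(epochs = 4, checkpoint_every = 2, batch_size = 2,
                      seed = 3)
  fit <- train_pix2pix(ds, tiny_gen_spec(), tiny_disc_spec(), cfg,
                       checkpoint_dir = dir)
  files <- list.files(dir)
  expect_length(grep("^checkpoint_pix2pix", files), 2)
  expect_true(all(c("config.yaml", "history.csv") %in% files))
  state <- readRDS(file.path(dir, grep("epoch004", files, value = TRUE)))
  seed_all(1)
  G <- build_generator(tiny_gen_spec(), input_size = 32L)
  set_weights(G, state$weights$G)
  expect_identical(get_weights(G), get_weights(fit$G))
})
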