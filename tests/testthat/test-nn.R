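# The convolution engine is the package's numerical core: its backward
# passes are validated against central finite differences.

numeric_grad_check <- function(loss_fn, ly, idx, analytic, eps = 1e-5,
                               tol = 1e-5) {
  for (i in idx) {
    w0 <- ly$W[i]
    ly$W[i] <- w0 + eps
    lp <- loss_fn()
    ly$W[i] <- w0 - eps
    lm <- loss_fn()
    ly$W[i] <- w0
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(analytic[i] - num), tol * max(abs(num), 1e-4))
  }
}

test_that("conv and transposed-conv agree with finite differences", {
  seed_all(11)
  x <- array(rnorm(12 * 12 * 3), dim = c(12, 12, 3))
  ly <- stedgan:::layer_conv(3L, 5L, 4L)
  tgt <- array(rnorm(6 * 6 * 5), dim = c(6, 6, 5))
  loss <- function() {
    y <- stedgan:::conv_forward(ly, x)
    mean((y - tgt)^2)
  }
  y <- stedgan:::conv_forward(ly, x)
  stedgan:::zero_grads(list(ly))
  gx <- stedgan:::conv_backward(ly, 2 * (y - tgt) / length(y))
  numeric_grad_check(loss, ly, sample(length(ly$W), 8), ly$gW)
  # input gradient
  for (i in sample(length(x), 4)) {
    v0 <- x[i]
    x[i] <- v0 + 1e-5; lp <- loss()
    x[i] <- v0 - 1e-5; lm <- loss()
    x[i] <- v0
    expect_lt(abs(gx[i] - (lp - lm) / 2e-5), 1e-6)
  }
  lt <- stedgan:::layer_convt(5L, 2L, 4L)
  z <- array(rnorm(6 * 6 * 5), dim = c(6, 6, 5))
  tgt2 <- array(rnorm(12 * 12 * 2), dim = c(12, 12, 2))
  loss2 <- function() {
    mean((stedgan:::convt_forward(lt, z) - tgt2)^2)
  }
  y2 <- stedgan:::convt_forward(lt, z)
  stedgan:::zero_grads(list(lt))
  stedgan:::convt_backward(lt, 2 * (y2 - tgt2) / length(y2))
  numeric_grad_check(loss2, lt, sample(length(lt$W), 8), lt$gW)
})

test_that("whole-network gradients are exact for both skip modes", {
  for (mode in c("add", "concat")) {
    seed_all(29)
    spec <- if (mode == "add") tiny_gen_spec(3L, 3L)
            else generator_spec("doubling", base_width = 2L, depth = 3L,
                                cap_multiplier = 4L, dropout_p = 0)
    G <- build_generator(spec, input_size = 16L)
    x <- array(runif(16 * 16) * 2 - 1, dim = c(16, 16, 1))
    tgt <- array(runif(16 * 16) * 2 - 1, dim = c(16, 16, 1))
    loss <- function() mean((stedgan:::gen_forward(G, x) - tgt)^2)
    y <- stedgan:::gen_forward(G, x)
    stedgan:::zero_grads(stedgan:::net_layers(G))
    gin <- stedgan:::gen_backward(G, 2 * (y - tgt) / length(y))
    for (ly in c(G$enc[c(1, spec$depth)], G$dec[c(1, spec$depth)])) {
      numeric_grad_check(loss, ly, sample(length(ly$W), 4), ly$gW)
    }
    for (i in sample(length(x), 3)) {
      v0 <- x[i]
      x[i] <- v0 + 1e-5; lp <- loss()
      x[i] <- v0 - 1e-5; lm <- loss()
      x[i] <- v0
      expect_lt(abs(gin[i] - (lp - lm) / 2e-5), 1e-6)
    }
  }
})

test_that("discriminator gradients are exact", {
  seed_all(13)
  D <- build_discriminator(tiny_disc_spec())
  x <- array(runif(16 * 16) * 2 - 1, dim = c(16, 16, 1))
  loss <- function() mean((stedgan:::disc_forward(D, x) - 1)^2)
  s <- stedgan:::disc_forward(D, x)
  stedgan:::zero_grads(stedgan:::net_layers(D))
  gx <- stedgan:::disc_backward(D, 2 * (s - 1) / length(s))
  for (ly in D$body) {
    if (is.null(ly$W)) next
    numeric_grad_check(loss, ly, sample(length(ly$W), 4), ly$gW)
  }
  for (i in sample(length(x), 3)) {
    v0 <- x[i]
    x[i] <- v0 + 1e-5; lp <- loss()
    x[i] <- v0 - 1e-5; lm <- loss()
    x[i] <- v0
    expect_lt(abs(gx[i] - (lp - lm) / 2e-5), 1e-6)
  }
})

test_that("parameter counting follows the layer contract", {
  seed_all(1)
  biased <- stedgan:::layer_conv(1L, 1L, 3L, bias = TRUE)
  expect_equal(stedgan:::n_params(biased), 10L)    # 9 weights + 1 bias
  unbiased <- stedgan:::layer_conv(1L, 1L, 3L)
  expect_equal(stedgan:::n_params(unbiased), 9L)
  # 2-level fixed-width-2 toy U-Net against a hand-summed count:
  # enc: 1*2*16 + 2*2*16 ; dec: 2*2*16 (bottleneck up) + 2*1*16 (final)
  net <- build_generator(tiny_gen_spec(2L, 2L), input_size = 16L)
  expect_equal(count_trainable(net), 32L + 64L + 64L + 32L)
})

test_that("instance norm normalizes per channel and backpropagates", {
  seed_all(3)
  ly <- stedgan:::layer_inorm(2L)
  x <- array(rnorm(8 * 8 * 2, mean = 3, sd = 2), dim = c(8, 8, 2))
  y <- stedgan:::inorm_forward(ly, x)
  for (c in 1:2) {
    expect_lt(abs(mean(y[, , c])), 1e-10)
    expect_lt(abs(var(as.vector(y[, , c])) * 63 / 64 - 1), 1e-4)
  }
  tgt <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2))
  loss <- function() mean((stedgan:::inorm_forward(ly, x) - tgt)^2)
  g <- stedgan:::inorm_backward(ly, 2 * (y - tgt) / length(y))
  for (i in sample(length(x), 5)) {
    v0 <- x[i]
    x[i] <- v0 + 1e-6; lp <- loss()
    x[i] <- v0 - 1e-6; lm <- loss()
    x[i] <- v0
    expect_lt(abs(g[i] - (lp - lm) / 2e-6), 1e-5)
  }
})
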