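# Deterministic fixtures shared across test files. The sinusoid images are
# index-based (no RNG) so reference values computed against independent
# implementations stay frozen.

sinusoid_image <- function(n = 64, shift = 0) {
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  0.5 + 0.5 * sin((i + shift) / 7) * cos(j / 5)
}

sinusoid_variant <- function(n = 64) {
  a <- sinusoid_image(n)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  pmin(pmax(a * 0.8 + 0.1 + 0.05 * sin((i * j) / 100), 0), 1)
}

tiny_gen_spec <- function(width = 4L, depth = 3L) {
  generator_spec("fixed", base_width = width, depth = depth,
                 kernel_size = 4L, skip_mode = "add", dropout_p = 0)
}

tiny_disc_spec <- function() discriminator_spec(widths = c(4L, 8L))

# Small paired dataset of blurred-vs-sharp phantoms for smoke training.
tiny_dataset <- function(n = 4, size = 32, seed = 123) {
  generate_dataset(n, phantom_config(size_px = size, seed = seed,
                                     n_structures = c(1L, 1L)))
}

# A generator whose final layer is zeroed: output is exactly tanh(0) = 0.
zeroed_generator <- function(spec = tiny_gen_spec(), input_size = 32L) {
  net <- build_generator(spec, input_size = input_size)
  net$dec[[1]]$W[] <- 0
  net
}

expect_all_close <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
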