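# Layer primitives over the C++ convolution kernels. A layer is a mutable
# environment holding its weights, gradient accumulator and Adam state; a
# forward pass caches whatever its backward pass needs. All feature maps are
# (H, W, C) arrays.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  dots <- list(...)
  for (nm in names(dots)) assign(nm, dots[[nm]], envir = e)
  e
}

# Weight init follows the DCGAN convention: N(0, 0.02). Convolutions are
# bias-free; normalization layers carry no affine parameters, so the
# trainable-parameter count of a network is exactly the sum of its
# convolution weight tensors.
.layer_counter <- new.env(parent = emptyenv())
.layer_counter$n <- 0L

next_layer_id <- function() {
  .layer_counter$n <- .layer_counter$n + 1L
  .layer_counter$n
}

layer_conv <- function(cin, cout, k, s = 2L, p = 1L, init_sd = 0.02,
                       bias = FALSE) {
  W <- matrix(rnorm(cout * cin * k * k, sd = init_sd), nrow = cout)
  new_layer("conv", k = as.integer(k), s = as.integer(s), p = as.integer(p),
            W = W, b = if (bias) numeric(cout), gW = NULL, gb = NULL,
            mW = NULL, vW = NULL, cache = NULL, cid = next_layer_id())
}

layer_convt <- function(cin, cout, k, s = 2L, p = 1L, opad = 0L, init_sd = 0.02) {
  W <- matrix(rnorm(cin * cout * k * k, sd = init_sd), nrow = cin)
  new_layer("convt", k = as.integer(k), s = as.integer(s), p = as.integer(p),
            opad = as.integer(opad), W = W, gW = NULL, mW = NULL, vW = NULL,
            cache = NULL)
}

layer_inorm <- function(c, eps = 1e-5) {
  new_layer("inorm", eps = eps, cache = NULL)
}

conv_forward <- function(ly, x, cache = TRUE) {
  if (cache) ly$cache <- x
  y <- conv2d_fwd(x, ly$W, ly$k, ly$s, ly$p, if (cache) ly$cid else 0L)
  if (!is.null(ly$b)) y <- y + rep(ly$b, each = dim(y)[1] * dim(y)[2])
  y
}

conv_backward <- function(ly, gy) {
  r <- conv2d_bwd(ly$cache, ly$W, gy, ly$k, ly$s, ly$p, ly$cid)
  ly$gW <- if (is.null(ly$gW)) r$gW else ly$gW + r$gW
  if (!is.null(ly$b)) {
    gb <- colSums(matrix(gy, ncol = dim(gy)[3]))
    ly$gb <- if (is.null(ly$gb)) gb else ly$gb + gb
  }
  r$gx
}

convt_forward <- function(ly, x, cache = TRUE) {
  if (cache) ly$cache <- x
  convt2d_fwd(x, ly$W, ly$k, ly$s, ly$p, ly$opad)
}

convt_backward <- function(ly, gy) {
  r <- convt2d_bwd(ly$cache, ly$W, gy, ly$k, ly$s, ly$p)
  ly$gW <- if (is.null(ly$gW)) r$gM else ly$gW + r$gM
  r$gx
}

# Instance normalization (per-channel, per-image), no affine parameters.
inorm_forward <- function(ly, x, cache = TRUE) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, nrow = n)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(v + ly$eps)
  y <- array((xm - rep(mu, each = n)) * rep(istd, each = n), dim = d)
  if (cache) ly$cache <- list(y = y, istd = istd)
  y
}

inorm_backward <- function(ly, gy) {
  d <- dim(gy)
  n <- d[1] * d[2]
  gm <- matrix(gy, nrow = n)
  ym <- matrix(ly$cache$y, nrow = n)
  mg <- colMeans(gm)
  mgy <- colMeans(gm * ym)
  gx <- (gm - rep(mg, each = n) - ym * rep(mgy, each = n)) *
    rep(ly$cache$istd, each = n)
  array(gx, dim = d)
}

lrelu_forward <- function(x, slope = 0.2) {
  mask <- slope + (1 - slope) * (x > 0)
  list(y = x * mask, mask = mask)
}

relu_forward <- function(x) {
  mask <- (x > 0) * 1
  list(y = x * mask, mask = mask)
}

n_params <- function(ly) {
  if (is.null(ly$W)) 0L else length(ly$W) + length(ly$b)
}

zero_grads <- function(layers) {
  for (ly in layers) {
    if (!is.null(ly$W)) ly$gW <- NULL
    if (!is.null(ly$b)) ly$gb <- NULL
  }
  invisible(NULL)
}

adam_step <- function(layers, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8,
                      t = 1L) {
  for (ly in layers) {
    if (is.null(ly$W) || is.null(ly$gW)) next
    if (is.null(ly$mW)) {
      ly$mW <- ly$gW * 0
      ly$vW <- ly$gW * 0
    }
    ly$mW <- beta1 * ly$mW + (1 - beta1) * ly$gW
    ly$vW <- beta2 * ly$vW + (1 - beta2) * ly$gW^2
    mhat <- ly$mW / (1 - beta1^t)
    vhat <- ly$vW / (1 - beta2^t)
    ly$W <- ly$W - lr * mhat / (sqrt(vhat) + eps)
    if (!is.null(ly$b) && !is.null(ly$gb)) {
      if (is.null(ly$mb)) {
        ly$mb <- ly$gb * 0
        ly$vb <- ly$gb * 0
      }
      ly$mb <- beta1 * ly$mb + (1 - beta1) * ly$gb
      ly$vb <- beta2 * ly$vb + (1 - beta2) * ly$gb^2
      ly$b <- ly$b - lr * (ly$mb / (1 - beta1^t)) /
        (sqrt(ly$vb / (1 - beta2^t)) + eps)
    }
  }
  invisible(NULL)
}

ch_concat <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

ch_split <- function(g, c1) {
  d <- dim(g)
  list(array(g[, , seq_len(c1)], dim = c(d[1], d[2], c1)),
       array(g[, , (c1 + 1):d[3]], dim = c(d[1], d[2], d[3] - c1)))
}
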