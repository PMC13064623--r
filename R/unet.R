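#' Build a U-Net generator from a spec
#'
#' Encoder of `depth` strided convolutions (stride 2), mirrored decoder of
#' transposed convolutions, skip connections per `skip_mode`, instance
#' normalization on all but the outermost and bottleneck convolutions, tanh
#' output, single input/output channel. Convolutions are bias-free, so
#' [count_trainable()] is exactly the sum of the weight tensors. Weights are
#' drawn from N(0, 0.02) using the current RNG state; seed via [seed_all()]
#' for reproducible initializations.
#'
#' @param spec A [generator_spec()].
#' @param in_channels,out_channels Image channels (1 for grayscale).
#' @param input_size Spatial size the network will be applied to; used only
#'   to validate that the bottleneck stays at least 1 pixel.
#' @return An object of class `sted_network` (an environment).
#' @export
build_generator <- function(spec, in_channels = 1L, out_channels = 1L,
                            input_size = 128L) {
  stopifnot(inherits(spec, "generator_spec"))
  if (input_size %% 2^spec$depth != 0 && 2^spec$depth > input_size)
    stop("depth ", spec$depth, " incompatible with input size ", input_size)
  w <- spec_widths(spec)
  d <- spec$depth
  k <- spec$kernel_size
  opad <- if (k == 3L) 1L else 0L
  use_norm <- spec$norm != "none"
  net <- new.env(parent = emptyenv())
  net$kind <- "generator"
  net$spec <- spec
  net$d <- d
  net$skip <- spec$skip_mode
  net$dropout_p <- spec$dropout_p
  net$drop <- seq_len(d) > max(d - 3L, 1L)   # innermost decoder blocks
  cin <- c(in_channels, w[-d])
  net$enc <- lapply(seq_len(d), function(i) layer_conv(cin[i], w[i], k))
  net$enc_norm <- lapply(seq_len(d), function(i) {
    if (use_norm && i > 1 && i < d) layer_inorm(w[i]) else NULL
  })
  mult <- if (spec$skip_mode == "concat") 2L else 1L
  dec_in <- c(mult * w[seq_len(d - 1)], w[d])  # index i = level
  dec_out <- c(out_channels, w[seq_len(d - 1)])
  net$dec <- lapply(seq_len(d), function(i)
    layer_convt(dec_in[i], dec_out[i], k, opad = opad))
  net$dec_norm <- lapply(seq_len(d), function(i) {
    if (use_norm && i > 1) layer_inorm(dec_out[i]) else NULL
  })
  class(net) <- c("sted_network", "environment")
  net
}

net_layers <- function(net) {
  c(net$enc, net$dec,
    Filter(Negate(is.null), net$enc_norm),
    Filter(Negate(is.null), net$dec_norm),
    if (!is.null(net$body)) net$body)
}

#' Count trainable parameters of a network
#'
#' @param net A network built by [build_generator()] or
#'   [build_discriminator()].
#' @return Integer: total number of trainable scalars.
#' @export
count_trainable <- function(net) {
  sum(vapply(net_layers(net), n_params, integer(1)))
}

#' @export
print.sted_network <- function(x, ...) {
  cat(sprintf("<sted_network %s: %s parameters>\n", x$kind,
              format(count_trainable(x), big.mark = ",")))
  invisible(x)
}

# Forward pass of a U-Net generator on one (H, W, C) array. Caches enough
# for gen_backward. Dropout (training only) draws from the current RNG.
gen_forward <- function(net, x, training = FALSE) {
  d <- net$d
  cache <- list(e = vector("list", d), lr = vector("list", d),
                re = vector("list", d), dm = vector("list", d))
  h <- x
  for (i in seq_len(d)) {
    if (i > 1) {
      a <- lrelu_forward(h)
      cache$lr[[i]] <- a$mask
      h <- a$y
    }
    h <- conv_forward(net$enc[[i]], h)
    if (!is.null(net$enc_norm[[i]])) h <- inorm_forward(net$enc_norm[[i]], h)
    cache$e[[i]] <- h
  }
  u <- NULL
  for (i in rev(seq_len(d))) {
    inp <- if (i == d) cache$e[[d]]
           else if (net$skip == "concat") ch_concat(u, cache$e[[i]])
           else u + cache$e[[i]]
    a <- relu_forward(inp)
    cache$re[[i]] <- a$mask
    t <- convt_forward(net$dec[[i]], a$y)
    if (i > 1) {
      if (!is.null(net$dec_norm[[i]])) t <- inorm_forward(net$dec_norm[[i]], t)
      if (training && net$drop[i] && net$dropout_p > 0) {
        m <- (array(runif(length(t)), dim = dim(t)) >= net$dropout_p) /
          (1 - net$dropout_p)
        cache$dm[[i]] <- m
        t <- t * m
      }
      u <- t
    } else {
      t <- tanh(t)
      cache$y <- t
    }
  }
  net$cache <- cache
  cache$y
}

# Backward pass; accumulates weight gradients in the layers and returns the
# gradient with respect to the input (needed when this generator's output
# feeds another network, as in the cycle loss).
gen_backward <- function(net, gy) {
  cache <- net$cache
  d <- net$d
  ge <- vector("list", d)        # grads w.r.t. cache$e[[i]]
  w <- spec_widths(net$spec)
  gu <- NULL
  for (i in seq_len(d)) {
    g <- if (i == 1) gy * (1 - cache$y^2) else gu
    if (i > 1) {
      if (!is.null(cache$dm[[i]])) g <- g * cache$dm[[i]]
      if (!is.null(net$dec_norm[[i]])) g <- inorm_backward(net$dec_norm[[i]], g)
    }
    gin <- convt_backward(net$dec[[i]], g) * cache$re[[i]]
    if (i == d) {
      ge[[d]] <- add_grad(ge[[d]], gin)
    } else if (net$skip == "concat") {
      parts <- ch_split(gin, dim(gin)[3] - dim(cache$e[[i]])[3])
      gu <- parts[[1]]
      ge[[i]] <- add_grad(ge[[i]], parts[[2]])
    } else {
      gu <- gin
      ge[[i]] <- add_grad(ge[[i]], gin)
    }
  }
  g <- NULL
  for (i in rev(seq_len(d))) {
    g <- add_grad(ge[[i]], g)
    if (!is.null(net$enc_norm[[i]])) g <- inorm_backward(net$enc_norm[[i]], g)
    g <- conv_backward(net$enc[[i]], g)
    if (i > 1) g <- g * cache$lr[[i]]
  }
  g
}

add_grad <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else a + b

as_net_input <- function(x) {
  px <- if (inherits(x, "micro_image")) x$pixels else x
  if (length(dim(px)) == 2) array(px, dim = c(dim(px), 1L)) else px
}

#' Translate an image through a trained generator
#'
#' Deterministic forward pass (dropout disabled). The input must be in the
#' network range \[-1, 1\]; the result is mapped back to \[0, 1\] and tagged
#' `modality = "generated"`.
#'
#' @param net Generator network.
#' @param img [micro_image()] or matrix in \[-1, 1\].
#' @return A [micro_image()] in \[0, 1\].
#' @export
translate <- function(net, img) {
  x <- as_net_input(img)
  if (min(x) < -1 - 1e-6 || max(x) > 1 + 1e-6)
    stop("translate() expects input in the network range [-1, 1]")
  y <- gen_forward(net, x, training = FALSE)
  px <- from_net_range(matrix(y[, , 1], nrow = dim(y)[1]))
  id <- if (inherits(img, "micro_image")) img$id else ""
  micro_image(px, modality = "generated", quality = "unknown", id = id)
}
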