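#' Describe a PatchGAN discriminator
#'
#' A stack of stride-2 convolutions followed by two stride-1 convolutions;
#' the output is a 2-D map of patch scores (one per overlapping receptive
#' field), never a scalar. `conditional = TRUE` (Pix2Pix) concatenates the
#' source and candidate target along channels before scoring.
#'
#' @param widths Channel widths of the convolution stack.
#' @param kernel_size Kernel size (default 4).
#' @param norm `"instance"` or `"none"`.
#' @param conditional Logical; TRUE for Pix2Pix, FALSE for CycleGAN.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(widths = c(64L, 128L, 256L, 512L),
                               kernel_size = 4L,
                               norm = c("instance", "none"),
                               conditional = FALSE) {
  norm <- match.arg(norm)
  stopifnot(length(widths) >= 1, all(widths >= 1), kernel_size %in% c(3L, 4L))
  structure(list(widths = as.integer(widths),
                 kernel_size = as.integer(kernel_size), norm = norm,
                 conditional = conditional),
            class = "discriminator_spec")
}

#' Build a PatchGAN discriminator
#'
#' @param spec A [discriminator_spec()].
#' @return A `sted_network` whose forward output is a raw patch-score map
#'   (apply the GAN loss in [adversarial_loss()] to interpret it).
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  w <- spec$widths
  n <- length(w)
  k <- spec$kernel_size
  use_norm <- spec$norm != "none"
  cin <- c(if (spec$conditional) 2L else 1L, w)
  layers <- list()
  for (i in seq_len(n)) {
    s <- if (i < n || n == 1) 2L else 1L  # last width layer runs at stride 1
    layers[[length(layers) + 1]] <- layer_conv(cin[i], w[i], k, s = s)
    layers[[length(layers) + 1]] <-
      if (use_norm && i > 1) layer_inorm(w[i]) else NULL
    layers[[length(layers) + 1]] <- "lrelu"
  }
  layers[[length(layers) + 1]] <- layer_conv(w[n], 1L, k, s = 1L)
  net <- new.env(parent = emptyenv())
  net$kind <- "discriminator"
  net$spec <- spec
  net$body <- Filter(function(l) !is.null(l) && !is.character(l), layers)
  net$chain <- layers
  class(net) <- c("sted_network", "environment")
  net
}

disc_forward <- function(net, x) {
  h <- x
  masks <- list()
  for (j in seq_along(net$chain)) {
    l <- net$chain[[j]]
    if (is.null(l)) next
    if (is.character(l)) {
      a <- lrelu_forward(h)
      masks[[as.character(j)]] <- a$mask
      h <- a$y
    } else if (l$type == "conv") {
      h <- conv_forward(l, h)
    } else {
      h <- inorm_forward(l, h)
    }
  }
  net$masks <- masks
  h
}

disc_backward <- function(net, gy) {
  g <- gy
  for (j in rev(seq_along(net$chain))) {
    l <- net$chain[[j]]
    if (is.null(l)) next
    if (is.character(l)) {
      g <- g * net$masks[[as.character(j)]]
    } else if (l$type == "conv") {
      g <- conv_backward(l, g)
    } else {
      g <- inorm_backward(l, g)
    }
  }
  g
}
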