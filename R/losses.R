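# Objective functions of the two adversarial frameworks. The evaluation
# functions here score fixed networks on a batch (no gradients); the
# training loops in training.R compute the matching gradients inline.

#' Mean absolute (L1) reconstruction loss
#'
#' @param generated,target Arrays or matrices of identical shape.
#' @return Scalar mean absolute difference.
#' @export
l1_loss <- function(generated, target) {
  a <- as_net_input(generated)
  b <- as_net_input(target)
  if (!identical(dim(a), dim(b))) stop("shape mismatch in l1_loss")
  mean(abs(a - b))
}

#' Adversarial loss from patch-score maps
#'
#' In `"bce"` mode the scores are probabilities in (0, 1): the discriminator
#' loss is the negated two-term log objective and the generator loss its
#' non-saturating form `-E[log D(fake)]`. In `"lsgan"` mode scores are raw:
#' squared error to labels 1 (real) and 0 (fake), with the conventional 1/2
#' on the discriminator. Patch scores are averaged, so the loss is invariant
#' to the spatial size of a constant score map.
#'
#' @param disc_scores_real,disc_scores_fake Patch-score maps.
#' @param mode `"bce"` or `"lsgan"`.
#' @return Named numeric: `loss_D` and `loss_G`.
#' @export
adversarial_loss <- function(disc_scores_real, disc_scores_fake,
                             mode = c("bce", "lsgan")) {
  mode <- match.arg(mode)
  if (!identical(dim(as_net_input(disc_scores_real)),
                 dim(as_net_input(disc_scores_fake))))
    stop("score maps must have the same shape")
  r <- as.numeric(disc_scores_real)
  f <- as.numeric(disc_scores_fake)
  if (mode == "bce") {
    if (any(r <= 0 | r >= 1) || any(f <= 0 | f >= 1))
      stop("bce mode expects probabilities in (0, 1)")
    c(loss_D = -(mean(log(r)) + mean(log(1 - f))),
      loss_G = -mean(log(f)))
  } else {
    c(loss_D = 0.5 * (mean((r - 1)^2) + mean(f^2)),
      loss_G = mean((f - 1)^2))
  }
}

#' Loss weights for the adversarial objectives
#'
#' @param lambda_l1 Weight of the L1 term in the Pix2Pix objective
#'   (default 100).
#' @param lambda_cyc Weight of the cycle-consistency term (default 10).
#' @param lambda_id Weight of the identity term (default 5).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_l1 = 100, lambda_cyc = 10, lambda_id = 5) {
  stopifnot(is.finite(lambda_l1), lambda_l1 >= 0,
            is.finite(lambda_cyc), lambda_cyc >= 0,
            is.finite(lambda_id), lambda_id >= 0)
  structure(list(lambda_l1 = lambda_l1, lambda_cyc = lambda_cyc,
                 lambda_id = lambda_id), class = "loss_weights")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Internal: loss value and d(loss)/d(raw score) for one score map.
gan_loss_grad <- function(scores, target_real, role = c("D", "G"),
                          mode = c("bce", "lsgan")) {
  role <- match.arg(role)
  mode <- match.arg(mode)
  n <- length(scores)
  if (mode == "lsgan") {
    lab <- if (target_real) 1 else 0
    scale <- if (role == "D") 0.5 else 1
    list(loss = scale * mean((scores - lab)^2),
         grad = scale * 2 * (scores - lab) / n)
  } else {
    s <- sigmoid(scores)
    if (target_real) {
      list(loss = -mean(log(pmax(s, 1e-12))), grad = (s - 1) / n)
    } else {
      list(loss = -mean(log(pmax(1 - s, 1e-12))), grad = s / n)
    }
  }
}

batch_list <- function(batch) {
  if (inherits(batch, "paired_sample")) batch <- list(batch)
  if (inherits(batch, "image_dataset")) batch <- batch$samples
  if (!is.list(batch)) stop("batch must be a list")
  batch
}

pair_arrays <- function(p) {
  list(x = as_net_input(p$source), y = as_net_input(p$target))
}

#' Evaluate the Pix2Pix objective on a paired batch
#'
#' Total = adversarial generator term + lambda_l1 x L1(G(x), y), with the
#' component breakdown. Scoring uses the conditional discriminator on the
#' (source, candidate) concatenation.
#'
#' @param G Generator network. @param D Conditional discriminator.
#' @param batch List of [paired_sample()]s in network range.
#' @param weights A [loss_weights()].
#' @param gan_mode `"bce"` or `"lsgan"`.
#' @return Named list: `total`, `adv_G`, `adv_D`, `l1`.
#' @export
pix2pix_objective <- function(G, D, batch, weights = loss_weights(),
                              gan_mode = "bce") {
  batch <- batch_list(batch)
  if (!all(vapply(batch, inherits, logical(1), "paired_sample")))
    stop("pix2pix requires a paired batch")
  adv_G <- adv_D <- l1 <- 0
  for (p in batch) {
    ab <- pair_arrays(p)
    fake <- gen_forward(G, ab$x)
    s_fake <- disc_forward(D, ch_concat(ab$x, fake))
    s_real <- disc_forward(D, ch_concat(ab$x, ab$y))
    adv_G <- adv_G + gan_loss_grad(s_fake, TRUE, "G", gan_mode)$loss
    adv_D <- adv_D + gan_loss_grad(s_real, TRUE, "D", gan_mode)$loss +
      gan_loss_grad(s_fake, FALSE, "D", gan_mode)$loss
    l1 <- l1 + l1_loss(fake, ab$y)
  }
  n <- length(batch)
  adv_G <- adv_G / n; adv_D <- adv_D / n; l1 <- l1 / n
  list(total = adv_G + weights$lambda_l1 * l1, adv_G = adv_G, adv_D = adv_D,
       l1 = l1)
}

#' Cycle-consistency loss of a generator pair
#'
#' Sum of both reconstruction directions:
#' `E_x |F(G(x)) - x| + E_y |G(F(y)) - y|`.
#'
#' @param G,F Generator networks (source-to-target and back).
#' @param batch_x,batch_y Lists of images (arrays or [micro_image()]s) in
#'   network range; need not be paired.
#' @return Scalar loss.
#' @export
cycle_loss <- function(G, F, batch_x, batch_y) {
  xs <- lapply(batch_list(batch_x), as_net_input)
  ys <- lapply(batch_list(batch_y), as_net_input)
  t1 <- mean(vapply(xs, function(x)
    l1_loss(gen_forward(F, gen_forward(G, x)), x), numeric(1)))
  t2 <- mean(vapply(ys, function(y)
    l1_loss(gen_forward(G, gen_forward(F, y)), y), numeric(1)))
  t1 + t2
}

#' Identity loss of a generator pair
#'
#' `E_y |G(y) - y| + E_x |F(x) - x|`: each generator applied to its own
#' target domain should behave like the identity.
#'
#' @inheritParams cycle_loss
#' @return Scalar loss.
#' @export
identity_loss <- function(G, F, batch_x, batch_y) {
  xs <- lapply(batch_list(batch_x), as_net_input)
  ys <- lapply(batch_list(batch_y), as_net_input)
  t1 <- mean(vapply(ys, function(y) l1_loss(gen_forward(G, y), y), numeric(1)))
  t2 <- mean(vapply(xs, function(x) l1_loss(gen_forward(F, x), x), numeric(1)))
  t1 + t2
}

#' Evaluate the full CycleGAN objective
#'
#' Two-sided adversarial terms plus weighted cycle and identity terms. No
#' pairing is assumed anywhere on this path: `batch_x` and `batch_y` are
#' independent collections.
#'
#' @param G,F Generators (x-to-y and y-to-x).
#' @param D_X,D_Y Domain discriminators (unconditional).
#' @param batch_x,batch_y Image collections in network range.
#' @param weights A [loss_weights()].
#' @param gan_mode `"bce"` or `"lsgan"`.
#' @return Named list with `total` and the component breakdown.
#' @export
cyclegan_objective <- function(G, F, D_X, D_Y, batch_x, batch_y,
                               weights = loss_weights(), gan_mode = "lsgan") {
  xs <- lapply(batch_list(batch_x), as_net_input)
  ys <- lapply(batch_list(batch_y), as_net_input)
  adv_G <- mean(vapply(xs, function(x)
    gan_loss_grad(disc_forward(D_Y, gen_forward(G, x)), TRUE, "G",
                  gan_mode)$loss, numeric(1)))
  adv_F <- mean(vapply(ys, function(y)
    gan_loss_grad(disc_forward(D_X, gen_forward(F, y)), TRUE, "G",
                  gan_mode)$loss, numeric(1)))
  cyc <- cycle_loss(G, F, xs, ys)
  idt <- identity_loss(G, F, xs, ys)
  list(total = adv_G + adv_F + weights$lambda_cyc * cyc +
         weights$lambda_id * idt,
       adv_G = adv_G, adv_F = adv_F, cycle = cyc, identity = idt)
}
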