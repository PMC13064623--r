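#' Training configuration for the adversarial frameworks
#'
#' Defaults follow common practice for both frameworks: Adam at learning
#' rate 2e-4 with betas (0.5, 0.999), 200 epochs with the learning rate
#' decaying linearly to zero from epoch 100, checkpoints every 5 epochs.
#'
#' @param epochs Training epochs (default 200).
#' @param checkpoint_every Checkpoint cadence in epochs (default 5); the
#'   final epoch is checkpointed regardless of cadence.
#' @param learning_rate Adam learning rate (default 2e-4).
#' @param adam_betas Numeric pair (default c(0.5, 0.999)).
#' @param batch_size Images per optimization step (default 4).
#' @param seed Master seed for [seed_all()].
#' @param gan_mode `"bce"` or `"lsgan"`; if `NULL`, Pix2Pix uses the
#'   non-saturating log loss and CycleGAN least squares.
#' @param lr_decay_start Epoch after which the learning rate decays linearly
#'   to zero at the final epoch (default 100).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, checkpoint_every = 5L,
                         learning_rate = 2e-4, adam_betas = c(0.5, 0.999),
                         batch_size = 4L, seed = 1L, gan_mode = NULL,
                         lr_decay_start = 100L) {
  stopifnot(epochs >= 1, checkpoint_every >= 1, learning_rate > 0,
            length(adam_betas) == 2, batch_size >= 1)
  if (!is.null(gan_mode)) gan_mode <- match.arg(gan_mode, c("bce", "lsgan"))
  structure(list(epochs = as.integer(epochs),
                 checkpoint_every = as.integer(checkpoint_every),
                 learning_rate = learning_rate, adam_betas = adam_betas,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 gan_mode = gan_mode,
                 lr_decay_start = as.integer(lr_decay_start)),
            class = "train_config")
}

#' Seed every source of randomness
#'
#' All randomness in the package (phantom generation, weight
#' initialization, shuffling, dropout, the image pool) flows through R's
#' RNG; this pins generator kind and seed so an experiment is reproducible
#' from its seed alone.
#'
#' @param seed Integer seed.
#' @return Invisibly, `seed`.
#' @export
seed_all <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(seed)
}

checkpoint_epochs <- function(epochs, every) {
  eps <- seq_len(epochs)[seq_len(epochs) %% every == 0]
  if (length(eps) == 0 || eps[length(eps)] != epochs) eps <- c(eps, epochs)
  eps
}

lr_at_epoch <- function(cfg, epoch) {
  if (epoch <= cfg$lr_decay_start || cfg$epochs <= cfg$lr_decay_start)
    return(cfg$learning_rate)
  cfg$learning_rate * (cfg$epochs - epoch + 1) /
    (cfg$epochs - cfg$lr_decay_start + 1)
}

#' Extract or restore network weights
#'
#' @param net A `sted_network`.
#' @return A list of weight matrices, ordered as the network's layers.
#' @export
get_weights <- function(net) {
  lapply(Filter(function(l) !is.null(l$W), net_layers(net)),
         function(l) list(W = l$W, b = l$b))
}

#' @rdname get_weights
#' @param weights A list as returned by `get_weights`.
#' @export
set_weights <- function(net, weights) {
  lys <- Filter(function(l) !is.null(l$W), net_layers(net))
  stopifnot(length(lys) == length(weights))
  for (i in seq_along(lys)) {
    stopifnot(identical(dim(lys[[i]]$W), dim(weights[[i]]$W)))
    lys[[i]]$W <- weights[[i]]$W
    lys[[i]]$b <- weights[[i]]$b
  }
  invisible(net)
}

save_checkpoint <- function(dir, tag, epoch, nets, cfg) {
  state <- list(epoch = epoch, config = unclass(cfg),
                weights = lapply(nets, get_weights))
  if (is.null(dir)) return(state)
  path <- file.path(dir, sprintf("checkpoint_%s_epoch%03d.rds", tag, epoch))
  saveRDS(state, path)
  path
}

finalize_run <- function(dir, cfg, weights, history) {
  if (is.null(dir)) return(invisible(NULL))
  yaml::write_yaml(list(train_config = unclass(cfg),
                        loss_weights = unclass(weights)),
                   file.path(dir, "config.yaml"))
  utils::write.csv(history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(NULL)
}

check_finite <- function(value, what, epoch) {
  if (!all(is.finite(value)))
    stop(sprintf("non-finite %s at epoch %d: training diverged", what, epoch))
  value
}

val_ssim <- function(G, validation) {
  if (is.null(validation)) return(NA_real_)
  mean(vapply(batch_list(validation), function(p) {
    out <- translate(G, to_net_range(p$source))
    ssim(out$pixels, p$target$pixels, data_range = 1)
  }, numeric(1)))
}

sign_grad <- function(diff) sign(diff) / length(diff)

#' Train a Pix2Pix model on paired data
#'
#' Alternating discriminator/generator updates with Adam, linear
#' learning-rate decay, per-epoch loss history and periodic checkpoints.
#' Fully deterministic given `config$seed` on a fixed machine.
#'
#' @param dataset An [image_dataset()] (or list) of preprocessed, registered
#'   [paired_sample()]s with intensities in \[0, 1\].
#' @param gen_spec A [generator_spec()].
#' @param disc_spec A [discriminator_spec()]; forced conditional.
#' @param config A [train_config()].
#' @param weights A [loss_weights()].
#' @param checkpoint_dir Optional directory for checkpoint/RDS, config echo
#'   and history CSV; if `NULL`, checkpoints are kept in memory.
#' @param validation Optional list of pairs for per-epoch validation SSIM.
#' @param verbose Print per-epoch losses.
#' @return List with `G`, `D`, `history` (tibble, one row per epoch) and
#'   `checkpoints`.
#' @export
train_pix2pix <- function(dataset, gen_spec, disc_spec = discriminator_spec(),
                          config = train_config(), weights = loss_weights(),
                          checkpoint_dir = NULL, validation = NULL,
                          verbose = FALSE) {
  pairs <- batch_list(dataset)
  if (length(pairs) == 0) stop("empty dataset")
  if (!all(vapply(pairs, inherits, logical(1), "paired_sample")))
    stop("pix2pix requires paired samples")
  mode <- config$gan_mode %||% "bce"
  seed_all(config$seed)
  disc_spec$conditional <- TRUE
  G <- build_generator(gen_spec)
  D <- build_discriminator(disc_spec)
  arrs <- lapply(pairs, function(p)
    list(x = as_net_input(to_net_range(p$source)),
         y = as_net_input(to_net_range(p$target))))
  ck_eps <- checkpoint_epochs(config$epochs, config$checkpoint_every)
  checkpoints <- list()
  hist <- vector("list", config$epochs)
  tG <- tD <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample(length(arrs))
    nb <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep <- c(loss_D = 0, adv_G = 0, l1 = 0)
    for (bi in nb) {
      B <- length(bi)
      fakes <- vector("list", B)
      # --- discriminator update ---
      zero_grads(net_layers(D))
      ld <- 0
      for (j in seq_len(B)) {
        ab <- arrs[[bi[j]]]
        fakes[[j]] <- gen_forward(G, ab$x, training = TRUE)
        sr <- disc_forward(D, ch_concat(ab$x, ab$y))
        gr <- gan_loss_grad(sr, TRUE, "D", mode)
        disc_backward(D, gr$grad / B)
        sf <- disc_forward(D, ch_concat(ab$x, fakes[[j]]))
        gf <- gan_loss_grad(sf, FALSE, "D", mode)
        disc_backward(D, gf$grad / B)
        ld <- ld + (gr$loss + gf$loss) / B
      }
      tD <- tD + 1L
      adam_step(net_layers(D), lr, config$adam_betas[1], config$adam_betas[2],
                t = tD)
      # --- generator update ---
      zero_grads(net_layers(G))
      zero_grads(net_layers(D))
      lg <- ll <- 0
      for (j in seq_len(B)) {
        ab <- arrs[[bi[j]]]
        fake <- gen_forward(G, ab$x, training = TRUE)
        sf <- disc_forward(D, ch_concat(ab$x, fake))
        gg <- gan_loss_grad(sf, TRUE, "G", mode)
        g_in <- disc_backward(D, gg$grad)
        g_fake <- ch_split(g_in, 1L)[[2]]
        diff <- fake - ab$y
        g_fake <- g_fake + weights$lambda_l1 * sign_grad(diff)
        gen_backward(G, g_fake / B)
        lg <- lg + gg$loss / B
        ll <- ll + mean(abs(diff)) / B
      }
      tG <- tG + 1L
      adam_step(net_layers(G), lr, config$adam_betas[1], config$adam_betas[2],
                t = tG)
      ep <- ep + c(ld, lg, ll) / length(nb)
    }
    check_finite(ep, "loss", epoch)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, loss_D = ep[["loss_D"]],
                                    adv_G = ep[["adv_G"]], l1 = ep[["l1"]],
                                    total_G = ep[["adv_G"]] +
                                      weights$lambda_l1 * ep[["l1"]],
                                    lr = lr,
                                    val_ssim = val_ssim(G, validation))
    if (verbose)
      message(sprintf("epoch %3d  D %.4f  G_adv %.4f  L1 %.4f", epoch,
                      ep[["loss_D"]], ep[["adv_G"]], ep[["l1"]]))
    if (epoch %in% ck_eps)
      checkpoints[[as.character(epoch)]] <-
        save_checkpoint(checkpoint_dir, "pix2pix", epoch, list(G = G), config)
  }
  history <- dplyr::bind_rows(hist)
  finalize_run(checkpoint_dir, config, weights, history)
  list(G = G, D = D, history = history, checkpoints = checkpoints)
}

# Seeded image pool (history of generated images) for CycleGAN
# discriminator updates; returns the image to score and stores the new one.
pool_query <- function(pool, img) {
  if (pool$size == 0) return(img)
  if (length(pool$imgs) < pool$size) {
    pool$imgs[[length(pool$imgs) + 1]] <- img
    return(img)
  }
  if (runif(1) > 0.5) {
    i <- sample.int(length(pool$imgs), 1)
    out <- pool$imgs[[i]]
    pool$imgs[[i]] <- img
    out
  } else {
    img
  }
}

new_pool <- function(size = 50L) {
  e <- new.env(parent = emptyenv())
  e$size <- size
  e$imgs <- list()
  e
}

#' Train a CycleGAN on two (possibly unpaired) image collections
#'
#' Four-network alternating optimization: generator pair G (x to y) and
#' F (y to x) with adversarial, cycle-consistency and identity terms, then
#' the two domain discriminators on real versus pooled fake images. No
#' pairing between `dataset_x` and `dataset_y` is consulted anywhere.
#'
#' @param dataset_x,dataset_y Collections of [micro_image()]s (or matrices)
#'   in \[0, 1\]; an [image_dataset()] is split into its sources (x) and
#'   targets (y).
#' @param gen_spec,disc_spec,config,weights,checkpoint_dir,verbose As in
#'   [train_pix2pix()]; the discriminators are unconditional.
#' @param validation Optional list of [paired_sample()]s for per-epoch
#'   validation SSIM of G.
#' @param pool_size Image-pool size for discriminator updates (default 50;
#'   0 disables the pool).
#' @return List with `G`, `F`, `D_X`, `D_Y`, `history` and `checkpoints`.
#' @export
train_cyclegan <- function(dataset_x, dataset_y = NULL,
                           gen_spec = registry_spec(9),
                           disc_spec = discriminator_spec(),
                           config = train_config(), weights = loss_weights(),
                           checkpoint_dir = NULL, validation = NULL,
                           pool_size = 50L, verbose = FALSE) {
  if (inherits(dataset_x, "image_dataset") && is.null(dataset_y)) {
    dataset_y <- lapply(dataset_x$samples, function(p) p$target)
    dataset_x <- lapply(dataset_x$samples, function(p) p$source)
  }
  xs <- lapply(batch_list(dataset_x), function(i) as_net_input(to_net_range(i)))
  ys <- lapply(batch_list(dataset_y), function(i) as_net_input(to_net_range(i)))
  if (length(xs) == 0 || length(ys) == 0) stop("empty dataset")
  mode <- config$gan_mode %||% "lsgan"
  seed_all(config$seed)
  disc_spec$conditional <- FALSE
  G <- build_generator(gen_spec)
  F_ <- build_generator(gen_spec)
  D_X <- build_discriminator(disc_spec)
  D_Y <- build_discriminator(disc_spec)
  pool_x <- new_pool(pool_size)
  pool_y <- new_pool(pool_size)
  ck_eps <- checkpoint_epochs(config$epochs, config$checkpoint_every)
  checkpoints <- list()
  hist <- vector("list", config$epochs)
  b1 <- config$adam_betas[1]; b2 <- config$adam_betas[2]
  tG <- tD <- 0L
  n <- min(length(xs), length(ys))
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    ord_x <- sample(length(xs), n)
    ord_y <- sample(length(ys), n)
    nb <- split(seq_len(n), ceiling(seq_len(n) / config$batch_size))
    ep <- c(adv_G = 0, adv_F = 0, cycle = 0, identity = 0, loss_DX = 0,
            loss_DY = 0)
    for (bi in nb) {
      B <- length(bi)
      fakes_y <- vector("list", B)
      fakes_x <- vector("list", B)
      # --- generator update (G and F jointly) ---
      zero_grads(c(net_layers(G), net_layers(F_), net_layers(D_X),
                   net_layers(D_Y)))
      la_G <- la_F <- lcyc <- lid <- 0
      for (j in seq_len(B)) {
        x <- xs[[ord_x[bi[j]]]]
        y <- ys[[ord_y[bi[j]]]]
        # x -> y -> x
        fake_y <- gen_forward(G, x, training = TRUE)
        fakes_y[[j]] <- fake_y
        s <- disc_forward(D_Y, fake_y)
        gg <- gan_loss_grad(s, TRUE, "G", mode)
        g_fy <- disc_backward(D_Y, gg$grad / B)
        rec_x <- gen_forward(F_, fake_y, training = TRUE)
        diff <- rec_x - x
        g_fy <- g_fy + gen_backward(F_, weights$lambda_cyc * sign_grad(diff) / B)
        gen_backward(G, g_fy)
        la_G <- la_G + gg$loss / B
        lcyc <- lcyc + mean(abs(diff)) / B
        # y -> x -> y
        fake_x <- gen_forward(F_, y, training = TRUE)
        fakes_x[[j]] <- fake_x
        s <- disc_forward(D_X, fake_x)
        gf <- gan_loss_grad(s, TRUE, "G", mode)
        g_fx <- disc_backward(D_X, gf$grad / B)
        rec_y <- gen_forward(G, fake_x, training = TRUE)
        diff <- rec_y - y
        g_fx <- g_fx + gen_backward(G, weights$lambda_cyc * sign_grad(diff) / B)
        gen_backward(F_, g_fx)
        la_F <- la_F + gf$loss / B
        lcyc <- lcyc + mean(abs(diff)) / B
        # identity terms
        if (weights$lambda_id > 0) {
          id_y <- gen_forward(G, y, training = TRUE)
          diff <- id_y - y
          gen_backward(G, weights$lambda_id * sign_grad(diff) / B)
          lid <- lid + mean(abs(diff)) / B
          id_x <- gen_forward(F_, x, training = TRUE)
          diff <- id_x - x
          gen_backward(F_, weights$lambda_id * sign_grad(diff) / B)
          lid <- lid + mean(abs(diff)) / B
        }
      }
      tG <- tG + 1L
      adam_step(c(net_layers(G), net_layers(F_)), lr, b1, b2, t = tG)
      # --- discriminator updates ---
      zero_grads(c(net_layers(D_X), net_layers(D_Y)))
      ldx <- ldy <- 0
      for (j in seq_len(B)) {
        y <- ys[[ord_y[bi[j]]]]
        x <- xs[[ord_x[bi[j]]]]
        sr <- disc_forward(D_Y, y)
        gr <- gan_loss_grad(sr, TRUE, "D", mode)
        disc_backward(D_Y, gr$grad / B)
        fy <- pool_query(pool_y, fakes_y[[j]])
        sf <- disc_forward(D_Y, fy)
        gf <- gan_loss_grad(sf, FALSE, "D", mode)
        disc_backward(D_Y, gf$grad / B)
        ldy <- ldy + (gr$loss + gf$loss) / B
        sr <- disc_forward(D_X, x)
        gr <- gan_loss_grad(sr, TRUE, "D", mode)
        disc_backward(D_X, gr$grad / B)
        fx <- pool_query(pool_x, fakes_x[[j]])
        sf <- disc_forward(D_X, fx)
        gf <- gan_loss_grad(sf, FALSE, "D", mode)
        disc_backward(D_X, gf$grad / B)
        ldx <- ldx + (gr$loss + gf$loss) / B
      }
      tD <- tD + 1L
      adam_step(c(net_layers(D_X), net_layers(D_Y)), lr, b1, b2, t = tD)
      ep <- ep + c(la_G, la_F, lcyc, lid, ldx, ldy) / length(nb)
    }
    check_finite(ep, "loss", epoch)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, adv_G = ep[["adv_G"]],
                                    adv_F = ep[["adv_F"]],
                                    cycle = ep[["cycle"]],
                                    identity = ep[["identity"]],
                                    loss_DX = ep[["loss_DX"]],
                                    loss_DY = ep[["loss_DY"]], lr = lr,
                                    val_ssim = val_ssim(G, validation))
    if (verbose)
      message(sprintf("epoch %3d  advG %.4f advF %.4f cyc %.4f id %.4f",
                      epoch, ep[["adv_G"]], ep[["adv_F"]], ep[["cycle"]],
                      ep[["identity"]]))
    if (epoch %in% ck_eps)
      checkpoints[[as.character(epoch)]] <-
        save_checkpoint(checkpoint_dir, "cyclegan", epoch,
                        list(G = G, F = F_), config)
  }
  history <- dplyr::bind_rows(hist)
  finalize_run(checkpoint_dir, config, weights, history)
  list(G = G, F = F_, D_X = D_X, D_Y = D_Y, history = history,
       checkpoints = checkpoints)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
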