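# Cross-validation, repeated-measures ANOVA across models, and
# Holm-corrected pairwise tests.

#' Random k-fold partition
#'
#' Partitions `n` items into `k` folds whose sizes differ by at most one;
#' deterministic given `seed`.
#'
#' @param n Number of items (>= k).
#' @param k Number of folds (>= 2).
#' @param seed Seed.
#' @return Integer vector of 0-based fold indices, length `n`.
#' @export
kfold_split <- function(n, k = 5L, seed = 1L) {
  if (n < k) stop("n must be at least k")
  stopifnot(k >= 2)
  seed_all(seed)
  sample(rep(seq_len(k) - 1L, length.out = n))
}

#' Assign folds to a dataset
#'
#' @param dataset An [image_dataset()].
#' @param k Number of folds.
#' @param seed Seed.
#' @return The dataset with `fold_of` filled (named 0-based integers).
#' @export
assign_folds <- function(dataset, k = 5L, seed = 1L) {
  ids <- vapply(dataset$samples, function(s) s$sample_id, character(1))
  f <- kfold_split(length(ids), k, seed)
  image_dataset(dataset$samples, fold_of = setNames(f, ids))
}

#' Evaluate a generator on a validation set
#'
#' Translates each source image and scores it against the target, together
#' with the untranslated confocal baseline on the same pairs (identical
#' metrics, identical preprocessing).
#'
#' @param generator A trained generator network, a plain function mapping a
#'   \[0, 1\] pixel matrix to a \[0, 1\] pixel matrix (e.g. `identity` as a
#'   reference translator), or `NULL` for baseline-only evaluation.
#' @param validation List of [paired_sample()]s in \[0, 1\].
#' @param fold_index Optional fold label attached to the rows.
#' @param cap_db Normalized-PSNR cap.
#' @return An object of class `fold_result`: list with `per_image`
#'   (tibble) and `summary` (mean and sd per metric).
#' @export
evaluate_model <- function(generator, validation, fold_index = 0L,
                           cap_db = 40) {
  pairs <- batch_list(validation)
  if (length(pairs) == 0) stop("empty validation set")
  rows <- purrr::map_dfr(pairs, function(p) {
    tgt <- p$target$pixels
    base <- metric_report(p$source$pixels, tgt, cap_db)
    names(base) <- paste0("baseline_", names(base))
    if (!is.null(generator)) {
      out_px <- if (is.function(generator)) generator(p$source$pixels)
                else translate(generator, to_net_range(p$source))$pixels
      gen <- metric_report(out_px, tgt, cap_db)
      dplyr::bind_cols(tibble::tibble(sample_id = p$sample_id,
                                      fold = fold_index), gen, base)
    } else {
      dplyr::bind_cols(tibble::tibble(sample_id = p$sample_id,
                                      fold = fold_index), base)
    }
  })
  metric_cols <- setdiff(names(rows), c("sample_id", "fold"))
  summary <- tidyr::pivot_longer(rows, dplyr::all_of(metric_cols),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value[is.finite(.data$value)]),
                     sd = sd(.data$value[is.finite(.data$value)]),
                     .groups = "drop")
  structure(list(fold_index = fold_index, per_image = rows,
                 summary = summary), class = "fold_result")
}

#' One-way repeated-measures ANOVA
#'
#' Subjects x models matrix of one metric; F = MS_model / MS_(model x
#' subject) with df (m - 1) and (m - 1)(n - 1). Degenerate inputs (zero
#' error variance) are reported with a flag rather than an error: identical
#' columns give F = 0, p = 1; a perfectly consistent nonzero effect gives
#' F = Inf, p = 0.
#'
#' @param mat Numeric matrix, subjects in rows, models in columns, no
#'   missing cells.
#' @return An object of class `rm_anova`: list with `f_stat`, `p_value`,
#'   `df1`, `df2`, `degenerate`.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("rm_anova requires complete cells")
  n <- nrow(mat); m <- ncol(mat)
  if (m < 2 || n < 3) stop("need >= 2 models and >= 3 subjects")
  grand <- mean(mat)
  col_m <- colMeans(mat)
  row_m <- rowMeans(mat)
  ss_model <- n * sum((col_m - grand)^2)
  ss_subj <- m * sum((row_m - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_model - ss_subj
  df1 <- m - 1
  df2 <- (m - 1) * (n - 1)
  ms_model <- ss_model / df1
  ms_err <- max(ss_err, 0) / df2
  eps <- 1e-12 * max(abs(mat))^2
  degenerate <- ms_err <= eps
  if (degenerate) {
    if (ms_model <= eps) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- ms_model / ms_err
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(f_stat = f, p_value = p, df1 = df1, df2 = df2,
                 degenerate = degenerate), class = "rm_anova")
}

#' Holm-corrected pairwise paired t-tests
#'
#' All m(m-1)/2 two-sided paired t-tests on subject-wise differences, with
#' the Holm step-down adjustment: sort raw p ascending, adjusted p_i is the
#' running maximum of (n_tests - j + 1) p_j for j <= i, capped at 1.
#'
#' @param mat Subjects x models matrix; column names label the models.
#' @return An object of class `holm_pairwise`: list with `p_matrix`
#'   (symmetric matrix of adjusted p), `raw_matrix` and `table` (tibble).
#' @export
holm_pairwise <- function(mat) {
  mat <- as.matrix(mat)
  m <- ncol(mat)
  if (m < 2 || nrow(mat) < 3) stop("need >= 2 models and >= 3 subjects")
  labs <- colnames(mat) %||% paste0("model", seq_len(m))
  prs <- utils::combn(m, 2)
  raw <- apply(prs, 2, function(ij) {
    d <- mat[, ij[1]] - mat[, ij[2]]
    if (sd(d) == 0) {
      if (mean(d) == 0) 1 else 0
    } else {
      t.test(d)$p.value
    }
  })
  adj <- holm_adjust(raw)
  pm <- rm <- matrix(NA_real_, m, m, dimnames = list(labs, labs))
  for (j in seq_len(ncol(prs))) {
    pm[prs[1, j], prs[2, j]] <- pm[prs[2, j], prs[1, j]] <- adj[j]
    rm[prs[1, j], prs[2, j]] <- rm[prs[2, j], prs[1, j]] <- raw[j]
  }
  tbl <- tibble::tibble(model_a = labs[prs[1, ]], model_b = labs[prs[2, ]],
                        p_raw = raw, p_holm = adj)
  structure(list(p_matrix = pm, raw_matrix = rm, table = tbl),
            class = "holm_pairwise")
}

#' Holm step-down adjustment of a p-value vector
#'
#' @param p Raw p-values.
#' @return Adjusted p-values in the original order (never smaller than the
#'   raw values, monotone in the step-down order).
#' @export
holm_adjust <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- pmin(cummax((k - seq_len(k) + 1) * p[o]), 1)
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Compare models on pooled per-image metrics
#'
#' Runs the repeated-measures ANOVA (images as subjects, model as the
#' within-factor) and Holm-corrected pairwise tests for each metric.
#'
#' @param per_image Long tibble with columns `sample_id`, `model` and the
#'   metric columns.
#' @param metrics Character vector of metric column names.
#' @return A list of `model_comparison` objects, one per metric, each with
#'   `metric_name`, `anova` and `pairwise`.
#' @export
compare_models <- function(per_image, metrics = c("ssim", "psnr_db")) {
  lapply(setNames(metrics, metrics), function(mn) {
    wide <- tidyr::pivot_wider(per_image[, c("sample_id", "model", mn)],
                               names_from = "model",
                               values_from = dplyr::all_of(mn))
    mat <- as.matrix(wide[, -1, drop = FALSE])
    rownames(mat) <- wide$sample_id
    if (anyNA(mat)) stop("missing cells for metric ", mn)
    structure(list(metric_name = mn, anova = rm_anova(mat),
                   pairwise = holm_pairwise(mat)),
              class = "model_comparison")
  })
}

#' Cross-validate one or more generator specs
#'
#' For each fold and model: reseed, train on the other folds, evaluate on
#' the held-out fold (every sample appears in exactly one validation fold);
#' then pool per-image metrics and compare models.
#'
#' @param dataset An [image_dataset()] with folds assigned (see
#'   [assign_folds()]); folds are assigned with `k` and the config seed if
#'   absent.
#' @param model_specs Named list of [generator_spec()]s.
#' @param config A [train_config()].
#' @param framework `"cyclegan"` or `"pix2pix"`.
#' @param disc_spec,weights Passed to the trainer.
#' @param k Folds when the dataset has none assigned.
#' @param metrics Metrics to compare.
#' @return List with `fold_results` (per model), `pooled` (long tibble) and
#'   `comparisons` (per metric), of class `cv_result`.
#' @export
cross_validate <- function(dataset, model_specs, config = train_config(),
                           framework = c("cyclegan", "pix2pix"),
                           disc_spec = discriminator_spec(),
                           weights = loss_weights(), k = 5L,
                           metrics = c("ssim", "psnr_db")) {
  framework <- match.arg(framework)
  if (is.null(dataset$fold_of)) dataset <- assign_folds(dataset, k,
                                                        config$seed)
  if (is.null(names(model_specs)))
    names(model_specs) <- paste0("model", seq_along(model_specs))
  folds <- sort(unique(dataset$fold_of))
  ids <- vapply(dataset$samples, function(s) s$sample_id, character(1))
  fold_results <- lapply(model_specs, function(spec) {
    lapply(folds, function(f) {
      val_ids <- names(dataset$fold_of)[dataset$fold_of == f]
      train <- dataset$samples[!(ids %in% val_ids)]
      val <- dataset$samples[ids %in% val_ids]
      seed_all(config$seed + f)
      cfg <- config
      cfg$seed <- config$seed + f
      fit <- if (framework == "pix2pix") {
        train_pix2pix(train, spec, disc_spec, cfg, weights)
      } else {
        train_cyclegan(image_dataset(train), gen_spec = spec,
                       disc_spec = disc_spec, config = cfg,
                       weights = weights)
      }
      evaluate_model(fit$G, val, fold_index = f)
    })
  })
  pooled <- purrr::imap_dfr(fold_results, function(frs, mname) {
    dplyr::mutate(dplyr::bind_rows(lapply(frs, function(fr) fr$per_image)),
                  model = mname)
  })
  comparisons <- if (length(model_specs) >= 2 &&
                       length(unique(pooled$sample_id)) >= 3) {
    compare_models(pooled, metrics)
  } else NULL
  structure(list(fold_results = fold_results, pooled = pooled,
                 comparisons = comparisons), class = "cv_result")
}
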