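# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an FRC curve into a tibble
#'
#' @param x An [frc()] curve.
#' @param ... Unused.
#' @return Tibble with `freq`, `correlation`, `n_samples`.
#' @export
tidy.frc_curve <- function(x, ...) {
  tibble::tibble(freq = x$ring_freqs, correlation = x$correlations,
                 n_samples = x$ring_counts)
}

#' @rdname tidy.frc_curve
#' @export
autoplot.frc_curve <- function(x, ...) {
  ggplot2::ggplot(tidy(x), ggplot2::aes(x = .data$freq,
                                        y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1 / 7, linetype = "dashed") +
    ggplot2::labs(x = "spatial frequency (cycles/pixel)",
                  y = "Fourier ring correlation") +
    ggplot2::theme_minimal()
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An [rm_anova()] result.
#' @param ... Unused.
#' @return One-row tibble with the F statistic, degrees of freedom and p.
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f_stat, df1 = x$df1, df2 = x$df2,
                 p.value = x$p_value, degenerate = x$degenerate)
}

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) tidy(x)

#' Tidy Holm-corrected pairwise tests
#'
#' @param x A [holm_pairwise()] result.
#' @param ... Unused.
#' @return Tibble with one row per model pair: raw and adjusted p.
#' @export
tidy.holm_pairwise <- function(x, ...) x$table

#' Tidy a model comparison (one metric)
#'
#' @param x A `model_comparison` from [compare_models()].
#' @param ... Unused.
#' @return The pairwise table with the metric name attached.
#' @export
tidy.model_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise$table, metric = x$metric_name, .before = 1)
}

#' @rdname tidy.model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  dplyr::mutate(tidy(x$anova), metric = x$metric_name, .before = 1)
}

#' Tidy a fold result
#'
#' @param x A `fold_result` from [evaluate_model()].
#' @param ... Unused.
#' @return The per-image metric tibble.
#' @export
tidy.fold_result <- function(x, ...) x$per_image

#' @rdname tidy.fold_result
#' @export
glance.fold_result <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Plot a microscopy image
#'
#' @param x A [micro_image()].
#' @param ... Unused.
#' @return A ggplot raster plot.
#' @export
autoplot.micro_image <- function(x, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(x$pixels)) - 1L,
                           col = seq_len(ncol(x$pixels)) - 1L)
  df$intensity <- as.vector(t(x$pixels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s/%s)", x$id, x$modality,
                                  x$quality)) +
    ggplot2::theme_void()
}

#' Plot a training history
#'
#' @param history The `history` tibble from [train_pix2pix()] or
#'   [train_cyclegan()].
#' @return A ggplot of loss components over epochs.
#' @export
plot_history <- function(history) {
  keep <- setdiff(names(history), c("epoch", "lr", "val_ssim"))
  long <- tidyr::pivot_longer(history[, c("epoch", keep)], -"epoch",
                              names_to = "term")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}

#' Plot a deviation map
#'
#' @param dev Result of [deviation_map()].
#' @return A ggplot raster of the absolute-deviation map.
#' @export
plot_deviation_map <- function(dev) {
  m <- dev$map
  df <- tidyr::expand_grid(row = seq_len(nrow(m)) - 1L,
                           col = seq_len(ncol(m)) - 1L)
  df$deviation <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$deviation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("deviation score %.4f", dev$score)) +
    ggplot2::theme_void()
}
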