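# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.ssstn_pretrain <- function(x, ...) x$loss_table

#' @export
glance.ssstn_pretrain <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id,
                 train_accuracy = x$train_accuracy,
                 test_accuracy = x$test_accuracy,
                 validation_accuracy = x$validation_accuracy,
                 n_epochs = nrow(x$loss_table),
                 final_loss = x$loss_table$loss[nrow(x$loss_table)])
}

#' @export
tidy.ssstn_transfer <- function(x, ...) {
  tidyr::pivot_longer(x$loss_table, cols = c("style", "content",
                                             "semantic", "total"),
                      names_to = "component", values_to = "loss")
}

#' @export
glance.ssstn_transfer <- function(x, ...) {
  n <- nrow(x$loss_table)
  tibble::tibble(variant = x$variant, n_epochs = n,
                 first_total = x$loss_table$total[1L],
                 final_total = x$loss_table$total[n],
                 alpha = x$bundle$weights$alpha,
                 beta_w = x$bundle$weights$beta_w,
                 gamma = x$bundle$weights$gamma)
}

#' @export
tidy.ssstn_eval <- function(x, ...) x$records

#' @export
glance.ssstn_eval <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, accuracy = x$accuracy,
                 source_path_accuracy = x$source_path_accuracy,
                 target_path_accuracy = x$target_path_accuracy,
                 pre_transfer_accuracy = x$pre_transfer_accuracy,
                 n_trials = nrow(x$records))
}

#' @export
autoplot.ssstn_pretrain <- function(object, ...) {
  ggplot2::ggplot(object$loss_table,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "classification loss",
                  title = sprintf("Pretraining, subject %s",
                                  object$subject_id)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ssstn_transfer <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = sprintf("Generator training (%s)",
                                  object$variant)) +
    ggplot2::theme_minimal()
}

#' Plot one channel of a scalogram as a time-frequency image
#'
#' @param x A `scalogram` (from [epoch_to_scalogram()]) or a
#'   `scalogram_set`.
#' @param trial Trial index when `x` is a set.
#' @param channel Electrode index to display.
#' @return A ggplot object.
#' @export
plot_scalogram <- function(x, trial = 1L, channel = 1L) {
  if (inherits(x, "scalogram_set")) {
    vals <- x$images[trial, channel, , ]
    freqs <- x$freqs_hz
    times <- x$times_s
  } else if (inherits(x, "scalogram")) {
    vals <- x$values[channel, , ]
    freqs <- x$freqs_hz
    times <- x$times_s
  } else {
    abort_arg("`x` must be a scalogram or scalogram_set.")
  }
  df <- tibble::tibble(
    freq_hz = rep(freqs, times = length(times)),
    time_s = rep(times, each = length(freqs)),
    power = as.numeric(vals))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "|CWT|") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scalogram <- function(object, channel = 1L, ...) {
  plot_scalogram(object, channel = channel)
}
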