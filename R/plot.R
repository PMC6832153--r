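# ggplot2 visualization methods. ggplot2 is a suggested dependency; every
# function checks for it at call time.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    mp_abort("ggplot2 is required for plotting", "parameter")
  }
}

#' Plot a scalogram
#'
#' Time-frequency magnitude raster with a logarithmic frequency axis.
#' @param object A `scalogram` from [morse_cwt()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scalogram <- function(object, ...) {
  need_ggplot()
  df <- expand.grid(time = object$times, freq = object$freqs)
  df$magnitude <- as.vector(t(object$magnitude))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "|W|") +
    ggplot2::theme_minimal()
}

#' Plot a trial image
#'
#' @param object A `trial_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trial_image <- function(object, ...) {
  need_ggplot()
  px <- object$pixels
  df <- expand.grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$value <- as.vector(px)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time ->", y = "frequency x source", fill = NULL,
                  title = sprintf("trial %s window %s (class %s)",
                                  object$trial_id, object$window_index, object$label)) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Train and validation accuracy (and loss) per epoch.
#' @param object A trained `cnn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cnn_model <- function(object, ...) {
  need_ggplot()
  h <- object$history
  mp_assert(nrow(h) > 0, "model has no training history", "parameter")
  long <- rbind(data.frame(epoch = h$epoch, metric = "train accuracy", value = h$accuracy),
                data.frame(epoch = h$epoch, metric = "validation accuracy",
                           value = h$val_accuracy))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "epoch", y = "accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an MRIC template and optional source profiles
#'
#' @param object An `mric_template`.
#' @param profiles Optional named list of `spectral_profile` objects drawn
#'   alongside the template.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mric_template <- function(object, profiles = NULL, ...) {
  need_ggplot()
  df <- data.frame(freq = object$freqs, density = object$weight, what = "template")
  for (nm in names(profiles)) {
    df <- rbind(df, data.frame(freq = profiles[[nm]]$freqs,
                               density = profiles[[nm]]$power, what = nm))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$density,
                                   colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "normalized power", colour = NULL) +
    ggplot2::theme_minimal()
}
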