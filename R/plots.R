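#' Plot a hypnogram
#'
#' Step plot of the per-epoch stage labels over time, with ERR epochs shown
#' as gaps.
#'
#' @param labeled Tibble from [classify_epochs()] (or any tibble with
#'   `t_start_s` and `label`).
#' @param epoch_len_s Epoch length in seconds.
#' @return A ggplot object.
#' @export
plot_hypnogram <- function(labeled, epoch_len_s = 8) {
  df <- dplyr::mutate(
    labeled,
    stage = factor(as.character(.data$label), levels = c("QS", "PS", "AW")),
    t_min = .data$t_start_s / 60
  ) |>
    dplyr::filter(!is.na(.data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$stage)) +
    ggplot2::geom_step(ggplot2::aes(group = 1), linewidth = 0.3) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "time (min)", y = NULL, title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' Plot HRV segments over time
#'
#' LF and HF band powers (log scale) of each 16 s segment, colored by the
#' assigned sleep stage.
#'
#' @param result A `somnark_result`.
#' @return A ggplot object.
#' @export
plot_hrv_segments <- function(result) {
  seg <- result$hrv_segments |>
    tidyr::pivot_longer(c("lf_ms2", "hf_ms2"), names_to = "band",
                        values_to = "power")
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$t_start_s / 60,
                                    y = .data$power,
                                    color = .data$stage)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~band, ncol = 1,
                        labeller = ggplot2::as_labeller(
                          c(lf_ms2 = "LF (0.06-0.6 Hz)",
                            hf_ms2 = "HF (0.6-2.4 Hz)"))) +
    ggplot2::labs(x = "time (min)", y = "band power (ms²)",
                  color = "stage") +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' For a pipeline result, the hypnogram; for a stage-conditioned HRV
#' summary, per-stratum log LF and log HF bars.
#'
#' @param object A `somnark_result` or `somnark_stagehrv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot somnark_result
#' @export
autoplot.somnark_result <- function(object, ...) {
  plot_hypnogram(object$labeled, object$config$epoch_len_s)
}

#' @rdname autoplot.somnark_result
#' @method autoplot somnark_stagehrv
#' @export
autoplot.somnark_stagehrv <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("log_lf", "log_hf", "log_lfhf"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$value,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "ln(ms²)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
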