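#' Plot normalised timecourses by dose group
#'
#' Group-mean normalised traces (one line per dose) with per-well traces
#' shown faintly behind, the standard presentation of ECIS dose-response
#' timecourses.
#'
#' @param data long table with columns `time_h`, `well`, `dose_uM`,
#'   `value` (e.g. the `normalized_traces` element of [run_pipeline()],
#'   filtered to one quantity).
#' @param log_scale plot `log10(value)`.
#' @return A ggplot object.
#' @export
plot_normalized_traces <- function(data, log_scale = FALSE) {
  require_columns(data, c("time_h", "well", "dose_uM", "value"))
  df <- as_tibble(data)
  if (log_scale) df <- mutate(df, value = log10(.data$value))
  means <- df %>%
    group_by(.data$dose_uM, .data$time_h) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot(df, aes(x = .data$time_h, y = .data$value,
                 colour = factor(.data$dose_uM))) +
    geom_line(aes(group = .data$well), alpha = 0.25, linewidth = 0.3) +
    geom_line(data = means, linewidth = 0.9) +
    labs(x = "Time post-treatment (h)",
         y = if (log_scale) "log10 normalised value" else "Normalised value",
         colour = "Dose (µM)") +
    theme_minimal()
}

#' Plot Mito-Stress metrics by dose
#'
#' @param metrics per-well metric table from [mito_metrics_by_well()].
#' @return A ggplot object: one panel per metric, points per well with
#'   group-mean bars.
#' @export
plot_mito_metrics <- function(metrics) {
  require_columns(metrics, c("dose_uM", "basal_ocr", "atp_linked_ocr",
                             "maximal_ocr"))
  long <- as_tibble(metrics) %>%
    tidyr::pivot_longer(c("basal_ocr", "atp_linked_ocr", "maximal_ocr"),
                        names_to = "metric", values_to = "ocr")
  ggplot(long, aes(x = factor(.data$dose_uM), y = .data$ocr)) +
    stat_summary(fun = mean, geom = "col", fill = "grey80") +
    geom_point(alpha = 0.7) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Dose (µM)", y = "OCR (pmol O2/min)") +
    theme_minimal()
}
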