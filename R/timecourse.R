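#' Ratio spectrum between cell-covered and cell-free wells
#'
#' Per-frequency ratio of group means (cell-covered divided by cell-free) of
#' either impedance magnitude, series resistance or series capacitance, at a
#' single timepoint. This is the spectrum used to choose the working
#' frequency for each quantity: impedance magnitude peaks at the frequency
#' giving the largest cell/cell-free contrast, resistance peaks lower, and
#' capacitance contrast is strongest at the top of the grid.
#'
#' @param cell_wells,cellfree_wells long impedance records (columns
#'   `time_h`, `well`, `frequency_hz`, `z_real_ohm`, `z_imag_ohm`) for the
#'   two groups.
#' @param quantity one of `"impedance_magnitude"`, `"resistance"`,
#'   `"capacitance"`.
#' @param at_time timepoint (h) at which to evaluate; rows with `time_h`
#'   nearest to it within `time_tol` are used.
#' @param time_tol matching tolerance in hours.
#' @return Tibble of class `ecis_ratio_spectrum` with columns
#'   `frequency_hz`, `ratio`, `quantity`. Frequencies missing from either
#'   group are omitted with a warning.
#' @export
ratio_spectrum <- function(cell_wells, cellfree_wells,
                           quantity = c("impedance_magnitude", "resistance",
                                        "capacitance"),
                           at_time = 0, time_tol = 1e-6) {
  quantity <- match.arg(quantity)
  if (nrow(cell_wells) == 0 || nrow(cellfree_wells) == 0)
    abort("Both groups must contain at least one well.")

  group_mean <- function(data) {
    require_columns(data, c("time_h", "frequency_hz", "z_real_ohm", "z_imag_ohm"))
    data <- dplyr::filter(as_tibble(data),
                          abs(.data$time_h - at_time) <= time_tol)
    if (nrow(data) == 0) abort("No records at the requested time.")
    data <- add_series_rc(data)
    data <- mutate(data,
                   value = switch(quantity,
                                  impedance_magnitude =
                                    sqrt(.data$z_real_ohm^2 + .data$z_imag_ohm^2),
                                  resistance = .data$resistance_ohm,
                                  capacitance = .data$capacitance_f))
    data %>%
      group_by(.data$frequency_hz) %>%
      summarise(value = mean(.data$value), .groups = "drop")
  }

  num <- group_mean(cell_wells)
  den <- group_mean(cellfree_wells)
  joint <- dplyr::inner_join(num, den, by = "frequency_hz",
                             suffix = c("_cell", "_free"))
  dropped <- setdiff(union(num$frequency_hz, den$frequency_hz),
                     joint$frequency_hz)
  if (length(dropped))
    warn(paste0("Frequencies missing from one group omitted: ",
                paste(dropped, collapse = ", "), " Hz."))
  out <- joint %>%
    mutate(ratio = .data$value_cell / .data$value_free,
           quantity = quantity) %>%
    select("frequency_hz", "ratio", "quantity") %>%
    arrange(.data$frequency_hz)
  class(out) <- c("ecis_ratio_spectrum", class(out))
  out
}

#' Select the working frequency from a ratio spectrum
#'
#' Returns the grid frequency attaining the extremum of the ratio. Ties are
#' broken toward the lower frequency.
#'
#' @param spec an [ratio_spectrum()] result (or any tibble with
#'   `frequency_hz` and `ratio`).
#' @param objective `"maximize"` or `"minimize"`.
#' @return A single frequency in Hz.
#' @export
select_frequency <- function(spec, objective = c("maximize", "minimize")) {
  objective <- match.arg(objective)
  require_columns(spec, c("frequency_hz", "ratio"))
  if (nrow(spec) == 0) abort("Empty spectrum.")
  spec <- dplyr::arrange(as_tibble(spec), .data$frequency_hz)
  idx <- if (objective == "maximize") which.max(spec$ratio) else which.min(spec$ratio)
  spec$frequency_hz[idx]
}

#' Normalise a timecourse to its value at treatment time
#'
#' Divides every value of a trace by its value at `t0` (treatment
#' application), optionally taking `log10`. At `t0` the normalised value is
#' exactly 1 (0 on the log scale). Respects `dplyr` grouping, so a grouped
#' long table is normalised per well/trace.
#'
#' @param data a data frame (possibly grouped) with a time column and a
#'   value column.
#' @param value column to normalise (tidy-eval; default `value`).
#' @param time column of times in hours (default `time_h`).
#' @param t0 reference time (h), default 0; must be present in every group's
#'   time grid (within `tol`).
#' @param log_scale if `TRUE`, return `log10` of the ratio.
#' @param tol tolerance for locating `t0` on the time grid.
#' @return The input tibble with `value` replaced by the normalised trace.
#' @export
normalize_trace <- function(data, value = value, time = time_h, t0 = 0,
                            log_scale = FALSE, tol = 1e-6) {
  value <- enquo(value)
  time <- enquo(time)
  norm_one <- function(df, ...) {
    tt <- dplyr::pull(df, !!time)
    vv <- dplyr::pull(df, !!value)
    i <- which(abs(tt - t0) <= tol)
    if (length(i) == 0) abort("`t0` is not on the time grid.")
    base <- vv[i[1]]
    if (!is.finite(base) || base == 0) abort("Baseline value at `t0` is zero or missing.")
    out <- vv / base
    if (log_scale) out <- log10(out)
    dplyr::mutate(df, !!value := out)
  }
  if (dplyr::is_grouped_df(data)) {
    gv <- dplyr::group_vars(data)
    data %>% dplyr::group_modify(norm_one) %>% dplyr::group_by(across(all_of(gv)))
  } else {
    norm_one(as_tibble(data))
  }
}

#' Area under a timecourse by the trapezoid rule
#'
#' Trapezoidal integral of a (possibly non-uniformly sampled) trace over
#' `[t_start, t_end]`. Window endpoints off the sample grid are linearly
#' interpolated, which makes the integral exactly additive over adjacent
#' windows. Exact for traces that are piecewise linear between samples.
#'
#' @param data data frame with time and value columns.
#' @param value,time tidy-eval column selections (defaults `value`,
#'   `time_h`).
#' @param t_start,t_end integration window in hours; must lie within the
#'   trace support. Defaults to the full trace.
#' @return A tibble with columns `auc` ((units of trace) x h), `t_start`,
#'   `t_end`, `method`.
#' @export
area_under_curve <- function(data, value = value, time = time_h,
                             t_start = NULL, t_end = NULL) {
  value <- enquo(value)
  time <- enquo(time)
  auc_one <- function(df, ...) {
    tt <- dplyr::pull(df, !!time)
    vv <- dplyr::pull(df, !!value)
    o <- order(tt)
    tt <- tt[o]; vv <- vv[o]
    a <- if (is.null(t_start)) tt[1] else t_start
    b <- if (is.null(t_end)) tt[length(tt)] else t_end
    if (a >= b) abort("`t_start` must be below `t_end`.")
    if (a < tt[1] - 1e-9 || b > tt[length(tt)] + 1e-9)
      abort("Integration window lies outside the trace support.")
    keep <- tt > a & tt < b
    ga <- approx(tt, vv, xout = a)$y
    gb <- approx(tt, vv, xout = b)$y
    x <- c(a, tt[keep], b)
    y <- c(ga, vv[keep], gb)
    tibble(auc = sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2),
           t_start = a, t_end = b, method = "trapezoid")
  }
  if (dplyr::is_grouped_df(data)) {
    data %>% dplyr::group_modify(auc_one) %>% ungroup()
  } else {
    auc_one(as_tibble(data))
  }
}

#' Earliest sustained-confluency time from a 64 kHz capacitance trace
#'
#' A well counts as confluent once its high-frequency series capacitance
#' drops strictly below `threshold_nF` (default 20 nF) and stays below it
#' for a dwell period (default 1 h), which suppresses noise-triggered
#' gating. Values exactly at the threshold do not qualify.
#'
#' @param data data frame with time and capacitance columns.
#' @param capacitance,time tidy-eval column selections (defaults
#'   `capacitance_f` in farad, `time_h`).
#' @param threshold_nF confluency threshold in nF.
#' @param dwell_h minimum time the trace must remain below threshold.
#' @return The earliest qualifying time in hours, or `NA_real_` if the well
#'   never qualifies.
#' @export
confluency_gate <- function(data, capacitance = capacitance_f, time = time_h,
                            threshold_nF = 20, dwell_h = 1) {
  capacitance <- enquo(capacitance)
  time <- enquo(time)
  df <- as_tibble(data)
  if (nrow(df) == 0) abort("Empty capacitance trace.")
  tt <- dplyr::pull(df, !!time)
  cc <- dplyr::pull(df, !!capacitance) * 1e9  # F -> nF
  o <- order(tt)
  tt <- tt[o]; cc <- cc[o]
  below <- cc < threshold_nF
  for (i in which(below)) {
    if (tt[length(tt)] < tt[i] + dwell_h) break  # dwell not observable
    window <- tt >= tt[i] & tt <= tt[i] + dwell_h
    if (all(below[window])) return(tt[i])
  }
  NA_real_
}

#' Time at which a trace first reaches its final plateau
#'
#' The plateau level is estimated as the mean of the trace over its last
#' `plateau_window` hours (which averages out measurement noise); the
#' function returns the first time the trace comes within a relative
#' tolerance of that level. Used to time the arrival of a normalised
#' resistance trace at its post-collapse minimum.
#'
#' @param data data frame with time and value columns.
#' @param value,time tidy-eval column selections (defaults `value`,
#'   `time_h`).
#' @param tol relative tolerance (default 0.01, i.e. within 1% of plateau).
#' @param plateau_window trailing window (h) whose mean defines the plateau
#'   level.
#' @return Time (same units as the time column) of plateau arrival;
#'   `NA_real_` if the trace never comes within tolerance.
#' @export
time_to_plateau <- function(data, value = value, time = time_h, tol = 0.01,
                            plateau_window = 2) {
  value <- enquo(value)
  time <- enquo(time)
  df <- as_tibble(data)
  tt <- dplyr::pull(df, !!time)
  vv <- dplyr::pull(df, !!value)
  o <- order(tt)
  tt <- tt[o]; vv <- vv[o]
  final <- mean(vv[tt >= tt[length(tt)] - plateau_window])
  within <- abs(vv - final) <= tol * abs(final)
  if (!any(within)) return(NA_real_)
  tt[which(within)[1]]
}

#' Significance stars for a p-value
#'
#' The conventional four-level annotation with inclusive thresholds:
#' `****` for p <= 1e-4, `***` for p <= 1e-3, `**` for p <= 0.01,
#' `*` for p <= 0.05, `"ns"` otherwise.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Character vector of star strings.
#' @export
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare dose groups by one-way ANOVA with Tukey HSD
#'
#' For endpoint or AUC summaries: one-way ANOVA across groups followed by
#' Tukey's honestly-significant-difference post-hoc test for all pairwise
#' contrasts (Tukey-Kramer for unequal group sizes, as provided by
#' [stats::TukeyHSD()]). With exactly two groups a two-tailed Welch t-test
#' is also reported. Star annotations follow the four inclusive thresholds
#' of [p_stars()].
#'
#' @param data data frame with one row per well.
#' @param value,group tidy-eval columns holding the response and the group
#'   label (defaults `value`, `group`).
#' @param design label recorded in the output (`"endpoint"` or `"auc"`).
#' @return Object of class `ecis_comparison` with [tidy()] (pairwise table)
#'   and [glance()] (omnibus ANOVA) methods.
#' @export
compare_groups <- function(data, value = value, group = group,
                           design = c("endpoint", "auc")) {
  design <- match.arg(design)
  value <- enquo(value)
  group <- enquo(group)
  df <- tibble(value = dplyr::pull(data, !!value),
               group = factor(dplyr::pull(data, !!group)))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$group)) < 2)
    abort("Need at least 2 groups.")
  df$group <- droplevels(df$group)
  counts <- table(df$group)
  if (any(counts < 2)) abort("Need at least 2 replicates per group.")
  degenerate <- length(unique(df$value)) == 1
  if (degenerate) {
    # all observations identical: no evidence of any difference
    combs <- utils::combn(levels(df$group), 2)
    pairwise <- tibble(
      contrast = paste(combs[2, ], combs[1, ], sep = "-"),
      estimate = 0, conf_low = 0, conf_high = 0, p_adj = 1, stars = "ns"
    )
    return(structure(
      list(design = design, statistic = 0, p_value = 1, stars = "ns",
           pairwise = pairwise, t_test = NULL, degenerate_variance = TRUE,
           groups = levels(df$group),
           n = as.integer(table(df$group))),
      class = "ecis_comparison"
    ))
  }

  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  f_stat <- an$`F value`[1]
  p_omni <- an$`Pr(>F)`[1]
  tk <- TukeyHSD(fit)$group
  pairwise <- tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"],
    stars = p_stars(tk[, "p adj"])
  )
  t_two <- NULL
  if (nlevels(df$group) == 2) {
    tt <- t.test(value ~ group, data = df)
    t_two <- tibble(statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  structure(
    list(design = design, statistic = f_stat, p_value = p_omni,
         stars = p_stars(p_omni), pairwise = pairwise, t_test = t_two,
         degenerate_variance = isTRUE(degenerate),
         groups = levels(df$group), n = as.integer(counts)),
    class = "ecis_comparison"
  )
}

#' @rdname compare_groups
#' @param x an `ecis_comparison` object.
#' @param ... unused.
#' @method tidy ecis_comparison
#' @export
tidy.ecis_comparison <- function(x, ...) {
  mutate(x$pairwise, design = x$design)
}

#' @rdname compare_groups
#' @method glance ecis_comparison
#' @export
glance.ecis_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, stars = x$stars,
         design = x$design, n_groups = length(x$groups),
         degenerate_variance = x$degenerate_variance)
}

#' @export
print.ecis_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s design): F = %.4g, p = %.3g %s\n",
              x$design, x$statistic, x$p_value, x$stars))
  if (x$degenerate_variance) cat("  [degenerate: zero variance in all groups]\n")
  print(x$pairwise)
  invisible(x)
}

#' Plot a ratio spectrum
#'
#' @param object an [ratio_spectrum()] result.
#' @param ... unused.
#' @return A ggplot object with the selected extremum highlighted.
#' @method autoplot ecis_ratio_spectrum
#' @export
autoplot.ecis_ratio_spectrum <- function(object, ...) {
  objective <- if (object$quantity[1] == "capacitance") "minimize" else "maximize"
  fsel <- select_frequency(object, objective)
  ggplot(object, aes(x = .data$frequency_hz, y = .data$ratio)) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = fsel, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "Frequency (Hz)", y = "Ratio (cell / cell-free)",
         title = paste0(object$quantity[1], " ratio spectrum"),
         subtitle = paste0("selected frequency: ", fsel, " Hz")) +
    theme_minimal()
}
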