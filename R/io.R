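#' Read long-format multifrequency impedance records
#'
#' Strict reader for the package's CSV interchange format: UTF-8,
#' comma-separated, `.` decimal, one row per (well, time, frequency) with
#' columns `time_h` (decimal hours, treatment at 0), `well`, `group`,
#' `frequency_hz`, `z_real_ohm`, `z_imag_ohm` (an optional `dose_uM` column
#' is kept). Schema violations are reported by column; duplicate
#' (well, time, frequency) rows are rejected.
#'
#' @param path CSV file path.
#' @return Tibble of validated impedance records.
#' @export
read_impedance_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("time_h", "well", "group", "frequency_hz",
                "z_real_ohm", "z_imag_ohm")
  require_columns(data, required)
  numeric_cols <- c("time_h", "frequency_hz", "z_real_ohm", "z_imag_ohm")
  for (col in numeric_cols) {
    if (!is.numeric(data[[col]]))
      abort(paste0("Column `", col, "` must be numeric."))
    bad <- which(!is.finite(data[[col]]))
    if (length(bad))
      abort(paste0("Column `", col, "` has non-finite values at row(s): ",
                   paste(head(bad, 5), collapse = ", "), "."))
  }
  if (any(data$frequency_hz <= 0)) abort("Column `frequency_hz` must be > 0.")
  dup <- duplicated(data[c("well", "time_h", "frequency_hz")])
  if (any(dup))
    abort(paste0("Duplicate (well, time, frequency) record(s) at row(s): ",
                 paste(head(which(dup), 5), collapse = ", "), "."))
  keep <- intersect(names(data), c(required, "dose_uM"))
  as_tibble(data)[keep]
}

#' Write impedance records to the package CSV format
#'
#' @param data impedance records (see [read_impedance_csv()] for the
#'   schema).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_impedance_csv <- function(data, path) {
  require_columns(data, c("time_h", "well", "group", "frequency_hz",
                          "z_real_ohm", "z_imag_ohm"))
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read Mito-Stress OCR traces
#'
#' CSV with columns `time_min`, `well`, `dose_uM`, `ocr_pmol_min`.
#'
#' @param path CSV file path.
#' @return Tibble of OCR records.
#' @export
read_ocr_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(data, c("time_min", "well", "dose_uM", "ocr_pmol_min"))
  as_tibble(data)
}

#' Run the full simulate -> deconvolve -> analyse pipeline
#'
#' End-to-end orchestration of a synthetic ECIS experiment: simulates the
#' study, selects working frequencies from the pre-treatment ratio spectra
#' (unless fixed), gates wells for confluency, builds normalised
#' resistance/capacitance timecourses and their AUCs, runs the dose-group
#' statistics, deconvolves the multifrequency spectra into Rb/alpha/Cm
#' traces with modelability masks, and computes Mito-Stress and LDH
#' endpoints. Artifacts are written to `outdir` as tidy CSVs plus a JSON
#' run summary carrying the provenance (seed, key configuration values,
#' selected frequencies, gate times).
#'
#' @param config an [synthetic_config()].
#' @param seed integer seed controlling every random draw.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param frequency `"auto"` to select analysis frequencies from the ratio
#'   spectra, or a fixed frequency in Hz to use for both resistance and
#'   impedance analysis.
#' @param deconvolve run the (slower) per-timepoint barrier-parameter
#'   deconvolution stage.
#' @return A list of result tables (invisibly written to `outdir`):
#'   `selected_frequencies`, `gate_times`, `normalized_traces`, `stats`,
#'   `deconvolution` (or `NULL`), `mito_metrics`, `ldh`, `provenance`.
#' @export
run_pipeline <- function(config = synthetic_config(), seed = 1,
                         outdir = NULL, frequency = "auto",
                         deconvolve = TRUE) {
  exp <- simulate_experiment(config, seed = seed)
  imp <- exp$impedance
  if (nrow(imp) == 0) abort("Simulation produced no impedance records.")
  cells <- dplyr::filter(imp, .data$group != "cell_free")
  free <- dplyr::filter(imp, .data$group == "cell_free")

  # frequency selection from pre-treatment spectra (t = 0, control group)
  ctrl0 <- dplyr::filter(cells, .data$dose_uM == 0)
  if (identical(frequency, "auto")) {
    f_z <- select_frequency(
      ratio_spectrum(ctrl0, free, "impedance_magnitude", at_time = 0), "maximize")
    f_r <- select_frequency(
      ratio_spectrum(ctrl0, free, "resistance", at_time = 0), "maximize")
  } else {
    f_z <- f_r <- as.numeric(frequency)
  }
  f_c <- max(config$frequencies_hz)  # capacitance read at the top of the grid
  selected <- tibble(quantity = c("impedance_magnitude", "resistance",
                                  "capacitance"),
                     frequency_hz = c(f_z, f_r, f_c))

  rc <- add_series_rc(cells)

  # confluency gate per well on the 64 kHz capacitance trace
  gates <- rc %>%
    dplyr::filter(.data$frequency_hz == f_c) %>%
    group_by(.data$well, .data$dose_uM) %>%
    dplyr::group_modify(~ tibble(gate_time_h = confluency_gate(.x))) %>%
    ungroup()

  # normalised R (at f_r) and C (at f_c) traces, treatment-relative
  norm_r <- rc %>%
    dplyr::filter(.data$frequency_hz == f_r, .data$time_h >= 0) %>%
    select("time_h", "well", "dose_uM", value = "resistance_ohm") %>%
    group_by(.data$well, .data$dose_uM) %>%
    normalize_trace() %>%
    ungroup() %>%
    mutate(quantity = "resistance", frequency_hz = f_r)
  norm_c <- rc %>%
    dplyr::filter(.data$frequency_hz == f_c, .data$time_h >= 0) %>%
    select("time_h", "well", "dose_uM", value = "capacitance_f") %>%
    group_by(.data$well, .data$dose_uM) %>%
    normalize_trace() %>%
    ungroup() %>%
    mutate(quantity = "capacitance", frequency_hz = f_c)
  norm <- bind_rows(norm_r, norm_c)

  # endpoint + AUC statistics per quantity
  stat_rows <- list()
  for (q in unique(norm$quantity)) {
    tr <- dplyr::filter(norm, .data$quantity == q)
    endpoint <- tr %>%
      group_by(.data$well, .data$dose_uM) %>%
      summarise(value = .data$value[which.max(.data$time_h)], .groups = "drop")
    aucs <- tr %>%
      group_by(.data$well, .data$dose_uM) %>%
      area_under_curve()
    cmp_end <- compare_groups(endpoint, value, dose_uM, design = "endpoint")
    cmp_auc <- compare_groups(dplyr::rename(aucs, value = "auc"),
                              value, dose_uM, design = "auc")
    stat_rows[[length(stat_rows) + 1]] <-
      mutate(tidy(cmp_end), quantity = q, measure = "endpoint")
    stat_rows[[length(stat_rows) + 1]] <-
      mutate(tidy(cmp_auc), quantity = q, measure = "auc")
  }
  stats_tbl <- bind_rows(stat_rows) %>%
    select("quantity", "measure", "contrast", "estimate", "p_adj", "stars")

  decon <- NULL
  if (deconvolve) {
    decon <- deconvolve_timecourse(imp)
  }

  ocr <- simulate_ocr(doses_uM = config$doses_uM,
                      wells_per_group = config$wells_per_group, seed = seed)
  mito <- mito_metrics_by_well(ocr$traces, ocr$schedule)
  ldh <- ldh_plate_cytotoxicity(
    simulate_ldh(doses_uM = config$doses_uM,
                 wells_per_group = config$wells_per_group, seed = seed))

  provenance <- list(
    seed = seed,
    doses_uM = config$doses_uM,
    wells_per_group = config$wells_per_group,
    noise_fraction = config$noise_fraction,
    selected_frequencies = setNames(as.list(selected$frequency_hz),
                                    selected$quantity),
    gate_times_h = setNames(as.list(gates$gate_time_h), gates$well),
    package_version = as.character(utils::packageVersion("ecisbarrier"))
  )

  result <- list(selected_frequencies = selected, gate_times = gates,
                 normalized_traces = norm, stats = stats_tbl,
                 deconvolution = decon, mito_metrics = mito, ldh = ldh,
                 provenance = provenance, experiment = exp)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_impedance_csv(imp, file.path(outdir, "impedance.csv"))
    readr::write_csv(selected, file.path(outdir, "selected_frequencies.csv"))
    readr::write_csv(gates, file.path(outdir, "gate_times.csv"))
    readr::write_csv(norm, file.path(outdir, "normalized_traces.csv"))
    readr::write_csv(stats_tbl, file.path(outdir, "stats.csv"))
    if (!is.null(decon))
      readr::write_csv(as_tibble(decon), file.path(outdir, "deconvolution.csv"))
    readr::write_csv(mito, file.path(outdir, "mito_metrics.csv"))
    readr::write_csv(ldh, file.path(outdir, "ldh.csv"))
    jsonlite::write_json(provenance, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
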