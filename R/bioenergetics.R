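#' Segment a Mito-Stress OCR trace into phase summary values
#'
#' Partitions an oxygen-consumption-rate trace at the injection times of the
#' standard Mito-Stress sequence (oligomycin, then FCCP, then
#' rotenone/antimycin) and summarises each phase with the usual
#' conventions: `basal_raw` is the last pre-oligomycin reading, `post_oligo`
#' the minimum between oligomycin and FCCP, `maximal_raw` the maximum
#' between FCCP and rotenone/antimycin, and `non_mito` the mean after
#' rotenone/antimycin.
#'
#' @param trace data frame with columns `time_min`, `ocr_pmol_min` (one
#'   well).
#' @param schedule data frame with columns `event`
#'   (`oligomycin`, `FCCP`, `rotenone_antimycin`) and `time_min`; events
#'   must occur in that order.
#' @return Tibble with columns `basal_raw`, `post_oligo`, `maximal_raw`,
#'   `non_mito` (pmol O2/min).
#' @export
segment_phases <- function(trace, schedule) {
  require_columns(trace, c("time_min", "ocr_pmol_min"))
  require_columns(schedule, c("event", "time_min"))
  wanted <- c("oligomycin", "FCCP", "rotenone_antimycin")
  missing <- setdiff(wanted, schedule$event)
  if (length(missing))
    abort(paste0("Injection schedule is missing: ",
                 paste(missing, collapse = ", "), "."))
  times <- setNames(schedule$time_min[match(wanted, schedule$event)], wanted)
  if (is.unsorted(times, strictly = TRUE))
    abort("Injections must occur in the order oligomycin -> FCCP -> rotenone_antimycin.")
  tt <- trace$time_min
  oc <- trace$ocr_pmol_min
  phase <- list(
    basal = oc[tt < times["oligomycin"]],
    post_oligo = oc[tt > times["oligomycin"] & tt < times["FCCP"]],
    maximal = oc[tt > times["FCCP"] & tt < times["rotenone_antimycin"]],
    non_mito = oc[tt > times["rotenone_antimycin"]]
  )
  empty <- names(phase)[lengths(phase) == 0]
  if (length(empty))
    abort(paste0("No measurement cycles in phase(s): ",
                 paste(empty, collapse = ", "), "."))
  tibble(
    basal_raw = phase$basal[length(phase$basal)],
    post_oligo = min(phase$post_oligo),
    maximal_raw = max(phase$maximal),
    non_mito = mean(phase$non_mito)
  )
}

#' Mito-Stress respiration metrics from phase summaries
#'
#' Converts the four phase values into the standard corrected metrics:
#' `basal = basal_raw - non_mito` (non-mitochondrial OCR subtracted),
#' `atp_linked = basal_raw - post_oligo` (respiration abolished by ATP
#' synthase inhibition) and `maximal = maximal_raw - non_mito`
#' (FCCP-uncoupled capacity). Negative corrected values are clipped at 0
#' with a warning.
#'
#' @param phases a one-or-more-row data frame as returned by
#'   [segment_phases()] (extra id columns are carried through).
#' @return The input with columns `basal_ocr`, `atp_linked_ocr`,
#'   `maximal_ocr`, `non_mito_ocr` appended.
#' @export
compute_mito_metrics <- function(phases) {
  require_columns(phases, c("basal_raw", "post_oligo", "maximal_raw",
                            "non_mito"))
  out <- as_tibble(phases) %>%
    mutate(non_mito_ocr = .data$non_mito,
           basal_ocr = .data$basal_raw - .data$non_mito,
           atp_linked_ocr = .data$basal_raw - .data$post_oligo,
           maximal_ocr = .data$maximal_raw - .data$non_mito)
  neg <- c("basal_ocr", "atp_linked_ocr", "maximal_ocr")
  if (any(unlist(out[neg]) < 0, na.rm = TRUE)) {
    warn("Negative corrected OCR metric(s) clipped at 0.")
    out <- mutate(out, across(all_of(neg), ~ pmax(., 0)))
  }
  out
}

#' Per-well Mito-Stress metrics for a whole plate
#'
#' Convenience wrapper applying [segment_phases()] and
#' [compute_mito_metrics()] to every well of a long OCR table, optionally
#' normalising each metric to the control-group mean.
#'
#' @param traces long OCR table (`time_min`, `well`, `dose_uM`,
#'   `ocr_pmol_min`).
#' @param schedule injection schedule (see [segment_phases()]).
#' @param normalize_to_control divide each metric by the mean of the
#'   `control_dose` group.
#' @param control_dose dose labelling the control group.
#' @return Tibble: one row per well with dose and the four metrics.
#' @export
mito_metrics_by_well <- function(traces, schedule,
                                 normalize_to_control = FALSE,
                                 control_dose = 0) {
  require_columns(traces, c("time_min", "well", "dose_uM", "ocr_pmol_min"))
  out <- as_tibble(traces) %>%
    group_by(.data$well, .data$dose_uM) %>%
    dplyr::group_modify(~ segment_phases(.x, schedule)) %>%
    ungroup() %>%
    compute_mito_metrics()
  if (normalize_to_control) {
    metrics <- c("basal_ocr", "atp_linked_ocr", "maximal_ocr")
    ctrl <- dplyr::filter(out, .data$dose_uM == control_dose)
    if (nrow(ctrl) == 0) abort("No control-group wells to normalise to.")
    for (m in metrics) out[[m]] <- out[[m]] / mean(ctrl[[m]])
  }
  out
}

#' LDH cytotoxicity percentage
#'
#' Control-corrected release fraction:
#' `100 * (sample - spontaneous) / (maximum - spontaneous)`, where
#' `spontaneous` and `maximum` are the mean absorbances of the
#' spontaneous-release and lysed maximum-release control wells.
#'
#' @param sample sample absorbance(s), vectorised.
#' @param spontaneous spontaneous-release control level (scalar mean).
#' @param maximum maximum-release control level; must exceed `spontaneous`.
#' @return Cytotoxicity percentage(s).
#' @export
ldh_cytotoxicity <- function(sample, spontaneous, maximum) {
  if (maximum <= spontaneous)
    abort("`maximum` release must exceed `spontaneous` release.")
  100 * (sample - spontaneous) / (maximum - spontaneous)
}

#' Cytotoxicity per dose group from an LDH plate
#'
#' @param plate tibble as produced by [simulate_ldh()] (columns `well`,
#'   `role`, `dose_uM`, `absorbance`).
#' @return Tibble with one row per sample well: `well`, `dose_uM`,
#'   `cytotoxicity_percent`.
#' @export
ldh_plate_cytotoxicity <- function(plate) {
  require_columns(plate, c("well", "role", "dose_uM", "absorbance"))
  spont <- mean(plate$absorbance[plate$role == "spontaneous"])
  maxi <- mean(plate$absorbance[plate$role == "maximum"])
  if (!is.finite(spont) || !is.finite(maxi))
    abort("Plate must contain spontaneous- and maximum-release wells.")
  plate %>%
    dplyr::filter(.data$role == "sample") %>%
    mutate(cytotoxicity_percent =
             ldh_cytotoxicity(.data$absorbance, spont, maxi)) %>%
    select("well", "dose_uM", "cytotoxicity_percent")
}
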