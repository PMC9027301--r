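#' Configuration of the synthetic CoCl2 dose-response experiment
#'
#' Defines the in-silico study: dose groups, plate layout, timing, the
#' barrier-kinetics ground truth, per-dose treatment effects and the noise
#' model. Defaults emulate a CoCl2 (cytopathic hypoxia) dose-response on a
#' human retinal endothelial monolayer: seeding 44.8 h before treatment,
#' 25 h follow-up, doses 0/10/100/1000 uM, and an Rb collapse whose
#' time-to-zero shortens with dose (reaching zero within 0-1 h at 1000 uM,
#' 10-15 h at 100 uM and 20-25 h at 10 uM), a delayed membrane-capacitance
#' rise at >= 100 uM, and a dose-independent alpha.
#'
#' @param doses_uM treatment doses, uM (0 = vehicle control).
#' @param wells_per_group cell-covered wells per dose group.
#' @param cellfree_wells number of cell-free reference wells.
#' @param seeding_to_treatment_h hours from seeding to dose application
#'   (treatment defines t = 0; seeding is at `-seeding_to_treatment_h`).
#' @param followup_h post-treatment follow-up, h.
#' @param sampling_interval_h acquisition interval, h.
#' @param frequencies_hz measurement grid, Hz.
#' @param electrode ground-truth [electrode_parameters()].
#' @param alpha_plateau,alpha_tau_h alpha plateau (Ohm cm^(1/2)) and
#'   saturating-rise time constant (h); attachment is established by ~2 h.
#' @param cm_baseline_uF membrane capacitance baseline, uF/cm^2.
#' @param rb_plateau,rb_onset_h,rb_mid_h,rb_rise_tau_h Rb plateau
#'   (Ohm cm^2) and logistic-rise timing: exactly zero before `rb_onset_h`
#'   post-seeding, half-maximal at `rb_mid_h`, near plateau by 10-12 h.
#' @param dose_effects per-dose effect table with columns `dose_uM`,
#'   `rb_time_to_zero_h` (post-treatment time at which Rb reaches exactly 0;
#'   `Inf` = never), `rb_collapse_width_h` (logistic width of the late
#'   collapse), `cm_rise_onset_h` (post-treatment time before which Cm
#'   is exactly at baseline), `cm_rise_mid_h`, `cm_rise_width_h` (logistic
#'   midpoint and width of the rise) and `cm_rise_amplitude` (fractional Cm
#'   increase; 0 = no rise). Effects must be monotone in dose.
#' @param noise_fraction multiplicative complex noise scale on impedance.
#' @param well_cv between-well biological coefficient of variation
#'   (lognormal) applied per well to the Rb and alpha plateaus and the Cm
#'   baseline; replicate wells of real arrays differ by several percent.
#' @param ttz_cv lognormal coefficient of variation of each well's
#'   post-treatment Rb time-to-zero; kept small so replicate wells of a
#'   group terminate inside the same few-hour window, as the grouped
#'   barrier-collapse timecourses show.
#' @param cm_drift_sd standard deviation of the per-well slow linear
#'   fractional drift of Cm, expressed over the follow-up period.
#' @return An object of class `ecis_synth_config`.
#' @export
synthetic_config <- function(doses_uM = c(0, 10, 100, 1000),
                             wells_per_group = 6,
                             cellfree_wells = 3,
                             seeding_to_treatment_h = 44.8,
                             followup_h = 25,
                             sampling_interval_h = 0.25,
                             frequencies_hz = ecis_frequencies(),
                             electrode = electrode_parameters(),
                             alpha_plateau = 12,
                             alpha_tau_h = 0.7,
                             cm_baseline_uF = 1.5,
                             rb_plateau = 3,
                             rb_onset_h = 5,
                             rb_mid_h = 8.5,
                             rb_rise_tau_h = 1.2,
                             dose_effects = NULL,
                             noise_fraction = 0.01,
                             well_cv = 0.08,
                             ttz_cv = 0.05,
                             cm_drift_sd = 0.03) {
  if (is.null(dose_effects)) {
    dose_effects <- tibble(
      dose_uM = c(0, 10, 100, 1000),
      rb_time_to_zero_h = c(Inf, 24.5, 12.5, 0.5),
      rb_collapse_width_h = c(NA, 0.75, 1.5, 0.1),
      cm_rise_onset_h = c(NA, NA, 9, 0.5),
      cm_rise_mid_h = c(NA, NA, 12, 1.5),
      cm_rise_width_h = c(NA, NA, 1.5, 0.5),
      cm_rise_amplitude = c(0, 0, 0.5, 0.6)
    )
  }
  dose_effects <- dplyr::filter(as_tibble(dose_effects),
                                .data$dose_uM %in% doses_uM)
  stopifnot(all(doses_uM %in% dose_effects$dose_uM))
  de <- dplyr::arrange(dose_effects, .data$dose_uM)
  if (is.unsorted(rev(de$rb_time_to_zero_h)) ||
      is.unsorted(de$cm_rise_amplitude))
    abort("`dose_effects` must be monotone in dose.")
  stopifnot(seeding_to_treatment_h > 0, followup_h > 0,
            sampling_interval_h > 0, alpha_tau_h > 0, rb_rise_tau_h > 0,
            noise_fraction >= 0, well_cv >= 0, ttz_cv >= 0, cm_drift_sd >= 0)
  structure(
    list(doses_uM = sort(doses_uM), wells_per_group = wells_per_group,
         cellfree_wells = cellfree_wells,
         seeding_to_treatment_h = seeding_to_treatment_h,
         followup_h = followup_h, sampling_interval_h = sampling_interval_h,
         frequencies_hz = frequencies_hz, electrode = electrode,
         alpha_plateau = alpha_plateau, alpha_tau_h = alpha_tau_h,
         cm_baseline_uF = cm_baseline_uF, rb_plateau = rb_plateau,
         rb_onset_h = rb_onset_h, rb_mid_h = rb_mid_h,
         rb_rise_tau_h = rb_rise_tau_h, dose_effects = de,
         noise_fraction = noise_fraction, well_cv = well_cv,
         ttz_cv = ttz_cv, cm_drift_sd = cm_drift_sd),
    class = "ecis_synth_config"
  )
}

#' Ground-truth barrier kinetics of the synthetic experiment
#'
#' Evaluates the deterministic (noise-free) barrier-parameter trajectory at
#' time `t_h` after seeding for a given dose. The kinetic forms are:
#' a saturating-exponential rise for alpha (attachment established by ~2 h,
#' dose-independent); a stable Cm baseline with a dose-gated logistic rise
#' after treatment (none at 0/10 uM, onset 9 h post-treatment at 100 uM,
#' within the first hour at 1000 uM); and for Rb, exactly zero before the onset time, a clipped
#' logistic rise peaking at 10-12 h post-seeding, then after treatment a
#' late clipped-logistic collapse reaching exactly 0 at the dose's
#' configured time-to-zero.
#'
#' @param t_h time since seeding, h (vectorised), >= 0.
#' @param dose_uM a single dose present in `config$dose_effects`.
#' @param config an [synthetic_config()].
#' @return Tibble with columns `t_h`, `rb`, `alpha`, `cm`.
#' @export
simulate_barrier_kinetics <- function(t_h, dose_uM = 0,
                                      config = synthetic_config()) {
  if (any(t_h < 0)) abort("`t_h` is measured from seeding and must be >= 0.")
  eff <- dplyr::filter(config$dose_effects, .data$dose_uM == !!dose_uM)
  if (nrow(eff) != 1) abort("Unknown dose.")
  t_treat <- config$seeding_to_treatment_h

  alpha <- config$alpha_plateau * (1 - exp(-t_h / config$alpha_tau_h))

  # Rb: clipped logistic rise (exact zero before onset), quadratic collapse
  s <- stats::plogis((t_h - config$rb_mid_h) / config$rb_rise_tau_h)
  s_on <- stats::plogis((config$rb_onset_h - config$rb_mid_h) / config$rb_rise_tau_h)
  rise <- pmax(0, (s - s_on) / (1 - s_on))
  tpost <- pmax(0, t_h - t_treat)
  decay <- if (is.finite(eff$rb_time_to_zero_h)) {
    # late collapse: clipped logistic equal to 1 at treatment and exactly 0
    # at the configured time-to-zero
    tz <- eff$rb_time_to_zero_h
    w <- eff$rb_collapse_width_h
    m <- tz - 3 * w
    sg <- stats::plogis((m - tpost) / w)
    s0 <- stats::plogis(m / w)
    sz <- stats::plogis((m - tz) / w)
    d <- pmax(0, (sg - sz) / (s0 - sz))
    d[tpost >= tz] <- 0
    d
  } else {
    rep(1, length(t_h))
  }
  rb <- config$rb_plateau * rise * decay

  cm <- rep(config$cm_baseline_uF, length(t_h))
  if (eff$cm_rise_amplitude > 0) {
    # clipped logistic: exactly baseline before the onset, so the rise is
    # invisible inside the short alpha/Cm modelable windows
    tp <- t_h - t_treat
    g <- stats::plogis((tp - eff$cm_rise_mid_h) / eff$cm_rise_width_h)
    g_on <- stats::plogis((eff$cm_rise_onset_h - eff$cm_rise_mid_h) /
                            eff$cm_rise_width_h)
    gate <- pmax(0, (g - g_on) / (1 - g_on))
    gate[tp <= eff$cm_rise_onset_h] <- 0
    cm <- cm * (1 + eff$cm_rise_amplitude * gate)
  }
  tibble(t_h = t_h, rb = rb, alpha = alpha, cm = cm)
}

# treatment-relative acquisition time grid (includes 0 and both endpoints)
synth_time_grid <- function(config) {
  pre <- -rev(unique(c(seq(0, config$seeding_to_treatment_h,
                           by = config$sampling_interval_h),
                       config$seeding_to_treatment_h)))
  post <- unique(c(seq(0, config$followup_h, by = config$sampling_interval_h),
                   config$followup_h))
  sort(unique(c(pre, post)))
}

#' Simulate a complete multifrequency ECIS experiment
#'
#' Composes the barrier-kinetics ground truth with the cell-covered
#' electrode forward model at every (well, time, frequency), adds
#' multiplicative complex Gaussian noise of the configured scale, and
#' includes cell-free reference wells. Identical seeds reproduce identical
#' experiments.
#'
#' Replicate wells are biologically distinct: each cell-covered well draws
#' lognormal multipliers for its Rb/alpha plateaus and Cm baseline
#' (`well_cv`), a lognormal jitter on its Rb time-to-zero (`ttz_cv`) and a
#' slow linear Cm drift (`cm_drift_sd`), so that group statistics across
#' wells see genuine between-replicate scatter, not just instrument noise.
#' The per-well realised trajectories are stored as the ground truth.
#'
#' @param config an [synthetic_config()].
#' @param seed integer RNG seed.
#' @return Object of class `ecis_experiment`: list with `impedance` (long
#'   tibble: `time_h`, `well`, `group`, `dose_uM`, `frequency_hz`,
#'   `z_real_ohm`, `z_imag_ohm`), `ground_truth` (tibble: `well`, `dose_uM`,
#'   `time_h`, `rb`, `alpha`, `cm` — the realised per-well trajectories),
#'   `config` and `seed`.
#' @export
simulate_experiment <- function(config = synthetic_config(), seed = 1) {
  set.seed(seed)
  times <- synth_time_grid(config)     # treatment-relative
  t_seed <- times + config$seeding_to_treatment_h
  freqs <- config$frequencies_hz
  el <- config$electrode

  make_records <- function(well_id, group, dose, z_clean_by_time) {
    nt <- length(times); nf <- length(freqs)
    eps <- complex(real = rnorm(nt * nf), imaginary = rnorm(nt * nf)) *
      (config$noise_fraction / sqrt(2))
    z <- z_clean_by_time * (1 + eps)
    tibble(time_h = rep(times, each = nf), well = well_id, group = group,
           dose_uM = dose, frequency_hz = rep(freqs, times = nt),
           z_real_ohm = Re(z), z_imag_ohm = Im(z))
  }

  # all well-level biology is drawn up front as one consecutive block, so
  # the per-well effects form a contiguous RNG subsequence independent of
  # the grid size (interleaving them with the large per-well noise blocks
  # would sample the generator at a huge fixed stride)
  n_wells <- length(config$doses_uM) * config$wells_per_group
  biology <- matrix(rnorm(5 * n_wells), ncol = 5)

  records <- list()
  truth <- list()
  iw <- 0
  for (d in config$doses_uM) {
    base <- simulate_barrier_kinetics(t_seed, d, config)
    for (w in seq_len(config$wells_per_group)) {
      iw <- iw + 1
      # per-well biology: plateau multipliers, collapse-time jitter, Cm drift
      mult <- exp(biology[iw, 1:3] * config$well_cv)
      ttz_mult <- exp(biology[iw, 4] * config$ttz_cv)
      slope <- biology[iw, 5] * config$cm_drift_sd
      eff <- dplyr::filter(config$dose_effects, .data$dose_uM == d)
      kin <- if (is.finite(eff$rb_time_to_zero_h) && config$ttz_cv > 0) {
        cfg_w <- config
        cfg_w$dose_effects$rb_time_to_zero_h[
          cfg_w$dose_effects$dose_uM == d] <- eff$rb_time_to_zero_h * ttz_mult
        simulate_barrier_kinetics(t_seed, d, cfg_w)
      } else {
        base
      }
      rb_w <- kin$rb * mult[1]
      alpha_w <- kin$alpha * mult[2]
      cm_w <- kin$cm * mult[3] *
        (1 + slope * times / config$followup_h)
      well_id <- sprintf("d%s_w%d", d, w)
      truth[[length(truth) + 1]] <-
        tibble(well = well_id, dose_uM = d, time_h = times,
               rb = rb_w, alpha = alpha_w, cm = cm_w)
      z_clean <- unlist(lapply(seq_along(times), function(i) {
        bar <- barrier_parameters(Rb = rb_w[i], alpha = alpha_w[i],
                                  Cm = cm_w[i])
        well_impedance(freqs, el, bar)
      }))
      records[[length(records) + 1]] <-
        make_records(well_id, paste0("dose_", d), d, z_clean)
    }
  }
  z_free_all <- rep(well_impedance(freqs, el), times = length(times))
  for (w in seq_len(config$cellfree_wells)) {
    records[[length(records) + 1]] <-
      make_records(sprintf("cf_w%d", w), "cell_free", NA_real_, z_free_all)
  }

  structure(
    list(impedance = bind_rows(records), ground_truth = bind_rows(truth),
         config = config, seed = seed),
    class = "ecis_experiment"
  )
}

#' @export
print.ecis_experiment <- function(x, ...) {
  cat("Synthetic ECIS experiment\n")
  cat(sprintf("  doses (uM): %s | %d wells/group + %d cell-free\n",
              paste(x$config$doses_uM, collapse = "/"),
              x$config$wells_per_group, x$config$cellfree_wells))
  cat(sprintf("  time: %.1f h pre- to %.1f h post-treatment, every %.2g h; %d frequencies\n",
              x$config$seeding_to_treatment_h, x$config$followup_h,
              x$config$sampling_interval_h, length(x$config$frequencies_hz)))
  cat(sprintf("  %d impedance records; seed %d\n", nrow(x$impedance), x$seed))
  invisible(x)
}

#' Simulate Seahorse Mito-Stress OCR traces
#'
#' Draws per-well oxygen-consumption-rate traces with four phase plateaus
#' (basal, post-oligomycin, post-FCCP maximal, post-rotenone/antimycin
#' non-mitochondrial) around configured per-dose means, with Gaussian
#' measurement noise. Default plateau means encode the study's findings:
#' basal OCR reduced dose-dependently at every dose, ATP-linked and maximal
#' OCR reduced only at 100 and 1000 uM, common non-mitochondrial OCR.
#'
#' @param doses_uM dose groups.
#' @param wells_per_group wells per dose.
#' @param phase_means data frame (`dose_uM`, `basal`, `post_oligo`,
#'   `maximal`, `non_mito`; pmol O2/min) or `NULL` for defaults.
#' @param cycles_per_phase measurement cycles per phase (>= 3).
#' @param cycle_min minutes between cycles.
#' @param noise_sd Gaussian noise SD per reading, pmol/min (set 0 for
#'   noiseless traces).
#' @param seed integer RNG seed.
#' @return List with `traces` (tibble: `time_min`, `well`, `dose_uM`,
#'   `ocr_pmol_min`), `schedule` (tibble: `event`, `time_min`) and
#'   `phase_means`.
#' @export
simulate_ocr <- function(doses_uM = c(0, 10, 100, 1000),
                         wells_per_group = 6,
                         phase_means = NULL,
                         cycles_per_phase = 3,
                         cycle_min = 6.5,
                         noise_sd = 4,
                         seed = 1) {
  set.seed(seed)
  if (is.null(phase_means)) {
    phase_means <- tibble(
      dose_uM = c(0, 10, 100, 1000),
      basal = c(100, 85, 65, 45),
      post_oligo = c(40, 25, 25, 20),
      maximal = c(150, 150, 110, 70),
      non_mito = c(10, 10, 10, 10)
    )
  }
  phase_means <- dplyr::filter(as_tibble(phase_means),
                               .data$dose_uM %in% doses_uM)
  stopifnot(cycles_per_phase >= 3, all(doses_uM %in% phase_means$dose_uM))
  n_cyc <- 4 * cycles_per_phase
  time_min <- seq_len(n_cyc) * cycle_min
  schedule <- tibble(
    event = c("oligomycin", "FCCP", "rotenone_antimycin"),
    time_min = time_min[c(1, 2, 3) * cycles_per_phase] + cycle_min / 2
  )
  phase_of <- rep(c("basal", "post_oligo", "maximal", "non_mito"),
                  each = cycles_per_phase)
  traces <- purrr::map_dfr(doses_uM, function(d) {
    mu <- dplyr::filter(phase_means, .data$dose_uM == d)
    level <- unname(unlist(mu[phase_of]))
    purrr::map_dfr(seq_len(wells_per_group), function(w) {
      tibble(time_min = time_min,
             well = sprintf("ocr_d%s_w%d", d, w),
             dose_uM = d,
             ocr_pmol_min = level + rnorm(n_cyc, sd = noise_sd))
    })
  })
  list(traces = traces, schedule = schedule, phase_means = phase_means)
}

#' Simulate an LDH cytotoxicity plate
#'
#' All treated doses share the control release distribution (the study
#' condition: no cytotoxicity at any dose); spontaneous- and maximum-release
#' control wells are included, so the plate carries its own 0% and 100%
#' anchors.
#'
#' @param doses_uM dose groups.
#' @param wells_per_group replicate wells per dose.
#' @param spontaneous_mean,maximum_mean,treated_mean absorbance means for
#'   the spontaneous-release, maximum-release and treated wells.
#' @param noise_sd absorbance noise SD.
#' @param seed integer RNG seed.
#' @return Tibble with columns `well`, `role`
#'   (`sample`/`spontaneous`/`maximum`), `dose_uM`, `absorbance`.
#' @export
simulate_ldh <- function(doses_uM = c(0, 10, 100, 1000),
                         wells_per_group = 6,
                         spontaneous_mean = 0.20,
                         maximum_mean = 1.20,
                         treated_mean = 0.21,
                         noise_sd = 0.012,
                         seed = 1) {
  set.seed(seed)
  stopifnot(maximum_mean > spontaneous_mean)
  samples <- purrr::map_dfr(doses_uM, function(d) {
    tibble(well = sprintf("ldh_d%s_w%d", d, seq_len(wells_per_group)),
           role = "sample", dose_uM = d,
           absorbance = rnorm(wells_per_group, treated_mean, noise_sd))
  })
  controls <- bind_rows(
    tibble(well = sprintf("ldh_spont_w%d", seq_len(wells_per_group)),
           role = "spontaneous", dose_uM = NA_real_,
           absorbance = rnorm(wells_per_group, spontaneous_mean, noise_sd)),
    tibble(well = sprintf("ldh_max_w%d", seq_len(wells_per_group)),
           role = "maximum", dose_uM = NA_real_,
           absorbance = rnorm(wells_per_group, maximum_mean, noise_sd))
  )
  bind_rows(samples, controls)
}
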