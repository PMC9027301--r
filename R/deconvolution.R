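#' Fit configuration for barrier-parameter deconvolution
#'
#' Controls the bounds-constrained nonlinear least-squares recovery of
#' `(Rb, alpha, Cm)` from a multifrequency spectrum.
#'
#' @param lower,upper named numeric bounds for `Rb` (Ohm cm^2), `alpha`
#'   (Ohm cm^(1/2)) and `Cm` (uF/cm^2). Lower bounds must be >= 0 and
#'   below the uppers.
#' @param init named numeric starting point used for the first timepoint of a
#'   trace (later timepoints warm-start from the previous fit when
#'   `warm_start = TRUE`).
#' @param rb_zero_threshold Rb floor, Ohm cm^2: a fitted Rb at or below this
#'   value is reported as exactly 0 and `alpha`/`Cm` are flagged
#'   non-modelable (the paracellular short makes them unidentifiable).
#' @param warm_start logical; initialise each timepoint's fit from the
#'   previous timepoint of the same well.
#' @param restart_ssq residual sum-of-squares above which the fit is retried
#'   from a set of fixed restarts (guards warm starts against local minima);
#'   the lowest-residual solution is kept.
#' @param max_iterations,ftol Levenberg-Marquardt iteration cap and relative
#'   sum-of-squares convergence tolerance.
#' @return An object of class `ecis_fit_config`.
#' @export
fit_config <- function(lower = c(Rb = 0, alpha = 0.01, Cm = 0.05),
                       upper = c(Rb = 1e4, alpha = 200, Cm = 50),
                       init = c(Rb = 2, alpha = 5, Cm = 1),
                       rb_zero_threshold = 0.05,
                       warm_start = TRUE,
                       restart_ssq = 0.02,
                       max_iterations = 200,
                       ftol = 1e-12) {
  nm <- c("Rb", "alpha", "Cm")
  stopifnot(all(nm %in% names(lower)), all(nm %in% names(upper)),
            all(nm %in% names(init)))
  if (any(lower[nm] < 0)) abort("Lower bounds must be >= 0.")
  if (any(lower[nm] >= upper[nm])) abort("Each lower bound must be below its upper bound.")
  if (rb_zero_threshold <= 0) abort("`rb_zero_threshold` must be > 0.")
  structure(
    list(lower = lower[nm], upper = upper[nm], init = init[nm],
         rb_zero_threshold = rb_zero_threshold, warm_start = warm_start,
         restart_ssq = restart_ssq,
         max_iterations = max_iterations, ftol = ftol),
    class = "ecis_fit_config"
  )
}

# complex spectrum from a long table (frequency_hz, z_real_ohm, z_imag_ohm)
spectrum_complex <- function(data) {
  require_columns(data, c("frequency_hz", "z_real_ohm", "z_imag_ohm"))
  data <- dplyr::arrange(as_tibble(data), .data$frequency_hz)
  list(f = data$frequency_hz,
       z = complex(real = data$z_real_ohm, imaginary = data$z_imag_ohm))
}

# relative complex residual vector (re, im interleaved by c())
barrier_residuals <- function(par, f, z_obs, electrode) {
  bar <- list(Rb = par[[1]], alpha = par[[2]], Cm = par[[3]])
  z_mod <- electrode$solution_resistance_Rsol +
    cell_covered_impedance_raw(f, electrode, bar) / electrode$electrode_area_A
  res <- (z_mod - z_obs) / z_obs
  c(Re(res), Im(res))
}

# unvalidated fast path used inside optimisation loops
cell_covered_impedance_raw <- function(f, electrode, barrier) {
  Zn <- 1 / (electrode$cpe_magnitude_Q * (2i * pi * f)^electrode$cpe_exponent_n)
  Zm <- 2 / (2i * pi * f * barrier$Cm * 1e-6)
  S <- 1 / Zn + 1 / Zm
  gamma <- barrier$alpha * sqrt(S)
  spread <- (gamma / 2) * vapply(gamma, bessel_ratio_one, complex(1))
  inv <- (1 / Zn) * (Zn / (Zn + Zm) + (Zm / (Zn + Zm)) / (spread + barrier$Rb * S))
  1 / inv
}

#' Fit electrode parameters from a cell-free reference spectrum
#'
#' Recovers the CPE coefficient `Q`, exponent `n` and solution resistance
#' `Rsol` of the cell-free well model `Z = Rsol + Zn(f)/A` by
#' Levenberg-Marquardt least squares on relative complex residuals. The
#' effective electrode area `A` is not separately identifiable from `Q` and
#' is held fixed.
#'
#' @param reference_spectrum data frame with columns `frequency_hz`,
#'   `z_real_ohm`, `z_imag_ohm` (one row per frequency; cell-free well).
#' @param electrode_area_A fixed effective area, cm^2 (defaults to the
#'   package's calibrated array profile).
#' @param init an [electrode_parameters()] starting point.
#' @return A fitted `ecis_electrode` object.
#' @export
fit_electrode_parameters <- function(reference_spectrum,
                                     electrode_area_A =
                                       electrode_parameters()$electrode_area_A,
                                     init = electrode_parameters()) {
  sp <- spectrum_complex(reference_spectrum)
  resid_fn <- function(par) {
    zn <- 1 / (par[[1]] * (2i * pi * sp$f)^par[[2]])
    z_mod <- par[[3]] + zn / electrode_area_A
    res <- (z_mod - sp$z) / sp$z
    c(Re(res), Im(res))
  }
  fit <- minpack.lm::nls.lm(
    par = c(Q = init$cpe_magnitude_Q, n = init$cpe_exponent_n,
            Rsol = init$solution_resistance_Rsol),
    lower = c(1e-9, 0.5, 0), upper = c(1e-2, 1, 1e5),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  electrode_parameters(cpe_magnitude_Q = fit$par[["Q"]],
                       cpe_exponent_n = fit$par[["n"]],
                       solution_resistance_Rsol = fit$par[["Rsol"]],
                       electrode_area_A = electrode_area_A)
}

#' Deconvolve one multifrequency spectrum into barrier parameters
#'
#' Recovers `(Rb, alpha, Cm)` from a cell-covered well spectrum by
#' minimising the frequency-summed squared relative complex residual
#' `sum_f | (Z_model(f) - Z_cell(f)) / Z_cell(f) |^2` under box constraints.
#' Relative residuals equalise the influence of frequencies across the
#' 250-64,000 Hz grid, where `|Z|` spans orders of magnitude, and make the
#' objective invariant to overall impedance scaling.
#'
#' If the fitted `Rb` does not exceed `config$rb_zero_threshold`, the
#' paracellular pathway is an effective short: `Rb` is reported as exactly 0
#' and `alpha`/`Cm` are flagged non-modelable.
#'
#' @param cell_spectrum data frame with columns `frequency_hz`, `z_real_ohm`,
#'   `z_imag_ohm` for the cell-covered well at one timepoint.
#' @param reference_spectrum matching cell-free spectrum on the same grid;
#'   used to fit the electrode when `electrode` is `NULL`.
#' @param electrode a known/fitted [electrode_parameters()] object, or `NULL`
#'   to fit one from `reference_spectrum` first.
#' @param config a [fit_config()].
#' @param init optional numeric `c(Rb, alpha, Cm)` override of
#'   `config$init` (used internally for warm starts).
#' @return An object of class `ecis_fit`: list with elements `barrier`
#'   ([barrier_parameters()]), `residual_norm`, `converged`,
#'   `n_frequencies_used` and `electrode`.
#' @export
fit_barrier_parameters <- function(cell_spectrum, reference_spectrum = NULL,
                                   electrode = NULL, config = fit_config(),
                                   init = NULL) {
  if (is.null(electrode)) {
    if (is.null(reference_spectrum))
      abort("Provide `electrode` or a cell-free `reference_spectrum` to fit it from.")
    electrode <- fit_electrode_parameters(reference_spectrum)
  }
  sp <- spectrum_complex(cell_spectrum)
  if (!is.null(reference_spectrum)) {
    ref <- spectrum_complex(reference_spectrum)
    if (length(ref$f) != length(sp$f) || any(ref$f != sp$f))
      abort("Cell and reference spectra must share the same frequency grid.")
  }
  usable <- is.finite(Re(sp$z)) & is.finite(Im(sp$z)) & abs(sp$z) > 0
  if (sum(usable) < 4)
    abort("Fewer than 4 usable frequencies; refusing to fit.")
  f <- sp$f[usable]
  z <- sp$z[usable]
  clamp <- function(p) setNames(pmin(pmax(p, config$lower + 1e-9), config$upper),
                                c("Rb", "alpha", "Cm"))
  starts <- list(if (is.null(init)) config$init else clamp(init))
  run_fit <- function(start) {
    minpack.lm::nls.lm(
      par = start, lower = config$lower, upper = config$upper,
      fn = barrier_residuals, f = f, z_obs = z, electrode = electrode,
      control = minpack.lm::nls.lm.control(maxiter = config$max_iterations,
                                           ftol = config$ftol)
    )
  }
  fit <- run_fit(starts[[1]])
  # multiple minima: retry from fixed restarts and keep the lowest residual
  ssq <- sum(fit$fvec^2)
  if (ssq > config$restart_ssq) {
    restarts <- list(config$init, c(Rb = 3, alpha = 12, Cm = 1.5),
                     c(Rb = 0.5, alpha = 12, Cm = 1), c(Rb = 20, alpha = 4, Cm = 2))
    for (s in restarts) {
      alt <- run_fit(clamp(s))
      if (sum(alt$fvec^2) < ssq) {
        fit <- alt
        ssq <- sum(alt$fvec^2)
      }
      if (ssq <= config$restart_ssq) break
    }
  }
  # a warm-started fit that lands on the Rb floor may be a local-minimum
  # valley inherited from the previous timepoint: verify against a cold
  # start and keep the lower-residual solution
  if (!is.null(init) && fit$par[["Rb"]] <= config$rb_zero_threshold) {
    alt <- run_fit(clamp(config$init))
    if (sum(alt$fvec^2) < sum(fit$fvec^2)) fit <- alt
  }
  converged <- fit$info %in% 1:4
  par <- fit$par
  rb_raw <- par[["Rb"]]
  degenerate <- rb_raw <= config$rb_zero_threshold
  barrier <- barrier_parameters(
    Rb = if (degenerate) 0 else rb_raw,
    alpha = par[["alpha"]], Cm = par[["Cm"]],
    alpha_modelable = !degenerate, cm_modelable = !degenerate
  )
  structure(
    list(barrier = barrier,
         raw = c(Rb = rb_raw, alpha = par[["alpha"]], Cm = par[["Cm"]]),
         residual_norm = sqrt(sum(fit$fvec^2)),
         converged = converged,
         n_frequencies_used = sum(usable),
         electrode = electrode),
    class = "ecis_fit"
  )
}

#' @export
print.ecis_fit <- function(x, ...) {
  b <- x$barrier
  cat("ECIS barrier fit\n")
  cat(sprintf("  Rb    = %.4g Ohm cm^2%s\n", b$Rb,
              if (b$Rb == 0) " (at floor; alpha/Cm non-modelable)" else ""))
  cat(sprintf("  alpha = %.4g Ohm cm^(1/2)%s\n", b$alpha,
              if (!b$alpha_modelable) " [non-modelable]" else ""))
  cat(sprintf("  Cm    = %.4g uF/cm^2%s\n", b$Cm,
              if (!b$cm_modelable) " [non-modelable]" else ""))
  cat(sprintf("  residual norm %.3g over %d frequencies; converged: %s\n",
              x$residual_norm, x$n_frequencies_used, x$converged))
  invisible(x)
}

#' @rdname fit_barrier_parameters
#' @param x an `ecis_fit` object.
#' @param ... unused.
#' @method tidy ecis_fit
#' @export
tidy.ecis_fit <- function(x, ...) {
  b <- x$barrier
  tibble(
    term = c("Rb", "alpha", "Cm"),
    estimate = c(b$Rb, b$alpha, b$Cm),
    unit = c("Ohm cm^2", "Ohm cm^(1/2)", "uF/cm^2"),
    modelable = c(TRUE, b$alpha_modelable, b$cm_modelable)
  )
}

#' @rdname fit_barrier_parameters
#' @method glance ecis_fit
#' @export
glance.ecis_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, converged = x$converged,
         n_frequencies_used = x$n_frequencies_used)
}

#' Deconvolve a whole-well timecourse into barrier-parameter traces
#'
#' Runs [fit_barrier_parameters()] at every timepoint of every cell-covered
#' well in a long impedance table, with warm-start initialisation from the
#' previous timepoint. The electrode model is fitted once from the cell-free
#' reference wells (time-averaged spectrum) and frozen. Failed timepoints are
#' recorded (`converged = FALSE`, `NA` parameters) without aborting the
#' trace.
#'
#' Output traces carry modelability masks: wherever the reported `Rb` is 0,
#' `alpha_modelable` and `cm_modelable` are `FALSE`, so downstream plots and
#' statistics terminate the alpha and Cm traces exactly where the
#' paracellular barrier vanishes.
#'
#' @param data long impedance records with columns `time_h`, `well`, `group`,
#'   `frequency_hz`, `z_real_ohm`, `z_imag_ohm` (and optionally `dose_uM`).
#' @param electrode known [electrode_parameters()], or `NULL` to fit from the
#'   reference wells.
#' @param config a [fit_config()].
#' @param reference_group value of `group` identifying cell-free wells
#'   (default `"cell_free"`).
#' @return A tibble of class `ecis_deconvolution`: one row per (well, time)
#'   with columns `well`, `dose_uM` (if present), `time_h`, `rb`, `alpha`,
#'   `cm`, `alpha_modelable`, `cm_modelable`, `residual_norm`, `converged`,
#'   `n_frequencies_used`.
#' @export
deconvolve_timecourse <- function(data, electrode = NULL,
                                  config = fit_config(),
                                  reference_group = "cell_free") {
  require_columns(data, c("time_h", "well", "group", "frequency_hz",
                          "z_real_ohm", "z_imag_ohm"))
  data <- as_tibble(data)
  ref <- dplyr::filter(data, .data$group == reference_group)
  cells <- dplyr::filter(data, .data$group != reference_group)
  if (nrow(cells) == 0) abort("No cell-covered wells in `data`.")
  if (is.null(electrode)) {
    if (nrow(ref) == 0)
      abort("No reference wells to fit the electrode from; supply `electrode`.")
    ref_mean <- ref %>%
      group_by(.data$frequency_hz) %>%
      summarise(z_real_ohm = mean(.data$z_real_ohm),
                z_imag_ohm = mean(.data$z_imag_ohm), .groups = "drop")
    electrode <- fit_electrode_parameters(ref_mean)
  }
  has_dose <- "dose_uM" %in% names(data)

  one_well <- function(wdat) {
    wdat <- dplyr::arrange(wdat, .data$time_h, .data$frequency_hz)
    times <- unique(wdat$time_h)
    prev <- NULL
    rows <- vector("list", length(times))
    for (i in seq_along(times)) {
      sub <- wdat[wdat$time_h == times[i], , drop = FALSE]
      init <- if (config$warm_start && !is.null(prev)) prev else NULL
      fit <- tryCatch(
        fit_barrier_parameters(sub, electrode = electrode, config = config,
                               init = init),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        rows[[i]] <- tibble(time_h = times[i], rb = NA_real_,
                            alpha = NA_real_, cm = NA_real_,
                            alpha_modelable = FALSE, cm_modelable = FALSE,
                            residual_norm = NA_real_, converged = FALSE,
                            n_frequencies_used = 0L)
      } else {
        prev <- fit$raw
        b <- fit$barrier
        rows[[i]] <- tibble(time_h = times[i], rb = b$Rb, alpha = b$alpha,
                            cm = b$Cm, alpha_modelable = b$alpha_modelable,
                            cm_modelable = b$cm_modelable,
                            residual_norm = fit$residual_norm,
                            converged = fit$converged,
                            n_frequencies_used = fit$n_frequencies_used)
      }
    }
    bind_rows(rows)
  }

  keys <- c("well", if (has_dose) "dose_uM", "group")
  out <- cells %>%
    dplyr::group_by(across(all_of(keys))) %>%
    dplyr::group_modify(~ one_well(.x)) %>%
    ungroup()
  # masks are sticky after barrier establishment: once a well whose barrier
  # has been solidly established (Rb above 30x the zero threshold for 4
  # consecutive samples - i.e. past the noisy onset where near-zero
  # stretches are normal) reports a PERSISTENT Rb = 0 - a zero whose
  # short look-ahead (2 h) mean also sits near the floor - its alpha/Cm
  # traces terminate for good (the degenerate paracellular short never
  # re-identifies them). Isolated noise zeros during the Rb rise, whose
  # look-ahead mean is clearly positive, only mask their own timepoints.
  terminal_zero <- function(rb, time_h) {
    n <- length(rb)
    up <- !is.na(rb) & rb > 30 * config$rb_zero_threshold
    run <- Reduce(function(acc, x) if (x) acc + 1 else 0, up, 0,
                  accumulate = TRUE)[-1]
    est <- cumsum(run >= 4) > 0
    dead <- logical(n)
    for (i in seq_len(n)) {
      if (est[i] && !is.na(rb[i]) && rb[i] == 0) {
        ahead <- rb[time_h >= time_h[i] & time_h <= time_h[i] + 2]
        if (mean(ahead, na.rm = TRUE) <= 20 * config$rb_zero_threshold) {
          dead[i:n] <- TRUE
          break
        }
      }
    }
    dead
  }
  out <- out %>%
    group_by(.data$well) %>%
    mutate(.dead = terminal_zero(.data$rb, .data$time_h),
           alpha_modelable = .data$alpha_modelable & !.data$.dead,
           cm_modelable = .data$cm_modelable & !.data$.dead) %>%
    ungroup() %>%
    select(-".dead")
  attr(out, "electrode") <- electrode
  class(out) <- c("ecis_deconvolution", class(out))
  out
}

#' Plot deconvolved barrier-parameter traces
#'
#' One panel per parameter (`Rb`, `alpha`, `Cm`) against time; the alpha and
#' Cm traces are masked (terminated) wherever they are non-modelable because
#' `Rb` has reached zero.
#'
#' @param object an `ecis_deconvolution` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ecis_deconvolution
#' @export
autoplot.ecis_deconvolution <- function(object, ...) {
  long <- tibble::as_tibble(object) %>%
    mutate(alpha = ifelse(.data$alpha_modelable, .data$alpha, NA_real_),
           cm = ifelse(.data$cm_modelable, .data$cm, NA_real_)) %>%
    tidyr::pivot_longer(c("rb", "alpha", "cm"),
                        names_to = "parameter", values_to = "value") %>%
    mutate(parameter = factor(.data$parameter, levels = c("rb", "alpha", "cm"),
                              labels = c("Rb (Ohm cm²)",
                                         "alpha (Ohm cm½)",
                                         "Cm (µF/cm²)")))
  colour_var <- if ("dose_uM" %in% names(long)) "factor(dose_uM)" else "well"
  ggplot(long, aes(x = .data$time_h, y = .data$value,
                   group = .data$well,
                   colour = !!rlang::parse_expr(colour_var))) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    labs(x = "Time (h, treatment at 0)", y = NULL,
         colour = if (colour_var == "well") "Well" else "Dose (µM)") +
    theme_minimal()
}
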