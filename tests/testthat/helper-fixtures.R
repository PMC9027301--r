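# Shared fixtures: small configurations and spectra built in code.

default_grid <- ecis_frequencies()

# spectrum tibble from a complex well impedance vector
spectrum_tbl <- function(z, f = default_grid) {
  tibble::tibble(frequency_hz = f, z_real_ohm = Re(z), z_imag_ohm = Im(z))
}

# noiseless forward spectra for a barrier on the default electrode
forward_spectra <- function(barrier = confluent_barrier(),
                            electrode = electrode_parameters()) {
  list(cell = spectrum_tbl(well_impedance(default_grid, electrode, barrier)),
       free = spectrum_tbl(well_impedance(default_grid, electrode)),
       electrode = electrode)
}

# a small, fast synthetic study: fewer wells, coarser clock, same kinetics
tiny_config <- function(...) {
  args <- utils::modifyList(list(wells_per_group = 2, cellfree_wells = 2,
                                 sampling_interval_h = 2), list(...))
  do.call(synthetic_config, args)
}

# long impedance records for a single timepoint from complex spectra
records_at <- function(z, group, well, time_h = 0, f = default_grid,
                       dose_uM = NA_real_) {
  tibble::tibble(time_h = time_h, well = well, group = group,
                 dose_uM = dose_uM, frequency_hz = f,
                 z_real_ohm = Re(z), z_imag_ohm = Im(z))
}
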