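# Shared fixtures: small synthetic configurations and an identity-scale
# calibration (instrument gain 1 at the default pixel factor, so micron truth
# round-trips exactly through instrument units).

identity_calibration <- function(ppm = 3.2937) {
  structure(list(
    pixels_per_micron = ppm,
    tof_to_um_slope = 1 / ppm,
    normext_to_um_slope = 1 / ppm,
    fit_diagnostics = c(length_resid_sd = 0, width_resid_sd = 0),
    n_pairs = 0L
  ), class = "biosort_calibration")
}

small_config <- function(seed, strains = c("N2", "dpy-1"), n_wells = 4,
                         n_animals = 12, contaminant_rate = 0, hours = 1:42) {
  simulation_config(
    strain_profiles = default_strain_profiles()[strains],
    n_wells_per_hour = n_wells, n_animals_per_well = n_animals,
    hours = hours, contaminant_rate = contaminant_rate, seed = seed
  )
}

# Well-level observations on a linear growth ramp with optional slope-ratio
# kink at `onset` (ramping dW/dL from c0 to c0*gain by the window end).
ramp_wells <- function(n_wells = 10, hours = 16:22, c0 = 0.045, onset = Inf,
                       gain = 1.5, rate = 28, l0 = 340, w0 = 15,
                       sd_l = 0, sd_w = 0, intercept = 0, seed = 1) {
  set.seed(seed)
  t_end <- max(hours)
  cpath <- function(u) {
    c0 * pmin(u, onset) +
      ifelse(u > onset & is.finite(onset),
             c0 * (u - onset) +
               c0 * (gain - 1) * (u - onset)^2 / (2 * (t_end - onset)),
             0)
  }
  do.call(rbind, lapply(seq_len(n_wells), function(w) {
    L <- l0 + rate * (hours - min(hours)) + stats::rnorm(length(hours), 0, sd_l)
    W <- w0 + intercept + rate * (cpath(hours) - cpath(min(hours))) +
      stats::rnorm(length(hours), 0, sd_w)
    data.frame(well = paste0("w", w), hour = hours, length_um = L,
               width_um = W, stringsAsFactors = FALSE)
  }))
}
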