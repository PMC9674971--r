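#' Define a strain growth profile for the synthetic-data generator
#'
#' A profile encodes everything the generator needs to draw one genotype's
#' larval trajectory over the 1-42 h observation span: molt times, per-stage
#' length growth rates, the baseline aspect slope c_k = dW/dL of each stage's
#' linear stretch regime, the nonlinear stiffening of the cuticle towards the
#' stage end (onset fraction and multiplicative slope gain), the direction and
#' magnitude of the post-molt relaxation step, and the feeding dip that marks
#' each molt.
#'
#' Growth is piecewise-linear in time within each stage and pauses during a
#' lethargus window of +/- `feeding_dip_halfwidth` hours around each molt
#' (animals do not feed or grow while molting); the relaxation step is applied
#' at the molt time itself. Width follows length through the stage-wise slope
#' ratio: dW/dL = c_k up to `nonlinear_onset_fraction` of the stage, then
#' rises linearly to `c_k * nonlinear_slope_gain` at the stage end.
#'
#' @param strain_id strain label, e.g. `"N2"`.
#' @param stage_boundaries numeric length-3, hours post-feeding of the
#'   L1/L2, L2/L3 and L3/L4 molts; strictly increasing, inside `span`.
#' @param growth_rate numeric length-4, per-stage length growth rate in
#'   micrometres per hour of active (non-lethargus) growth.
#' @param aspect_slope numeric length-4, per-stage baseline dW/dL (`c_k > 0`).
#' @param nonlinear_onset_fraction fraction of stage duration at which the
#'   slope ratio begins to rise; in (0, 1). Recycled to length 4.
#' @param nonlinear_slope_gain multiplicative rise of dW/dL by stage end
#'   (>= 1). Recycled to length 4.
#' @param relaxation_direction `"length-relax"` (width decreases at the molt
#'   while length steps up) or `"width-relax"` (length decreases while width
#'   steps up).
#' @param relaxation_magnitude micrometres lost by the decreasing dimension at
#'   each molt.
#' @param feeding_dip_depth fractional drop of the feeding rate at a molt,
#'   in (0, 1].
#' @param feeding_dip_halfwidth half-width of the feeding dip (and of the
#'   growth pause) in hours.
#' @param length0,width0 length and width (micrometres) at the start of the
#'   observation span.
#' @param span observation span in hours, default `c(1, 42)`.
#' @return an object of class `"strain_profile"`.
#' @seealso [default_strain_profiles()], [simulate_trajectory()]
#' @export
strain_profile <- function(strain_id,
                           stage_boundaries,
                           growth_rate,
                           aspect_slope,
                           nonlinear_onset_fraction = 0.7,
                           nonlinear_slope_gain = 1.5,
                           relaxation_direction = c("length-relax", "width-relax"),
                           relaxation_magnitude = 5,
                           feeding_dip_depth = 0.5,
                           feeding_dip_halfwidth = 2,
                           length0 = 190,
                           width0 = 11,
                           span = c(1, 42)) {
  relaxation_direction <- match.arg(relaxation_direction)
  stage_boundaries <- as.numeric(stage_boundaries)
  .assert(length(stage_boundaries) == 3L &&
            all(diff(stage_boundaries) > 0),
          "stage_boundaries must be 3 strictly increasing hours")
  .assert(all(stage_boundaries > span[1] & stage_boundaries < span[2]),
          "stage_boundaries must lie inside the observation span")
  growth_rate <- rep_len(as.numeric(growth_rate), 4L)
  aspect_slope <- rep_len(as.numeric(aspect_slope), 4L)
  nonlinear_onset_fraction <- rep_len(as.numeric(nonlinear_onset_fraction), 4L)
  nonlinear_slope_gain <- rep_len(as.numeric(nonlinear_slope_gain), 4L)
  .assert(all(growth_rate >= 0), "growth_rate must be >= 0")
  .assert(all(aspect_slope > 0), "aspect_slope (c_k) must be > 0")
  .assert(all(nonlinear_onset_fraction > 0 & nonlinear_onset_fraction < 1),
          "nonlinear_onset_fraction must be in (0,1)")
  .assert(all(nonlinear_slope_gain >= 1), "nonlinear_slope_gain must be >= 1")
  .assert(feeding_dip_depth > 0 && feeding_dip_depth <= 1,
          "feeding_dip_depth must be in (0,1]")
  .assert(feeding_dip_halfwidth > 0, "feeding_dip_halfwidth must be > 0")
  .assert(relaxation_magnitude >= 0, "relaxation_magnitude must be >= 0")
  .assert(length0 > 0 && width0 > 0, "length0 and width0 must be > 0")
  structure(list(
    strain_id = as.character(strain_id),
    stage_boundaries = stage_boundaries,
    growth_rate = growth_rate,
    aspect_slope = aspect_slope,
    nonlinear_onset_fraction = nonlinear_onset_fraction,
    nonlinear_slope_gain = nonlinear_slope_gain,
    relaxation_direction = relaxation_direction,
    relaxation_magnitude = relaxation_magnitude,
    feeding_dip_depth = feeding_dip_depth,
    feeding_dip_halfwidth = feeding_dip_halfwidth,
    length0 = length0,
    width0 = width0,
    span = as.numeric(span)
  ), class = "strain_profile")
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("<strain_profile>", x$strain_id, "\n")
  cat("  molts at", paste(x$stage_boundaries, collapse = ", "), "h;",
      x$relaxation_direction, sprintf("(%.1f um)", x$relaxation_magnitude), "\n")
  cat("  growth rate (um/h):", paste(format(x$growth_rate), collapse = ", "), "\n")
  cat("  aspect slope c_k:  ", paste(format(x$aspect_slope), collapse = ", "), "\n")
  invisible(x)
}

#' Default profiles for the four study genotypes
#'
#' Encodes the qualitative strain contrasts of the study system: the wild type
#' N2 and `lon-3(e2175)` follow near-identical developmental schedules; both
#' `dpy` mutants are delayed, with `dpy-1(e1)` molting latest at every stage;
#' `dpy` animals are shorter and wider (larger aspect slopes); `dpy-1` shows a
#' weak nonlinear stretch regime and a reduced relaxation magnitude; `dpy-5`
#' relaxes post-molt in the opposite direction (length decreases) from the
#' other three strains.
#'
#' @return a named list of [strain_profile()] objects
#'   (`N2`, `dpy-1`, `dpy-5`, `lon-3`).
#' @export
default_strain_profiles <- function() {
  list(
    "N2" = strain_profile(
      "N2",
      stage_boundaries = c(14, 25, 33.5),
      growth_rate = c(13, 28, 40, 45),
      aspect_slope = c(0.035, 0.045, 0.050, 0.060),
      nonlinear_slope_gain = c(1.3, 1.5, 1.5, 1.4),
      relaxation_direction = "length-relax",
      relaxation_magnitude = 5,
      length0 = 190, width0 = 11
    ),
    "dpy-1" = strain_profile(
      "dpy-1",
      stage_boundaries = c(16.5, 28.5, 37.5),
      growth_rate = c(11, 19, 27, 30),
      aspect_slope = c(0.063, 0.081, 0.090, 0.108),
      nonlinear_slope_gain = c(1.15, 1.15, 1.1, 1.1),
      relaxation_direction = "length-relax",
      relaxation_magnitude = 2,
      length0 = 185, width0 = 12.5
    ),
    "dpy-5" = strain_profile(
      "dpy-5",
      stage_boundaries = c(15.5, 27, 36.5),
      growth_rate = c(11.5, 20, 28, 32),
      aspect_slope = c(0.060, 0.078, 0.086, 0.104),
      nonlinear_slope_gain = c(1.3, 1.5, 1.4, 1.3),
      relaxation_direction = "width-relax",
      relaxation_magnitude = 10,
      length0 = 186, width0 = 12.3
    ),
    "lon-3" = strain_profile(
      "lon-3",
      stage_boundaries = c(14, 25, 34.5),
      growth_rate = c(13.5, 29, 40, 46),
      aspect_slope = c(0.033, 0.042, 0.047, 0.057),
      nonlinear_slope_gain = c(1.3, 1.5, 1.5, 1.4),
      relaxation_direction = "length-relax",
      relaxation_magnitude = 5,
      length0 = 192, width0 = 10.8
    )
  )
}
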