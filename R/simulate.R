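#' Configure a synthetic large-particle-cytometry growth assay
#'
#' Bundles the generator settings: strain profiles, sampling design (hours,
#' wells per hour, animals per well), measurement noise, contamination rate,
#' and the instrument measurement model. TOF (time of flight, axial length
#' proxy) and norm.EXT (optical extinction per unit length, width proxy) are
#' produced from the true micron sizes via the pixel conversion factor and
#' per-pixel instrument gains; red fluorescence is proportional to the feeding
#' rate times the optical area of the animal.
#'
#' @param strain_profiles named list of [strain_profile()] objects.
#' @param n_wells_per_hour wells sampled at each hour (per strain).
#' @param n_animals_per_well animals per well.
#' @param hours sampling grid in hours post-feeding; default `1:42`.
#' @param contaminant_rate expected fraction of non-animal objects among all
#'   records; in `[0, 1)`.
#' @param noise_sd_length,noise_sd_width per-object measurement noise SD in
#'   micrometres.
#' @param noise_sd_fluorescence fractional (multiplicative) fluorescence noise SD.
#' @param pixels_per_micron imaging conversion factor; default 3.2937 px/um.
#' @param tof_per_pixel,ext_per_pixel instrument gain: TOF (norm.EXT) units per
#'   pixel of length (width).
#' @param fluor_gain scale of the red-fluorescence channel.
#' @param molt_jitter_sd per-animal molt-time jitter SD (hours) for molts 1-3;
#'   population desynchronization grows with stage.
#' @param contaminant_params distributions of the two contaminant classes, in
#'   instrument units: dense small objects ("blobs", e.g. bacterial clumps)
#'   and elongated faint objects ("streaks", e.g. shed cuticles).
#' @param seed master integer seed; per-well streams are derived with
#'   [split_seed()], so the output is bit-identical for identical config and
#'   unaffected in well `w` by changes to the number of other wells.
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(strain_profiles = default_strain_profiles(),
                              n_wells_per_hour = 30,
                              n_animals_per_well = 50,
                              hours = 1:42,
                              contaminant_rate = 0.05,
                              noise_sd_length = 10,
                              noise_sd_width = 1.5,
                              noise_sd_fluorescence = 0.15,
                              pixels_per_micron = 3.2937,
                              tof_per_pixel = 1,
                              ext_per_pixel = 1,
                              fluor_gain = 5e-3,
                              molt_jitter_sd = c(0.3, 0.6, 1.0),
                              contaminant_params = list(
                                blob_fraction = 0.6,
                                blob_log_tof = c(mean = log(300), sd = 0.35),
                                blob_log_normext = c(mean = log(250), sd = 0.30),
                                streak_log_tof = c(mean = log(900), sd = 0.50),
                                streak_log_normext = c(mean = log(12), sd = 0.40)
                              ),
                              seed = 1L) {
  .assert(length(strain_profiles) >= 1 &&
            all(vapply(strain_profiles, inherits, TRUE, "strain_profile")),
          "strain_profiles must be a list of strain_profile objects")
  if (is.null(names(strain_profiles)) || any(names(strain_profiles) == "")) {
    names(strain_profiles) <- vapply(strain_profiles, `[[`, "", "strain_id")
  }
  .assert(n_wells_per_hour >= 1 && n_animals_per_well >= 1,
          "counts must be >= 1")
  .assert(length(hours) >= 1 && all(diff(hours) > 0),
          "hours must be strictly increasing")
  .assert(contaminant_rate >= 0 && contaminant_rate < 1,
          "contaminant_rate must be in [0,1)")
  .assert(all(c(noise_sd_length, noise_sd_width, noise_sd_fluorescence) >= 0),
          "noise SDs must be >= 0")
  .assert(pixels_per_micron > 0 && tof_per_pixel > 0 && ext_per_pixel > 0,
          "conversion and gain factors must be > 0")
  .assert(length(molt_jitter_sd) == 3 && all(molt_jitter_sd >= 0),
          "molt_jitter_sd must be 3 nonnegative values")
  structure(list(
    strain_profiles = strain_profiles,
    n_wells_per_hour = as.integer(n_wells_per_hour),
    n_animals_per_well = as.integer(n_animals_per_well),
    hours = as.numeric(hours),
    contaminant_rate = contaminant_rate,
    noise_sd_length = noise_sd_length,
    noise_sd_width = noise_sd_width,
    noise_sd_fluorescence = noise_sd_fluorescence,
    pixels_per_micron = pixels_per_micron,
    tof_per_pixel = tof_per_pixel,
    ext_per_pixel = ext_per_pixel,
    fluor_gain = fluor_gain,
    molt_jitter_sd = as.numeric(molt_jitter_sd),
    contaminant_params = contaminant_params,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Antiderivative of the stage slope-ratio function c(u):
#   c(u) = c  for u <= onset
#   c(u) = c * (1 + (gain-1) * (u-onset)/(e-onset)) for u > onset
# Vectorized over u (and over onset/e when those are vectors).
.c_antideriv <- function(u, onset, e, cc, gain) {
  base <- cc * u
  ramp_len <- e - onset
  extra <- ifelse(u > onset & gain > 1 & ramp_len > 0,
                  cc * (gain - 1) * (pmin(u, e) - onset)^2 / (2 * ramp_len),
                  0)
  base + extra
}

# Closed-form trajectory evaluation, vectorized over animals.
# t: vector of hours (one per animal); b: n x 3 matrix of per-animal molt
# times. Returns length/width in um, feeding rate in [0,1], and stage index.
.eval_trajectory <- function(t, b, prof) {
  n <- length(t)
  hw <- prof$feeding_dip_halfwidth
  tmin <- prof$span[1]; tmax <- prof$span[2]
  stage <- 1L + (t >= b[, 1]) + (t >= b[, 2]) + (t >= b[, 3])
  L <- W <- numeric(n)
  L0 <- rep(prof$length0, n)
  W0 <- rep(prof$width0, n)
  starts <- cbind(rep(tmin, n), b)
  ends <- cbind(b, rep(tmax, n))
  if (prof$relaxation_direction == "length-relax") {
    dL_step <- 2 * prof$relaxation_magnitude
    dW_step <- -prof$relaxation_magnitude
  } else {
    dL_step <- -prof$relaxation_magnitude
    dW_step <- 0.3 * prof$relaxation_magnitude
  }
  for (k in 1:4) {
    s <- starts[, k]; e <- ends[, k]
    a <- if (k == 1) s else s + hw       # active growth begins after lethargus
    d <- if (k == 4) e else e - hw       # and ends before the next one
    d <- pmax(d, a)
    onset <- s + prof$nonlinear_onset_fraction[k] * (e - s)
    rate <- prof$growth_rate[k]
    cc <- prof$aspect_slope[k]
    g <- prof$nonlinear_slope_gain[k]
    in_k <- stage == k
    if (any(in_k)) {
      u <- pmax(a, pmin(t, d))
      Lk <- L0 + rate * (u - a)
      Wk <- W0 + rate * (.c_antideriv(u, onset, e, cc, g) -
                           .c_antideriv(a, onset, e, cc, g))
      L[in_k] <- Lk[in_k]
      W[in_k] <- Wk[in_k]
    }
    if (k < 4) {
      Lend <- L0 + rate * (d - a)
      Wend <- W0 + rate * (.c_antideriv(d, onset, e, cc, g) -
                             .c_antideriv(a, onset, e, cc, g))
      L0 <- Lend + dL_step
      W0 <- pmax(Wend + dW_step, 1)
    }
  }
  dip_sd <- hw / 2
  feeding <- rep(1, n)
  for (k in 1:3) {
    feeding <- feeding -
      prof$feeding_dip_depth * exp(-0.5 * ((t - b[, k]) / dip_sd)^2)
  }
  feeding <- pmin(pmax(feeding, 0), 1)
  list(length = L, width = W, feeding = feeding, stage = stage)
}

#' Evaluate a strain's noiseless growth trajectory
#'
#' Closed-form population trajectory for one profile: length and width in
#' micrometres and the feeding rate (1 = baseline feeding, dipping at each
#' molt). Length grows linearly in time within each stage, pausing during the
#' lethargus window around each molt; width follows length through the
#' stage-wise slope ratio, which ramps from `c_k` to `c_k * gain` after the
#' nonlinear onset; the post-molt relaxation step is applied at the molt.
#'
#' @param profile a [strain_profile()].
#' @param t hours post-feeding; all values must lie within `profile$span`.
#' @return a data.frame with columns `hour`, `length_um`, `width_um`,
#'   `feeding`, `stage`.
#' @export
simulate_trajectory <- function(profile, t) {
  .assert(inherits(profile, "strain_profile"), "profile must be a strain_profile")
  t <- as.numeric(t)
  if (any(t < profile$span[1] | t > profile$span[2])) {
    stop("t outside the observation span [", profile$span[1], ", ",
         profile$span[2], "]", call. = FALSE)
  }
  b <- matrix(profile$stage_boundaries, nrow = length(t), ncol = 3, byrow = TRUE)
  tr <- .eval_trajectory(t, b, profile)
  data.frame(hour = t, length_um = tr$length, width_um = tr$width,
             feeding = tr$feeding, stage = tr$stage)
}

#' Simulate a full BIOSORT-like object table with ground truth
#'
#' Draws per-object records for every strain, hour and well in the config.
#' Animals get per-animal molt-time jitter (desynchronization growing with
#' stage), micron-level measurement noise, and are converted to instrument
#' units: `tof = tof_per_pixel * pixels_per_micron * length`, `norm_ext`
#' analogously from width, `ext = tof * norm_ext`, and red fluorescence
#' proportional to feeding rate times pixel area. Contaminants are drawn from
#' a two-component mixture (dense small "blobs" and faint elongated
#' "streaks") and labeled in the truth table.
#'
#' @param config a [simulation_config()].
#' @return a list with class `"biosort_simulation"`:
#'   \describe{
#'     \item{records}{data.frame `object_id, strain, well, hour, tof, ext,
#'       norm_ext, red` — what the instrument would report.}
#'     \item{truth}{data.frame `object_id, strain, well, hour, truth_class,
#'       truth_length_um, truth_width_um` (sizes `NA` for contaminants),
#'       row-aligned with `records`.}
#'   }
#' @export
simulate_dataset <- function(config) {
  .assert(inherits(config, "simulation_config"), "config must be a simulation_config")
  cfg <- config
  ppm <- cfg$pixels_per_micron
  cp <- cfg$contaminant_params
  acc <- vector("list", length(cfg$strain_profiles) * length(cfg$hours) *
                  cfg$n_wells_per_hour)
  slot <- 0L
  out <- with_seed(cfg$seed, {
    for (si in seq_along(cfg$strain_profiles)) {
      prof <- cfg$strain_profiles[[si]]
      sid <- prof$strain_id
      for (hi in seq_along(cfg$hours)) {
        h <- cfg$hours[hi]
        for (w in seq_len(cfg$n_wells_per_hour)) {
          set.seed(split_seed(cfg$seed, si, hi, w))
          na <- cfg$n_animals_per_well
          well <- sprintf("%s_h%02d_w%02d", sid, hi, w)
          # per-animal molt-time jitter, SD growing with stage index
          jit <- matrix(stats::rnorm(na * 3, 0, rep(cfg$molt_jitter_sd, each = na)),
                        na, 3)
          b <- matrix(prof$stage_boundaries, na, 3, byrow = TRUE) + jit
          b <- t(apply(b, 1, sort))
          b <- pmin(pmax(b, prof$span[1] + 0.1), prof$span[2] - 0.1)
          tr <- .eval_trajectory(rep(h, na), b, prof)
          len <- pmax(tr$length + stats::rnorm(na, 0, cfg$noise_sd_length), 5)
          wid <- pmax(tr$width + stats::rnorm(na, 0, cfg$noise_sd_width), 0.5)
          tof <- cfg$tof_per_pixel * ppm * len
          nex <- cfg$ext_per_pixel * ppm * wid
          red <- cfg$fluor_gain * tr$feeding * (len * ppm) * (wid * ppm) *
            pmax(1 + stats::rnorm(na, 0, cfg$noise_sd_fluorescence), 0)
          # contaminants: Poisson count so the expected contaminant fraction
          # equals contaminant_rate
          nc <- if (cfg$contaminant_rate > 0) {
            stats::rpois(1, na * cfg$contaminant_rate / (1 - cfg$contaminant_rate))
          } else 0L
          if (nc > 0) {
            is_blob <- stats::runif(nc) < cp$blob_fraction
            nb <- sum(is_blob); ns <- nc - nb
            ctof <- cnex <- cred <- numeric(nc)
            if (nb > 0) {
              ctof[is_blob] <- exp(stats::rnorm(nb, cp$blob_log_tof["mean"],
                                                cp$blob_log_tof["sd"]))
              cnex[is_blob] <- exp(stats::rnorm(nb, cp$blob_log_normext["mean"],
                                                cp$blob_log_normext["sd"]))
              cred[is_blob] <- abs(stats::rnorm(nb, 20, 10))
            }
            if (ns > 0) {
              ctof[!is_blob] <- exp(stats::rnorm(ns, cp$streak_log_tof["mean"],
                                                 cp$streak_log_tof["sd"]))
              cnex[!is_blob] <- exp(stats::rnorm(ns, cp$streak_log_normext["mean"],
                                                 cp$streak_log_normext["sd"]))
              cred[!is_blob] <- abs(stats::rnorm(ns, 5, 3))
            }
            tof <- c(tof, ctof); nex <- c(nex, cnex); red <- c(red, cred)
            len <- c(len, rep(NA_real_, nc)); wid <- c(wid, rep(NA_real_, nc))
            cls <- c(rep("animal", na), rep("contaminant", nc))
          } else {
            cls <- rep("animal", na)
          }
          ntot <- na + nc
          slot <- slot + 1L
          acc[[slot]] <- list(
            object_id = sprintf("%s_o%03d", well, seq_len(ntot)),
            strain = rep(sid, ntot), well = rep(well, ntot),
            hour = rep(h, ntot), tof = tof, ext = tof * nex, norm_ext = nex,
            red = red, truth_class = cls,
            truth_length_um = len, truth_width_um = wid
          )
        }
      }
    }
    acc[seq_len(slot)]
  })
  col <- function(nm) unlist(lapply(out, `[[`, nm), use.names = FALSE)
  records <- data.frame(
    object_id = col("object_id"), strain = col("strain"), well = col("well"),
    hour = col("hour"), tof = col("tof"), ext = col("ext"),
    norm_ext = col("norm_ext"), red = col("red"),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    object_id = records$object_id, strain = records$strain,
    well = records$well, hour = records$hour,
    truth_class = col("truth_class"),
    truth_length_um = col("truth_length_um"),
    truth_width_um = col("truth_width_um"),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, truth = truth, config = config),
            class = "biosort_simulation")
}

#' @export
print.biosort_simulation <- function(x, ...) {
  cat("<biosort_simulation>", nrow(x$records), "objects;",
      length(unique(x$records$strain)), "strain(s);",
      length(unique(x$records$hour)), "hour(s);",
      sum(x$truth$truth_class == "contaminant"), "contaminants\n")
  invisible(x)
}

#' Simulate the manual image-measurement table used for calibration
#'
#' Emulates the calibration protocol: a number of animals per well, across a
#' number of wells per hour, measured in pixels from images (length head to
#' tail, width at the widest point). Measurements are the true micron sizes
#' converted at `pixels_per_micron` plus pixel-level measurement noise.
#'
#' @param sim a `"biosort_simulation"` from [simulate_dataset()].
#' @param n_wells_per_hour wells sampled per hour (default 30, the assay's
#'   imaging design).
#' @param n_per_well animals measured per well (default 5).
#' @param noise_sd_px measurement noise SD in pixels.
#' @param seed integer seed.
#' @return data.frame `hour, well, length_px, width_px` (one row per measured
#'   animal).
#' @export
simulate_manual_measurements <- function(sim, n_wells_per_hour = 30,
                                         n_per_well = 5, noise_sd_px = 4,
                                         seed = 1L) {
  .assert(inherits(sim, "biosort_simulation"), "sim must be a biosort_simulation")
  ppm <- sim$config$pixels_per_micron
  animals <- sim$truth[sim$truth$truth_class == "animal", ]
  with_seed(split_seed(seed, 104729L), {
    res <- lapply(split(animals, animals$hour), function(d) {
      wells <- unique(d$well)
      wells <- wells[seq_len(min(length(wells), n_wells_per_hour))]
      do.call(rbind, lapply(wells, function(wl) {
        dd <- d[d$well == wl, ]
        pick <- sample(nrow(dd), min(n_per_well, nrow(dd)))
        data.frame(
          hour = dd$hour[pick], well = wl,
          length_px = dd$truth_length_um[pick] * ppm +
            stats::rnorm(length(pick), 0, noise_sd_px),
          width_px = pmax(dd$truth_width_um[pick] * ppm +
                            stats::rnorm(length(pick), 0, noise_sd_px / 4), 1),
          stringsAsFactors = FALSE
        )
      }))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Write a simulated dataset to plain-text CSVs
#'
#' Writes `raw_objects.csv` with the instrument schema
#' `strain,well,hour,tof,ext,norm_ext,red` and a row-aligned `truth.csv`
#' carrying `truth_class,truth_length_um,truth_width_um`.
#'
#' @param sim a `"biosort_simulation"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_csv <- function(sim, dir) {
  .assert(inherits(sim, "biosort_simulation"), "sim must be a biosort_simulation")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw <- file.path(dir, "raw_objects.csv")
  tru <- file.path(dir, "truth.csv")
  utils::write.csv(sim$records[, c("strain", "well", "hour", "tof", "ext",
                                   "norm_ext", "red")],
                   raw, row.names = FALSE)
  utils::write.csv(sim$truth[, c("strain", "well", "hour", "truth_class",
                                 "truth_length_um", "truth_width_um")],
                   tru, row.names = FALSE)
  invisible(c(raw = raw, truth = tru))
}

#' Read a raw object table written by [write_simulated_csv()]
#'
#' @param path path to a CSV with columns
#'   `strain,well,hour,tof,ext,norm_ext,red`.
#' @return a data.frame of object records.
#' @export
read_biosort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "well", "hour", "tof", "ext", "norm_ext", "red")
  .assert(all(need %in% names(d)),
          paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  d
}
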