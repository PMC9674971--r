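#' Default per-strain, per-stage growth windows
#'
#' The study's growth windows: hour ranges of active growth, excluding
#' post-molt relaxation, used to select well observations for the shape
#' analysis. L1 is 1-10 h for all strains; L2 is 16-22 (N2, lon-3), 19-26
#' (dpy-1), 19-24 (dpy-5); L3 is 27-31 (N2), 27-32 (lon-3), 31-35 (dpy-1),
#' 30-34 (dpy-5). No L4 window is defined (the population is too variable in
#' L4 to analyze).
#'
#' @return data.frame `strain, stage, start, end`.
#' @seealso [windows_from_molts()] for windows derived from detected molts.
#' @export
stage_windows <- function() {
  data.frame(
    strain = rep(c("N2", "dpy-1", "dpy-5", "lon-3"), each = 3),
    stage = rep(c("L1", "L2", "L3"), times = 4),
    start = c(1, 16, 27,  1, 19, 31,  1, 19, 30,  1, 16, 27),
    end   = c(10, 22, 31, 10, 26, 35, 10, 24, 34, 10, 22, 32),
    stringsAsFactors = FALSE
  )
}

#' Build growth windows from detected molt annotations
#'
#' For each strain, stage k runs from molt k-1 (or the span start) plus
#' `relax_margin` to molt k minus `relax_margin`, so that post-molt
#' relaxation periods are excluded. L4 is not produced.
#'
#' @param annotations list of [detect_molts()] annotations (one per strain).
#' @param relax_margin hours trimmed at each end of a stage; default 2.
#' @param span_start first observed hour; default 1.
#' @return data.frame `strain, stage, start, end`.
#' @export
windows_from_molts <- function(annotations, relax_margin = 2, span_start = 1) {
  rows <- lapply(annotations, function(a) {
    m <- a$molt_times
    if (length(m) == 0) return(NULL)
    edges <- c(span_start, m)
    k <- length(m)
    data.frame(
      strain = a$strain,
      stage = paste0("L", seq_len(k)),
      start = ifelse(seq_len(k) == 1, span_start, edges[seq_len(k)] + relax_margin),
      end = m - relax_margin,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[out$end > out$start, ]
  rownames(out) <- NULL
  out
}

#' Select the well observations inside a growth window
#'
#' @param summaries a calibrated `"well_summary"` data.frame (with
#'   `median_length_um`, `median_width_um`).
#' @param windows a window table as from [stage_windows()].
#' @param strain,stage which window to apply.
#' @return data.frame `well, hour, length_um, width_um`, one row per well.
#' @export
select_window <- function(summaries, windows, strain, stage) {
  w <- windows[windows$strain == strain & windows$stage == stage, ]
  if (nrow(w) == 0) {
    stop("select_window: no growth window defined for ", strain, " ", stage,
         call. = FALSE)
  }
  .assert(all(c("median_length_um", "median_width_um") %in% names(summaries)),
          "summaries must be unit-converted (see convert_units)")
  d <- summaries[summaries$strain == strain &
                   summaries$hour >= w$start[1] & summaries$hour <= w$end[1], ]
  if (nrow(d) == 0) {
    stop("select_window: no observations for ", strain, " ", stage,
         " in [", w$start[1], ", ", w$end[1], "]", call. = FALSE)
  }
  data.frame(well = d$well, hour = d$hour,
             length_um = d$median_length_um, width_um = d$median_width_um,
             stringsAsFactors = FALSE)
}

#' Kernel-smoothed shape curves with cluster-bootstrap bands
#'
#' Smooths well-level length and width against hour by local-linear Gaussian
#' kernel regression on a fine grid, and quantifies population uncertainty by
#' a cluster bootstrap: whole wells are resampled with replacement and the
#' smoothing repeated per replicate; the same resamples are used for length
#' and width so downstream ratios are computed within replicate. Deterministic
#' under `seed`.
#'
#' @param obs data.frame `well, hour, length_um, width_um` (e.g. from
#'   [select_window()]); at least 5 distinct wells.
#' @param n_boot number of bootstrap replicates (>= 100); default 1000.
#' @param h_bw kernel bandwidth in hours; default 0.5.
#' @param grid_step grid resolution in hours (<= 0.25); default 0.25.
#' @param seed integer seed for the resampling.
#' @return an object of class `"shape_curves"`: `grid`, and for each of
#'   `length`/`width` the central `fit` and `deriv`, bootstrap matrices
#'   `boot_fit`/`boot_deriv` (`n_boot` x grid), and per-grid bootstrap
#'   `mean`/`sd` of the fit.
#' @export
bootstrap_bands <- function(obs, n_boot = 1000, h_bw = 0.5, grid_step = 0.25,
                            seed = 1L) {
  .assert(all(c("well", "hour", "length_um", "width_um") %in% names(obs)),
          "obs must have well, hour, length_um, width_um")
  wells <- unique(obs$well)
  nw <- length(wells)
  .assert(nw >= 5, "bootstrap_bands: need >= 5 wells")
  .assert(n_boot >= 100, "bootstrap_bands: need n_boot >= 100")
  .assert(grid_step <= 0.25, "grid_step must be <= 0.25 h")
  grid <- seq(min(obs$hour), max(obs$hour), by = grid_step)
  ks <- .kernel_design(obs$hour, grid, h_bw)
  widx <- match(obs$well, wells)
  ones <- rep(1, nrow(obs))
  cenL <- .kernel_solve(ks, obs$length_um, ones)
  cenW <- .kernel_solve(ks, obs$width_um, ones)
  if (anyNA(cenL$fit) || anyNA(cenW$fit)) {
    stop("bootstrap_bands: grid point(s) with no effective neighbors; ",
         "increase h_bw", call. = FALSE)
  }
  ng <- length(grid)
  bfL <- bdL <- bfW <- bdW <- matrix(NA_real_, n_boot, ng)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      counts <- tabulate(sample.int(nw, nw, replace = TRUE), nbins = nw)
      m <- counts[widx]
      rl <- .kernel_solve(ks, obs$length_um, m)
      rw <- .kernel_solve(ks, obs$width_um, m)
      bfL[b, ] <- rl$fit; bdL[b, ] <- rl$deriv
      bfW[b, ] <- rw$fit; bdW[b, ] <- rw$deriv
    }
  })
  mk <- function(cen, bf, bd) list(
    fit = cen$fit, deriv = cen$deriv, boot_fit = bf, boot_deriv = bd,
    mean = colMeans(bf, na.rm = TRUE),
    sd = apply(bf, 2, stats::sd, na.rm = TRUE)
  )
  structure(list(grid = grid,
                 length = mk(cenL, bfL, bdL),
                 width = mk(cenW, bfW, bdW),
                 n_boot = n_boot, h_bw = h_bw, n_wells = nw, seed = seed),
            class = "shape_curves")
}

#' The local slope ratio r(t) = dW/dL with a bootstrap SD band
#'
#' Computes, within each bootstrap replicate, the ratio of the local width
#' slope to the local length slope, then reports the across-replicate mean as
#' the central curve and the across-replicate SD as the band (so the band
#' reflects ratio variability, not a ratio of averaged derivatives). Grid
#' points where the central length slope falls below `deriv_floor_frac` of
#' the window's median absolute length slope are masked to avoid ratio
#' blow-up; the same floor is applied within replicates.
#'
#' @param curves a `"shape_curves"` object from [bootstrap_bands()].
#' @param deriv_floor_frac slope floor as a fraction of the median absolute
#'   central length slope; default 0.05.
#' @return an object of class `"slope_ratio_curve"`: data.frame
#'   `t, r, sd, masked` with attributes `n_boot`, `h_bw`.
#' @export
slope_ratio <- function(curves, deriv_floor_frac = 0.05) {
  .assert(inherits(curves, "shape_curves"), "curves must be shape_curves")
  dL <- curves$length$deriv
  # absolute floor guards against windows with no length growth at all,
  # where the relative floor would be numerically zero
  abs_floor <- 1e-9 * (mean(abs(curves$length$fit)) + 1) /
    diff(range(curves$grid))
  floor_abs <- max(deriv_floor_frac * stats::median(abs(dL)), abs_floor)
  masked <- abs(dL) < floor_abs
  bdL <- curves$length$boot_deriv
  bdW <- curves$width$boot_deriv
  rmat <- bdW / bdL
  rmat[abs(bdL) < floor_abs] <- NA_real_
  r <- colMeans(rmat, na.rm = TRUE)
  sdv <- apply(rmat, 2, stats::sd, na.rm = TRUE)
  na_frac <- colMeans(is.na(rmat))
  masked <- masked | na_frac > 0.5 | !is.finite(r)
  if (all(masked)) {
    stop("slope_ratio: all grid points masked (no resolvable length growth)",
         call. = FALSE)
  }
  out <- data.frame(t = curves$grid, r = r, sd = sdv, masked = masked)
  out$r[masked] <- NA_real_
  out$sd[masked] <- NA_real_
  attr(out, "n_boot") <- curves$n_boot
  attr(out, "h_bw") <- curves$h_bw
  class(out) <- c("slope_ratio_curve", "data.frame")
  out
}

#' Segment a slope-ratio curve into linear and nonlinear stretch regimes
#'
#' The linear-regime baseline is the median of r(t) over the first third of
#' the window (the linear regime sits at the start of a larval stage). The
#' nonlinear onset is the earliest grid time after which
#' `r(t) - baseline > z * SD(t)` holds at every later unmasked point; points
#' from the onset on are labeled `"nonlinear"`, which therefore always forms
#' a suffix of the window. If the threshold is never durably crossed the
#' whole window is `"linear"`. Windows shorter than 3 h are returned
#' unclassified and flagged.
#'
#' @param curve a `"slope_ratio_curve"` from [slope_ratio()].
#' @param z threshold in bootstrap SDs; default 2. Increasing `z` never moves
#'   the onset earlier.
#' @return an object of class `"regime_segmentation"`: `labels` (data.frame
#'   `t, label`), `onset` (hour or `NA`), `baseline`, `z`, `flagged`.
#' @export
classify_regimes <- function(curve, z = 2) {
  .assert(inherits(curve, "slope_ratio_curve"), "curve must be a slope_ratio_curve")
  tspan <- diff(range(curve$t))
  if (tspan < 3) {
    return(structure(list(labels = data.frame(t = curve$t, label = NA_character_),
                          onset = NA_real_, baseline = NA_real_, z = z,
                          flagged = TRUE),
                     class = "regime_segmentation"))
  }
  first_third <- curve$t <= min(curve$t) + tspan / 3
  base_vals <- curve$r[first_third & !curve$masked]
  .assert(length(base_vals) > 0, "no unmasked points in the first third of the window")
  baseline <- stats::median(base_vals)
  ok <- !curve$masked & (curve$r - baseline > z * curve$sd)
  onset <- NA_real_
  idx_un <- which(!curve$masked)
  if (length(idx_un) > 0) {
    # earliest unmasked index from which every later unmasked point exceeds
    # the threshold
    exceeds <- ok[idx_un]
    suffix_all <- rev(cumprod(rev(exceeds))) == 1
    if (any(suffix_all)) onset <- curve$t[idx_un[suffix_all][1]]
  }
  label <- rep("linear", nrow(curve))
  if (!is.na(onset)) label[curve$t >= onset] <- "nonlinear"
  structure(list(labels = data.frame(t = curve$t, label = label),
                 onset = onset, baseline = baseline, z = z, flagged = FALSE),
            class = "regime_segmentation")
}

#' Characterize post-molt relaxation from well summaries
#'
#' For each detected molt, compares the population median length and width in
#' the pre-molt window `[molt - margin, molt)` against the post-molt window
#' `(molt, molt + margin]`. The direction is `"length-relax"` when length
#' steps up and width decreases (`dL > 0, dW < 0`), `"width-relax"` when
#' length decreases and width moves the opposite way (`dL < 0, dW > 0`); the
#' reported magnitude is the absolute value of the decreasing component. Any
#' other sign pattern is flagged `"ambiguous"` with zero magnitude. Molts too
#' close to the span edge for the margins are skipped with a message.
#'
#' @param summaries a calibrated `"well_summary"` data.frame.
#' @param molts a `"molt_annotation"` or list of them.
#' @param margin half-window in hours on each side of the molt; default 2.
#' @return data.frame `strain, molt, molt_hour, delta_length_um,
#'   delta_width_um, direction, magnitude_um, flagged`.
#' @export
characterize_relaxation <- function(summaries, molts, margin = 2) {
  .assert(margin > 0, "margin must be > 0")
  .assert(all(c("median_length_um", "median_width_um") %in% names(summaries)),
          "summaries must be unit-converted (see convert_units)")
  if (inherits(molts, "molt_annotation")) molts <- list(molts)
  rows <- list()
  for (a in molts) {
    d <- summaries[summaries$strain == a$strain, ]
    if (nrow(d) == 0) next
    span <- range(d$hour)
    for (k in seq_along(a$molt_times)) {
      m <- a$molt_times[k]
      if (m - margin < span[1] || m + margin > span[2]) {
        message("characterize_relaxation: molt at ", m, " h too close to the ",
                "span edge for margin ", margin, "; skipped")
        next
      }
      pre <- d[d$hour >= m - margin & d$hour < m, ]
      post <- d[d$hour > m & d$hour <= m + margin, ]
      if (nrow(pre) == 0 || nrow(post) == 0) {
        message("characterize_relaxation: no observations around molt at ",
                m, " h; skipped")
        next
      }
      dL <- stats::median(post$median_length_um) - stats::median(pre$median_length_um)
      dW <- stats::median(post$median_width_um) - stats::median(pre$median_width_um)
      if (dL > 0 && dW < 0) {
        dir <- "length-relax"; mag <- abs(dW); flag <- FALSE
      } else if (dL < 0 && dW > 0) {
        dir <- "width-relax"; mag <- abs(dL); flag <- FALSE
      } else {
        dir <- "ambiguous"; mag <- 0; flag <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strain = a$strain, molt = k, molt_hour = m,
        delta_length_um = dL, delta_width_um = dW,
        direction = dir, magnitude_um = mag, flagged = flag,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(strain = character(), molt = integer(),
                      molt_hour = numeric(), delta_length_um = numeric(),
                      delta_width_um = numeric(), direction = character(),
                      magnitude_um = numeric(), flagged = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the Stretcher shape-dynamics analysis
#'
#' The package's central fit. For every (strain, stage) growth window it
#' smooths the well-level length and width trajectories (local-linear
#' Gaussian kernel regression), quantifies uncertainty by cluster bootstrap
#' over wells, forms the local slope-ratio curve r(t) = dW/dL with its SD
#' band, and segments the window into the linear stretch regime (constant
#' ratio, start of stage) and the nonlinear stretch regime (rising ratio,
#' end of stage). If molt annotations are available (passed or detected from
#' the fluorescence channel) the post-molt relaxation at each molt is
#' characterized as well.
#'
#' @param summaries a calibrated `"well_summary"` data.frame (see
#'   [convert_units()]); needs `median_norm_fluorescence` for molt detection.
#' @param windows growth-window table; default [stage_windows()], the study
#'   windows. Use [windows_from_molts()] to analyze detected windows instead.
#' @param molts optional `"molt_annotation"` list; if `NULL`, molts are
#'   detected per strain from the fluorescence channel when present.
#' @param h_bw kernel bandwidth (hours); default 0.5 (matched to the hourly sampling so regime-transition times are localized without bias).
#' @param n_boot bootstrap replicates per window; default 1000.
#' @param grid_step grid resolution (hours, <= 0.25).
#' @param z regime-segmentation threshold in bootstrap SDs; default 2.
#' @param deriv_floor_frac slope-ratio masking floor; see [slope_ratio()].
#' @param relax_margin half-window for relaxation characterization (hours).
#' @param seed master seed; each window gets a derived sub-seed.
#' @return an object of class `"stretcher"` with per-window results
#'   (`curves`, `ratio`, `segmentation`), the `relaxation` table, `molts`,
#'   `windows` and fit parameters. See [coef.stretcher()],
#'   [summary.stretcher()], [plot.stretcher()].
#' @examples
#' sim <- simulate_dataset(simulation_config(
#'   strain_profiles = default_strain_profiles()["N2"],
#'   n_wells_per_hour = 6, n_animals_per_well = 15, contaminant_rate = 0,
#'   seed = 7))
#' sums <- summarize_wells(sim$records)
#' cal <- structure(list(pixels_per_micron = 3.2937,
#'                       tof_to_um_slope = 1 / 3.2937,
#'                       normext_to_um_slope = 1 / 3.2937,
#'                       fit_diagnostics = c(0, 0), n_pairs = 0),
#'                  class = "biosort_calibration")
#' fit <- stretcher(convert_units(sums, cal), n_boot = 100, seed = 7)
#' coef(fit)
#' @export
stretcher <- function(summaries, windows = stage_windows(), molts = NULL,
                      h_bw = 0.5, n_boot = 1000, grid_step = 0.25, z = 2,
                      deriv_floor_frac = 0.05, relax_margin = 2, seed = 1L) {
  strains <- intersect(unique(windows$strain), unique(summaries$strain))
  .assert(length(strains) > 0, "no strain in common between summaries and windows")
  results <- list()
  i <- 0L
  for (s in strains) {
    for (st in windows$stage[windows$strain == s]) {
      i <- i + 1L
      obs <- tryCatch(select_window(summaries, windows, s, st),
                      error = function(e) {
                        message(conditionMessage(e)); NULL
                      })
      if (is.null(obs)) next
      curves <- bootstrap_bands(obs, n_boot = n_boot, h_bw = h_bw,
                                grid_step = grid_step,
                                seed = split_seed(seed, i))
      ratio <- slope_ratio(curves, deriv_floor_frac = deriv_floor_frac)
      seg <- classify_regimes(ratio, z = z)
      results[[paste(s, st, sep = ":")]] <- list(
        strain = s, stage = st, obs = obs, curves = curves,
        ratio = ratio, segmentation = seg
      )
    }
  }
  .assert(length(results) > 0, "no analyzable (strain, stage) windows")
  if (is.null(molts) && "median_norm_fluorescence" %in% names(summaries)) {
    molts <- lapply(strains, function(s)
      suppressWarnings(detect_molts(fluorescence_series(summaries, s))))
  }
  relaxation <- if (!is.null(molts)) {
    characterize_relaxation(summaries, molts, margin = relax_margin)
  } else NULL
  structure(list(
    results = results, relaxation = relaxation, molts = molts,
    windows = windows,
    params = list(h_bw = h_bw, n_boot = n_boot, grid_step = grid_step, z = z,
                  deriv_floor_frac = deriv_floor_frac,
                  relax_margin = relax_margin, seed = seed),
    call = match.call()
  ), class = "stretcher")
}

#' Linear-regime slope ratios of a Stretcher fit
#'
#' @param object a `"stretcher"` fit.
#' @param ... unused.
#' @return data.frame `strain, stage, slope_ratio, onset_hour`: the mean of
#'   r(t) over the linear-regime grid points (the estimate of the stage's
#'   baseline aspect slope c_k) and the detected nonlinear onset (`NA` when
#'   the whole window is linear).
#' @export
coef.stretcher <- function(object, ...) {
  rows <- lapply(object$results, function(res) {
    lin <- res$segmentation$labels$label == "linear" & !res$ratio$masked
    data.frame(strain = res$strain, stage = res$stage,
               slope_ratio = mean(res$ratio$r[lin], na.rm = TRUE),
               onset_hour = res$segmentation$onset,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.stretcher <- function(x, ...) {
  cat("<stretcher fit>\n")
  cat("  windows analyzed :", length(x$results), "\n")
  cat("  bootstrap        :", x$params$n_boot, "replicates, bandwidth",
      x$params$h_bw, "h\n")
  cf <- coef(x)
  cat("  linear-regime dW/dL:\n")
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("    %-6s %-3s  r = %.4f   nonlinear onset: %s h\n",
                cf$strain[i], cf$stage[i], cf$slope_ratio[i],
                ifelse(is.na(cf$onset_hour[i]), "none", format(cf$onset_hour[i]))))
  }
  invisible(x)
}

#' Summarize a Stretcher fit
#'
#' @param object a `"stretcher"` fit.
#' @param ... unused.
#' @return a `"summary.stretcher"` list with the coefficient table and the
#'   relaxation table.
#' @export
summary.stretcher <- function(object, ...) {
  structure(list(coef = coef(object), relaxation = object$relaxation,
                 params = object$params),
            class = "summary.stretcher")
}

#' @export
print.summary.stretcher <- function(x, ...) {
  cat("Stretcher shape-dynamics fit\n\n")
  cat("Linear-regime slope ratios (dW/dL) and nonlinear onsets:\n")
  print(x$coef, row.names = FALSE)
  if (!is.null(x$relaxation) && nrow(x$relaxation) > 0) {
    cat("\nPost-molt relaxation:\n")
    print(x$relaxation, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a Stretcher fit
#'
#' `type = "ratio"` draws the slope-ratio curve r(t) per analyzed window with
#' the bootstrap SD band shaded and the nonlinear onset marked;
#' `type = "phase"` draws the smoothed length-width phase plane per window.
#'
#' @param x a `"stretcher"` fit.
#' @param type `"ratio"` or `"phase"`.
#' @param ... passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.stretcher <- function(x, type = c("ratio", "phase"), ...) {
  type <- match.arg(type)
  n <- length(x$results)
  old <- graphics::par(mfrow = grDevices::n2mfrow(n), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (res in x$results) {
    if (type == "ratio") {
      d <- res$ratio[!res$ratio$masked, ]
      ylim <- range(c(d$r - d$sd, d$r + d$sd), na.rm = TRUE)
      plot(d$t, d$r, type = "n", ylim = ylim, xlab = "hour",
           ylab = "dW/dL", main = paste(res$strain, res$stage), ...)
      graphics::polygon(c(d$t, rev(d$t)), c(d$r - d$sd, rev(d$r + d$sd)),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
      graphics::lines(d$t, d$r, lwd = 2, col = "steelblue4")
      if (!is.na(res$segmentation$onset)) {
        graphics::abline(v = res$segmentation$onset, lty = 2, col = "firebrick")
      }
    } else {
      plot(res$curves$length$fit, res$curves$width$fit, type = "l", lwd = 2,
           xlab = "length (um)", ylab = "width (um)",
           main = paste(res$strain, res$stage), ...)
    }
  }
  invisible(x)
}
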