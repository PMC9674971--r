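#' Remove non-animal objects from raw cytometer records
#'
#' Separates animal objects from contaminants (bacterial clumps, shed
#' cuticles, next-generation larvae) without using any truth annotation. The
#' rule, applied independently to each (strain, hour) pool of objects (the
#' animals of one strain at one hour form a single tight size cluster):
#'
#' * **Model-based gate** (pools of at least `min_cluster_n` objects):
#'   a Gaussian mixture with 1 to `max_components` components is fitted to
#'   `(log tof, log ext)` by [mclust::Mclust()]. Objects are removed only if
#'   a multi-component model is decisively better than a single Gaussian
#'   (BIC improvement larger than `bic_margin`). The largest component is
#'   called animal (animals dominate every pool at any contamination rate
#'   below one half); any other component whose mean lies within
#'   `min_separation` of the animal mean in both log-TOF and log-EXT is
#'   merged back into the kept set (transitively, so the pre- and post-molt
#'   sub-clusters that straddle a molt are never half-discarded). Where a
#'   component was discarded, kept objects that are better explained by a
#'   discarded component (higher unweighted component density) and extreme
#'   under every kept component (Mahalanobis beyond the 99.9% chi-squared
#'   quantile) are trimmed as well. Otherwise the pool is treated as
#'   uncontaminated.
#' * **Robust-quantile fallback** (small pools): keep objects whose log-TOF
#'   and log-EXT lie within 1.5 IQR of the pool medians.
#' * A single object passes through untouched.
#' * **Late-hour size floor**: after `floor_after_hour`, objects with
#'   `tof < tof_floor` are removed regardless (next-generation larvae are
#'   small animals, indistinguishable by shape alone).
#'
#' Each pool is iterated to a fixed point (the rule is re-applied to the kept
#' set until nothing further is removed, at most `max_iter` times), so gating
#' is idempotent: gating the kept set removes nothing. The decision is
#' deterministic given the input.
#'
#' @param records data.frame of object records with columns `hour`, `tof`,
#'   `ext` (additional columns are carried through).
#' @param min_cluster_n minimum pool size for the model-based gate.
#' @param max_components maximum number of mixture components considered.
#' @param bic_margin required BIC improvement of a multi-component model over
#'   a single Gaussian before any object is removed.
#' @param min_separation required component mean separation (log units) from
#'   the animal component before a component is discarded.
#' @param tof_floor instrument-unit TOF floor applied after `floor_after_hour`.
#' @param floor_after_hour hour after which the TOF floor applies.
#' @param max_iter maximum fixed-point iterations per pool.
#' @return a list with elements `kept` and `removed`, a partition of `records`.
#' @export
gate_animals <- function(records, min_cluster_n = 20, max_components = 4,
                         bic_margin = 10, min_separation = 0.8,
                         tof_floor = 600, floor_after_hour = 30,
                         max_iter = 20) {
  if (is.null(records) || nrow(records) == 0) {
    warning("gate_animals: empty input")
    return(list(kept = records, removed = records))
  }
  .assert(all(c("hour", "tof", "ext") %in% names(records)),
          "records must have hour, tof, ext columns")
  keep <- rep(TRUE, nrow(records))
  pool <- if ("strain" %in% names(records)) {
    paste(records$strain, records$hour)
  } else {
    as.character(records$hour)
  }
  for (h in unique(pool)) {
    idx <- which(pool == h)
    for (it in seq_len(max_iter)) {
      cur <- idx[keep[idx]]
      ok <- .gate_pool(log(records$tof[cur]), log(records$ext[cur]),
                       min_cluster_n, max_components, bic_margin,
                       min_separation)
      if (all(ok)) break
      keep[cur[!ok]] <- FALSE
    }
  }
  late <- records$hour > floor_after_hour & records$tof < tof_floor
  keep[late] <- FALSE
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

# One pass of the pool-level gate: returns a logical keep mask.
.gate_pool <- function(lt, le, min_cluster_n, max_components, bic_margin,
                       min_separation) {
  n <- length(lt)
  ok <- rep(TRUE, n)
  if (n <= 1) return(ok)  # degenerate input passes through
  if (n < min_cluster_n) {
    iqr_t <- stats::IQR(lt); iqr_e <- stats::IQR(le)
    return(abs(lt - stats::median(lt)) <= 1.5 * iqr_t + 1e-12 &
             abs(le - stats::median(le)) <= 1.5 * iqr_e + 1e-12)
  }
  X <- cbind(log_tof = lt, log_ext = le)
  ctrl <- mclust::emControl(itmax = c(200, 200), tol = c(1e-4, 1e-5))
  fit1 <- tryCatch(Mclust(X, G = 1, verbose = FALSE, control = ctrl),
                   error = function(e) NULL)
  fitk <- tryCatch(Mclust(X, G = 2:max_components, verbose = FALSE,
                          control = ctrl),
                   error = function(e) NULL)
  if (is.null(fit1) || is.null(fitk)) return(ok)
  if (!is.finite(fitk$bic) || !is.finite(fit1$bic) ||
      fitk$bic - fit1$bic <= bic_margin) return(ok)
  mu <- fitk$parameters$mean  # dims x components
  sizes <- tabulate(fitk$classification, nbins = fitk$G)
  animal_comp <- which.max(sizes)
  # grow the kept set transitively: a component within min_separation of any
  # kept component belongs to the animal cloud (near molts the animal
  # population is genuinely bimodal: pre- and post-molt sub-clusters)
  kept_comps <- animal_comp
  repeat {
    add <- integer(0)
    for (g in setdiff(seq_len(fitk$G), kept_comps)) {
      sep <- min(vapply(kept_comps,
                        function(k) max(abs(mu[, g] - mu[, k])), 0))
      if (sep < min_separation) add <- c(add, g)
    }
    if (length(add) == 0) break
    kept_comps <- c(kept_comps, add)
  }
  ok <- fitk$classification %in% kept_comps
  disc_comps <- setdiff(seq_len(fitk$G), kept_comps)
  if (length(disc_comps) > 0) {
    # contaminants straggling into the animal cloud are soft-assigned to the
    # large animal component by its prior weight; re-assign by unweighted
    # component density: trim kept points better explained by a discarded
    # component, provided they are also extreme under every kept component
    cd <- tryCatch(mclust::cdens(fitk$modelName, X,
                                 parameters = fitk$parameters),
                   error = function(e) NULL)
    md_kept <- rep(Inf, n)
    for (k in kept_comps) {
      mk <- tryCatch(stats::mahalanobis(X, mu[, k],
                                        fitk$parameters$variance$sigma[, , k]),
                     error = function(e) NULL)
      if (!is.null(mk)) md_kept <- pmin(md_kept, mk)
    }
    if (!is.null(cd) && all(is.finite(md_kept))) {
      dens_kept <- apply(cd[, kept_comps, drop = FALSE], 1, max)
      dens_disc <- apply(cd[, disc_comps, drop = FALSE], 1, max)
      ok <- ok & !(dens_disc > dens_kept &
                     md_kept > stats::qchisq(0.999, df = 2))
    }
  }
  ok
}

#' Summarize kept records into per-well medians
#'
#' One row per (strain, well, hour): median TOF, median norm.EXT, and the
#' median area-normalized fluorescence, computed per object as
#' `red / (tof * norm_ext)` (the optical-area proxy) before taking the
#' median. Wells whose objects were all removed are omitted with a message.
#'
#' @param kept data.frame of kept (animal-classified) records with columns
#'   `strain, well, hour, tof, norm_ext, red`.
#' @param removed optional data.frame of removed records, used only to fill
#'   `n_objects_removed` per well.
#' @return data.frame of class `"well_summary"` with columns `strain, well,
#'   hour, median_tof, median_norm_ext, median_norm_fluorescence,
#'   n_objects_kept, n_objects_removed`.
#' @export
summarize_wells <- function(kept, removed = NULL) {
  .assert(all(c("strain", "well", "hour", "tof", "norm_ext", "red") %in% names(kept)),
          "kept records must carry strain/well/hour keys and measurements")
  if (nrow(kept) == 0) {
    message("summarize_wells: no kept records")
    out <- data.frame(strain = character(), well = character(), hour = numeric(),
                      median_tof = numeric(), median_norm_ext = numeric(),
                      median_norm_fluorescence = numeric(),
                      n_objects_kept = integer(), n_objects_removed = integer())
    class(out) <- c("well_summary", "data.frame")
    return(out)
  }
  key <- interaction(kept$strain, kept$well, kept$hour, drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(seq_len(nrow(kept)), key), function(ix) {
    d <- kept[ix, ]
    data.frame(
      strain = d$strain[1], well = d$well[1], hour = d$hour[1],
      median_tof = stats::median(d$tof),
      median_norm_ext = stats::median(d$norm_ext),
      median_norm_fluorescence = stats::median(d$red / (d$tof * d$norm_ext)),
      n_objects_kept = nrow(d),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$strain, out$hour, out$well), ]
  rownames(out) <- NULL
  out$n_objects_removed <- 0L
  if (!is.null(removed) && nrow(removed) > 0) {
    rem <- table(paste(removed$strain, removed$well, removed$hour, sep = "\r"))
    k <- paste(out$strain, out$well, out$hour, sep = "\r")
    hit <- match(k, names(rem))
    out$n_objects_removed[!is.na(hit)] <- as.integer(rem[hit[!is.na(hit)]])
    gone <- setdiff(names(rem), k)
    if (length(gone) > 0) {
      message("summarize_wells: ", length(gone),
              " well(s) had no kept objects and were omitted")
    }
  }
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Convert manual pixel measurements to micrometres
#'
#' @param px pixel measurement(s).
#' @param pixels_per_micron conversion factor, default 3.2937 px/um.
#' @return micrometres.
#' @export
px_to_um <- function(px, pixels_per_micron = 3.2937) {
  .assert(pixels_per_micron > 0, "pixels_per_micron must be > 0")
  px / pixels_per_micron
}

#' @rdname px_to_um
#' @param um micrometre measurement(s).
#' @export
um_to_px <- function(um, pixels_per_micron = 3.2937) {
  .assert(pixels_per_micron > 0, "pixels_per_micron must be > 0")
  um * pixels_per_micron
}

#' Fit the instrument-to-micron calibration
#'
#' Manual image measurements (pixels) are converted to micrometres with the
#' fixed imaging factor and regressed, through the origin, on the matched
#' per-well instrument medians: micron length on `median_tof` and micron
#' width on `median_norm_ext`. Through-origin is the physically sensible
#' parameterization (a zero-length object has zero TOF) and avoids
#' extrapolation artifacts at small L1 sizes.
#'
#' @param manual data.frame `hour, well, length_px, width_px`, one row per
#'   measured animal (several animals per well).
#' @param summaries a `"well_summary"` data.frame to match against, by
#'   `(well, hour)`.
#' @param pixels_per_micron imaging conversion factor, default 3.2937 px/um.
#' @param min_pairs minimum matched (instrument, manual) well pairs required.
#' @return an object of class `"biosort_calibration"` with elements
#'   `pixels_per_micron`, `tof_to_um_slope`, `normext_to_um_slope`,
#'   `fit_diagnostics` (residual SD per dimension), `n_pairs`.
#' @export
fit_calibration <- function(manual, summaries, pixels_per_micron = 3.2937,
                            min_pairs = 10) {
  .assert(all(c("hour", "well", "length_px", "width_px") %in% names(manual)),
          "manual must have hour, well, length_px, width_px")
  agg <- stats::aggregate(cbind(length_px, width_px) ~ well + hour,
                          data = manual, FUN = stats::median)
  pairs <- merge(agg, summaries, by = c("well", "hour"))
  if (nrow(pairs) < min_pairs) {
    stop("fit_calibration: only ", nrow(pairs), " matched pairs (need >= ",
         min_pairs, ")", call. = FALSE)
  }
  pairs$length_um <- px_to_um(pairs$length_px, pixels_per_micron)
  pairs$width_um <- px_to_um(pairs$width_px, pixels_per_micron)
  fl <- stats::lm(length_um ~ 0 + median_tof, data = pairs)
  fw <- stats::lm(width_um ~ 0 + median_norm_ext, data = pairs)
  sl <- unname(stats::coef(fl))
  sw <- unname(stats::coef(fw))
  .assert(sl > 0 && sw > 0, "calibration slopes must be positive")
  structure(list(
    pixels_per_micron = pixels_per_micron,
    tof_to_um_slope = sl,
    normext_to_um_slope = sw,
    fit_diagnostics = c(length_resid_sd = stats::sd(stats::resid(fl)),
                        width_resid_sd = stats::sd(stats::resid(fw))),
    n_pairs = nrow(pairs)
  ), class = "biosort_calibration")
}

#' @export
print.biosort_calibration <- function(x, ...) {
  cat("<biosort_calibration>\n")
  cat(sprintf("  pixels per micron : %.4f\n", x$pixels_per_micron))
  cat(sprintf("  um per TOF unit   : %.6g\n", x$tof_to_um_slope))
  cat(sprintf("  um per nEXT unit  : %.6g\n", x$normext_to_um_slope))
  cat(sprintf("  residual SD (um)  : length %.3g, width %.3g  (%d well pairs)\n",
              x$fit_diagnostics[1], x$fit_diagnostics[2], x$n_pairs))
  invisible(x)
}

#' Convert well summaries to micrometres
#'
#' Applies a fitted [fit_calibration()] model:
#' `median_length_um = tof_to_um_slope * median_tof` and
#' `median_width_um = normext_to_um_slope * median_norm_ext`. Raw instrument
#' columns are retained, so the conversion is invertible.
#'
#' @param summaries a `"well_summary"` data.frame.
#' @param model a `"biosort_calibration"`.
#' @return `summaries` with `median_length_um` and `median_width_um` added.
#' @export
convert_units <- function(summaries, model) {
  if (missing(model) || !inherits(model, "biosort_calibration")) {
    stop("convert_units: a fitted biosort_calibration model is required",
         call. = FALSE)
  }
  summaries$median_length_um <- model$tof_to_um_slope * summaries$median_tof
  summaries$median_width_um <- model$normext_to_um_slope * summaries$median_norm_ext
  summaries
}
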