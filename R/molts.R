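#' Build a per-strain population fluorescence time series
#'
#' Aggregates well summaries into the population median (and SD over wells)
#' of area-normalized red fluorescence at each hour, for one strain.
#'
#' @param summaries a `"well_summary"` data.frame.
#' @param strain strain label to extract.
#' @return a data.frame of class `"fluorescence_series"` with columns `hour`,
#'   `value`, `sd` and a `strain` attribute.
#' @export
fluorescence_series <- function(summaries, strain) {
  d <- summaries[summaries$strain == strain, ]
  .assert(nrow(d) > 0, paste("no summaries for strain", strain))
  hs <- sort(unique(d$hour))
  out <- data.frame(
    hour = hs,
    value = vapply(hs, function(h)
      stats::median(d$median_norm_fluorescence[d$hour == h]), 0),
    sd = vapply(hs, function(h)
      stats::sd(d$median_norm_fluorescence[d$hour == h]), 0)
  )
  attr(out, "strain") <- strain
  class(out) <- c("fluorescence_series", "data.frame")
  out
}

# Topographic prominence of local maxima of z (standard walk-out algorithm):
# for each peak, walk outwards until a higher point or the edge, and take the
# higher of the two interval minima as the peak's base.
.peak_prominences <- function(z) {
  n <- length(z)
  d <- diff(z)
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(peaks) == 0) return(list(peaks = integer(), prominence = numeric()))
  prom <- vapply(peaks, function(i) {
    lo_l <- z[i]
    j <- i - 1L
    while (j >= 1 && z[j] < z[i]) { lo_l <- min(lo_l, z[j]); j <- j - 1L }
    lo_r <- z[i]
    j <- i + 1L
    while (j <= n && z[j] < z[i]) { lo_r <- min(lo_r, z[j]); j <- j + 1L }
    z[i] - max(lo_l, lo_r)
  }, 0)
  list(peaks = peaks, prominence = prom)
}

#' Detect molts as feeding minima in a fluorescence series
#'
#' Smooths the population fluorescence with the same local-linear kernel
#' machinery used for the shape analysis, then reports local minima whose
#' prominence is at least `min_prominence` times the dynamic range of the
#' smoothed series (so detection is invariant to affine rescaling of the
#' fluorescence units), separated by at least `min_separation` hours (the
#' more prominent dip wins). At most `max_molts` minima are reported, and
#' stage windows L1..L4 are tiled between them.
#'
#' @param series a [fluorescence_series()] (or data.frame with `hour`, `value`).
#' @param min_prominence minimum dip prominence as a fraction of the smoothed
#'   series' dynamic range; default 0.15.
#' @param min_separation minimum spacing between reported molts in hours;
#'   default 5 (larval stages are well over 5 h apart).
#' @param h_bw kernel bandwidth in hours.
#' @param grid_step evaluation grid step in hours.
#' @param max_molts maximum number of molts to report (3 within a 1-42 h span).
#' @return an object of class `"molt_annotation"`: list with `strain`,
#'   `molt_times` (increasing hours), `stage_windows` (data.frame
#'   `stage, start, end`), `source = "detected"`.
#' @export
detect_molts <- function(series, min_prominence = 0.15, min_separation = 5,
                         h_bw = 1.5, grid_step = 0.25, max_molts = 3) {
  .assert(all(c("hour", "value") %in% names(series)),
          "series must have hour and value columns")
  .assert(nrow(series) >= 10, "need >= 10 time points")
  strain <- attr(series, "strain") %||% NA_character_
  grid <- seq(min(series$hour), max(series$hour), by = grid_step)
  ks <- kernel_smooth(series$hour, series$value, grid, h_bw = h_bw)
  rng <- diff(range(ks$fit))
  molts <- numeric(0)
  if (rng > 0) {
    z <- max(ks$fit) - ks$fit  # dips become peaks
    pp <- .peak_prominences(z)
    ok <- pp$prominence >= min_prominence * rng
    cand <- pp$peaks[ok]
    prom <- pp$prominence[ok]
    if (length(cand) > 0) {
      ord <- order(prom, decreasing = TRUE)
      chosen <- integer(0)
      for (i in ord) {
        if (all(abs(grid[cand[i]] - grid[chosen]) >= min_separation)) {
          chosen <- c(chosen, cand[i])
        }
      }
      chosen <- chosen[seq_len(min(length(chosen), max_molts))]
      molts <- sort(grid[chosen])
    }
  }
  if (length(molts) == 0) {
    warning("detect_molts: no feeding minima found",
            if (!is.na(strain)) paste0(" for strain ", strain))
  }
  edges <- c(min(series$hour), molts, max(series$hour))
  stage_windows <- data.frame(
    stage = paste0("L", seq_len(length(edges) - 1)),
    start = edges[-length(edges)],
    end = edges[-1]
  )
  structure(list(strain = strain, molt_times = molts,
                 stage_windows = stage_windows, source = "detected"),
            class = "molt_annotation")
}

#' @export
print.molt_annotation <- function(x, ...) {
  cat("<molt_annotation>", x$strain, "(", x$source, ")\n")
  if (length(x$molt_times) == 0) {
    cat("  no molts detected\n")
  } else {
    cat("  molts at:", paste(format(x$molt_times), collapse = ", "), "h\n")
  }
  invisible(x)
}

#' Compare molt timing across strains
#'
#' Tabulates per-stage transition hours for each strain and ranks strains by
#' transition hour at each stage (rank 1 = earliest). Exact ties share the
#' minimum rank and are flagged; display order breaks ties by strain label.
#' Strains without detections are excluded with a message.
#'
#' @param annotations a list of [detect_molts()] annotations.
#' @return data.frame `stage, strain, transition_hour, rank, tied`; `rank` is
#'   `NA` when only one strain is available.
#' @export
compare_molt_timing <- function(annotations) {
  .assert(length(annotations) >= 1, "need at least one annotation")
  ann <- Filter(function(a) length(a$molt_times) > 0, annotations)
  dropped <- setdiff(vapply(annotations, `[[`, "", "strain"),
                     vapply(ann, `[[`, "", "strain"))
  if (length(dropped) > 0) {
    message("compare_molt_timing: excluded strain(s) without detections: ",
            paste(dropped, collapse = ", "))
  }
  .assert(length(ann) >= 1, "no strains with detections")
  rows <- do.call(rbind, lapply(ann, function(a) {
    data.frame(stage = seq_along(a$molt_times), strain = a$strain,
               transition_hour = a$molt_times, stringsAsFactors = FALSE)
  }))
  single <- length(ann) == 1
  out <- do.call(rbind, lapply(split(rows, rows$stage), function(d) {
    d <- d[order(d$transition_hour, d$strain), ]
    d$rank <- if (single) NA_integer_ else rank(d$transition_hour, ties.method = "min")
    d$tied <- duplicated(d$transition_hour) |
      duplicated(d$transition_hour, fromLast = TRUE)
    if (single) d$tied <- FALSE
    d
  }))
  rownames(out) <- NULL
  out
}
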