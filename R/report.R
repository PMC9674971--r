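#' Tukey boxplot statistics
#'
#' The convention used throughout the package's figures: the box spans the
#' 25th to 75th quantiles (linear-interpolation quantiles, R type 7), the
#' whiskers extend to the most extreme observations within 1.5 IQR of the
#' quartiles, and points beyond the whisker fences are outliers.
#'
#' @param values numeric vector, at least one value, no NAs.
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
tukey_box_stats <- function(values) {
  .assert(length(values) >= 1, "tukey_box_stats: need at least one value")
  .assert(!anyNA(values), "tukey_box_stats: NA values not allowed")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Assemble the inputs of a report
#'
#' @param summaries a calibrated `"well_summary"` data.frame.
#' @param fit optional `"stretcher"` fit (required for the slope-ratio and
#'   relaxation outputs).
#' @return an object of class `"report_bundle"`.
#' @export
report_bundle <- function(summaries, fit = NULL) {
  structure(list(summaries = summaries, fit = fit,
                 strains = unique(summaries$strain)),
            class = "report_bundle")
}

.box_stats_table <- function(summaries, column, metric) {
  rows <- lapply(split(summaries, list(summaries$strain, summaries$hour),
                       drop = TRUE), function(d) {
    s <- tukey_box_stats(d[[column]])
    data.frame(strain = d$strain[1], hour = d$hour[1], metric = metric,
               median = s$median, q1 = s$q1, q3 = s$q3,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               n_outliers = length(s$outliers), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$strain, out$hour), ]
}

.open_device <- function(path, device, width = 9, height = 6) {
  switch(device,
         png = grDevices::png(paste0(path, ".png"), width = width * 100,
                              height = height * 100, res = 100),
         svg = grDevices::svg(paste0(path, ".svg"), width = width, height = height),
         pdf = grDevices::pdf(paste0(path, ".pdf"), width = width, height = height))
  paste0(path, ".", device)
}

.boxplot_figure <- function(summaries, column, ylab) {
  strains <- sort(unique(summaries$strain))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(strains)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in strains) {
    d <- summaries[summaries$strain == s, ]
    graphics::boxplot(d[[column]] ~ d$hour, range = 1.5, xlab = "hour",
                      ylab = ylab, main = s, outcex = 0.4, cex.axis = 0.7)
  }
}

#' Render the figure and table outputs of a run
#'
#' Writes, deterministically, per-hour Tukey boxplot figures of normalized
#' fluorescence, length and width, the length-width phase plane, the
#' slope-ratio curves with SD shading, plus `boxstats.csv`,
#' `slope_ratio.csv`, `relaxation.csv` and a provenance `manifest.csv`.
#' Re-running on identical inputs reproduces identical CSVs byte for byte.
#' With no strains in the bundle only the manifest is written.
#'
#' @param bundle a [report_bundle()].
#' @param out_dir output directory (created if needed).
#' @param device figure device: `"png"`, `"svg"` or `"pdf"`; devices not
#'   supported by the R build fall back to `"pdf"`.
#' @return invisibly, the manifest data.frame.
#' @export
render_report <- function(bundle, out_dir, device = c("png", "svg", "pdf")) {
  .assert(inherits(bundle, "report_bundle"), "bundle must be a report_bundle")
  device <- match.arg(device)
  if (device == "png" && !capabilities("png")) device <- "pdf"
  if (device == "svg" && !capabilities("cairo")) device <- "pdf"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("render_report: cannot create output directory ", out_dir, call. = FALSE)
  }
  manifest <- list()
  note <- function(file, kind, n_rows, source) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(file), kind = kind, n_rows = n_rows, source = source,
      stringsAsFactors = FALSE)
  }
  if (length(bundle$strains) > 0) {
    .assert(!is.null(bundle$fit), "render_report: bundle incomplete (no fit)")
    sums <- bundle$summaries
    # tables
    box <- rbind(
      .box_stats_table(sums, "median_norm_fluorescence", "norm_fluorescence"),
      .box_stats_table(sums, "median_length_um", "length_um"),
      .box_stats_table(sums, "median_width_um", "width_um")
    )
    f <- file.path(out_dir, "boxstats.csv")
    utils::write.csv(box, f, row.names = FALSE)
    note(f, "table", nrow(box), "well summaries")
    sr <- do.call(rbind, lapply(bundle$fit$results, function(res) {
      data.frame(strain = res$strain, stage = res$stage, t = res$ratio$t,
                 r = res$ratio$r, sd = res$ratio$sd,
                 label = res$segmentation$labels$label,
                 masked = res$ratio$masked, stringsAsFactors = FALSE)
    }))
    rownames(sr) <- NULL
    f <- file.path(out_dir, "slope_ratio.csv")
    utils::write.csv(sr, f, row.names = FALSE)
    note(f, "table", nrow(sr), "stretcher fit")
    relax <- bundle$fit$relaxation
    if (is.null(relax)) relax <- characterize_relaxation(sums, list())
    f <- file.path(out_dir, "relaxation.csv")
    utils::write.csv(relax, f, row.names = FALSE)
    note(f, "table", nrow(relax), "stretcher fit")
    # figures (panels B-F analogues)
    fig <- function(name, draw) {
      path <- .open_device(file.path(out_dir, name), device)
      on.exit(grDevices::dev.off())
      draw()
      note(path, "figure", NA_integer_, "well summaries / stretcher fit")
    }
    fig("fig_fluorescence_boxplot",
        function() .boxplot_figure(sums, "median_norm_fluorescence",
                                   "norm. fluorescence"))
    fig("fig_length_boxplot",
        function() .boxplot_figure(sums, "median_length_um", "length (um)"))
    fig("fig_width_boxplot",
        function() .boxplot_figure(sums, "median_width_um", "width (um)"))
    fig("fig_phase_plane", function() plot(bundle$fit, type = "phase"))
    fig("fig_slope_ratio", function() plot(bundle$fit, type = "ratio"))
  }
  man <- if (length(manifest) > 0) {
    do.call(rbind, manifest)
  } else {
    data.frame(file = character(), kind = character(), n_rows = integer(),
               source = character())
  }
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
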