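#' Read and write growth-window tables as YAML
#'
#' The YAML layout is a mapping strain -> stage -> `[start, end]`:
#' ```yaml
#' N2:
#'   L1: [1, 10]
#'   L2: [16, 22]
#' ```
#'
#' @param path file path.
#' @return for the reader, a window data.frame as from [stage_windows()].
#' @export
read_stage_windows <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- list()
  for (s in names(y)) {
    for (st in names(y[[s]])) {
      v <- as.numeric(y[[s]][[st]])
      .assert(length(v) == 2 && v[1] < v[2],
              paste("bad window for", s, st))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, stage = st, start = v[1], end = v[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname read_stage_windows
#' @param windows a window data.frame (`strain, stage, start, end`).
#' @export
write_stage_windows <- function(windows, path) {
  y <- lapply(split(windows, windows$strain), function(d) {
    stats::setNames(lapply(seq_len(nrow(d)),
                           function(i) c(d$start[i], d$end[i])), d$stage)
  })
  yaml::write_yaml(y, path)
  invisible(path)
}
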