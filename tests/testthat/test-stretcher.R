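test_that("window selection honours the configured growth windows", {
  sums <- data.frame(
    strain = rep("dpy-1", 42), well = paste0("w", 1:42), hour = 1:42,
    median_length_um = 300, median_width_um = 20
  )
  obs <- select_window(sums, stage_windows(), "dpy-1", "L2")
  expect_equal(sort(obs$hour), 19:26)
  # a window covering everything returns the input rows
  wide <- data.frame(strain = "dpy-1", stage = "all", start = 1, end = 42)
  expect_equal(nrow(select_window(sums, wide, "dpy-1", "all")), 42)
  # L4 is excluded by default
  expect_error(select_window(sums, stage_windows(), "N2", "L4"),
               "no growth window")
  expect_error(select_window(sums[0, ], stage_windows(), "dpy-1", "L2"),
               "no observations")
})

test_that("bootstrap bands vanish for identical wells and obey the seed", {
  obs <- ramp_wells(n_wells = 6)  # noiseless: all wells identical
  b1 <- bootstrap_bands(obs, n_boot = 120, seed = 5)
  expect_lt(max(b1$length$sd), 1e-9)
  expect_lt(max(b1$width$sd), 1e-9)
  b2 <- bootstrap_bands(obs, n_boot = 120, seed = 5)
  expect_identical(b1$length$boot_fit, b2$length$boot_fit)
  b3 <- bootstrap_bands(obs, n_boot = 120, seed = 6)
  expect_false(identical(b1$length$boot_fit, b3$length$boot_fit))
  expect_error(bootstrap_bands(ramp_wells(n_wells = 3), n_boot = 120), "wells")
  expect_error(bootstrap_bands(obs, n_boot = 50), "n_boot")
})

test_that("slope ratio is exact for linear and closed-form cases", {
  # W = 0.2 L (+ intercept): ratio identically 0.2
  obs <- ramp_wells(n_wells = 6, c0 = 0.2, intercept = 5)
  sr <- slope_ratio(bootstrap_bands(obs, n_boot = 100, seed = 1))
  expect_equal(sr$r[!sr$masked], rep(0.2, sum(!sr$masked)), tolerance = 1e-9)
  # L = t, W = t^2 on [1, 2]: r(1.5) = 2 t = 3 exactly
  tt <- seq(1, 2, by = 0.05)
  obs2 <- do.call(rbind, lapply(1:6, function(w)
    data.frame(well = paste0("w", w), hour = tt, length_um = tt,
               width_um = tt^2)))
  sr2 <- slope_ratio(bootstrap_bands(obs2, n_boot = 100, h_bw = 0.3, seed = 1))
  expect_equal(sr2$r[sr2$t == 1.5], 3, tolerance = 1e-6)
})

test_that("slope ratio masks flat-growth regions and errors when all flat", {
  obs <- ramp_wells(n_wells = 6)
  obs$length_um <- 500  # no length growth anywhere
  bb <- bootstrap_bands(obs, n_boot = 100, seed = 1)
  expect_error(slope_ratio(bb), "masked")
})

test_that("regime classification finds planted onsets and degenerate cases", {
  # constant ratio with noise: all linear, no onset
  obs <- ramp_wells(n_wells = 12, sd_l = 1, sd_w = 0.2, seed = 3)
  sr <- slope_ratio(bootstrap_bands(obs, n_boot = 150, seed = 3))
  seg <- classify_regimes(sr)
  expect_true(is.na(seg$onset))
  expect_true(all(seg$labels$label == "linear"))
  # planted kink at 70% of the window
  obs2 <- ramp_wells(n_wells = 20, onset = 20.2, sd_l = 0.5, sd_w = 0.1,
                     seed = 4)
  sr2 <- slope_ratio(bootstrap_bands(obs2, n_boot = 150, seed = 4))
  seg2 <- classify_regimes(sr2)
  expect_false(is.na(seg2$onset))
  expect_lte(abs(seg2$onset - 20.2), 1)
  # nonlinear labels form a suffix
  labs <- seg2$labels$label
  expect_true(all(labs[seg2$labels$t >= seg2$onset] == "nonlinear"))
  expect_true(all(labs[seg2$labels$t < seg2$onset] == "linear"))
  # strictly increasing ratio with tiny SD: onset at the first admissible point
  obs3 <- ramp_wells(n_wells = 6, onset = 16, gain = 3)
  sr3 <- slope_ratio(bootstrap_bands(obs3, n_boot = 100, seed = 5))
  seg3 <- classify_regimes(sr3)
  expect_false(is.na(seg3$onset))
  expect_lte(seg3$onset, min(sr3$t) + diff(range(sr3$t)) / 3 + 0.5)
})

test_that("short windows are flagged unclassified", {
  obs <- ramp_wells(n_wells = 6, hours = 16:18)
  sr <- slope_ratio(bootstrap_bands(obs, n_boot = 100, seed = 1))
  seg <- classify_regimes(sr)
  expect_true(seg$flagged)
  expect_true(is.na(seg$onset))
})

test_that("raising z never moves the detected onset earlier", {
  obs <- ramp_wells(n_wells = 15, onset = 20.2, sd_l = 0.5, sd_w = 0.1,
                    seed = 8)
  sr <- slope_ratio(bootstrap_bands(obs, n_boot = 150, seed = 8))
  onsets <- sapply(c(1, 2, 3, 4), function(z) {
    o <- classify_regimes(sr, z = z)$onset
    if (is.na(o)) Inf else o
  })
  expect_true(all(diff(onsets) >= 0))
})

test_that("relaxation bookkeeping follows the sign rules", {
  sums <- data.frame(
    strain = "N2",
    well = paste0("w", 1:8), hour = c(12, 13, 15, 16, 12, 13, 15, 16),
    median_length_um = c(400, 400, 410, 410, 400, 400, 410, 410),
    median_width_um = c(40, 40, 38, 38, 40, 40, 38, 38)
  )
  ann <- structure(list(strain = "N2", molt_times = 14, stage_windows = NULL,
                        source = "configured"), class = "molt_annotation")
  rel <- characterize_relaxation(sums, ann)
  expect_equal(rel$direction, "length-relax")
  expect_equal(rel$delta_length_um, 10)
  expect_equal(rel$delta_width_um, -2)
  expect_equal(rel$magnitude_um, 2)
  expect_false(rel$flagged)
  # pre == post exactly: ambiguous with zero magnitude
  sums2 <- sums
  sums2$median_length_um <- 400
  sums2$median_width_um <- 40
  rel2 <- characterize_relaxation(sums2, ann)
  expect_equal(rel2$direction, "ambiguous")
  expect_true(rel2$flagged)
  expect_equal(rel2$magnitude_um, 0)
  # molt too close to the span edge is skipped
  ann_edge <- structure(list(strain = "N2", molt_times = 12.5,
                             stage_windows = NULL, source = "configured"),
                        class = "molt_annotation")
  expect_message(rel3 <- characterize_relaxation(sums, ann_edge), "skipped")
  expect_equal(nrow(rel3), 0)
})

test_that("planted relaxation directions survive the full pipeline", {
  profs <- default_strain_profiles()
  for (seed in c(1, 2)) {
    cfg <- simulation_config(n_wells_per_hour = 8, n_animals_per_well = 20,
                             contaminant_rate = 0, seed = seed)
    sums <- convert_units(summarize_wells(simulate_dataset(cfg)$records),
                          identity_calibration())
    for (s in c("N2", "dpy-5")) {
      ann <- detect_molts(fluorescence_series(sums, s))
      rel <- characterize_relaxation(sums, ann)
      expect_equal(nrow(rel), 3)
      expect_true(all(rel$direction == profs[[s]]$relaxation_direction))
    }
  }
})

test_that("the analysis is invariant to a common rescaling of all sizes", {
  obs <- ramp_wells(n_wells = 10, onset = 20.2, sd_l = 0.5, sd_w = 0.1,
                    seed = 12)
  obs2 <- obs
  obs2$length_um <- obs$length_um * 7
  obs2$width_um <- obs$width_um * 7
  sr1 <- slope_ratio(bootstrap_bands(obs, n_boot = 150, seed = 2))
  sr2 <- slope_ratio(bootstrap_bands(obs2, n_boot = 150, seed = 2))
  expect_equal(sr1$r, sr2$r, tolerance = 1e-9)
  expect_equal(sr1$masked, sr2$masked)
  s1 <- classify_regimes(sr1); s2 <- classify_regimes(sr2)
  expect_equal(s1$onset, s2$onset)
  expect_equal(s1$labels$label, s2$labels$label)
})

test_that("the stretcher fit exposes coef, summary, print and plot methods", {
  cfg <- simulation_config(
    strain_profiles = default_strain_profiles()["N2"],
    n_wells_per_hour = 10, n_animals_per_well = 25, contaminant_rate = 0,
    seed = 17)
  sums <- convert_units(summarize_wells(simulate_dataset(cfg)$records),
                        identity_calibration())
  fit <- stretcher(sums, n_boot = 120, seed = 17)
  cf <- coef(fit)
  expect_equal(nrow(cf), 3)  # L1-L3 windows for N2
  ck <- default_strain_profiles()[["N2"]]$aspect_slope[1:3]
  expect_lt(max(abs(cf$slope_ratio - ck) / ck), 0.10)
  expect_s3_class(summary(fit), "summary.stretcher")
  expect_output(print(fit), "linear-regime dW/dL")
  expect_equal(nrow(fit$relaxation), 3)
  tmp <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(tmp)
  expect_invisible(plot(fit, type = "ratio"))
  expect_invisible(plot(fit, type = "phase"))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})

test_that("stage window YAML round-trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "w.yaml")
  write_stage_windows(stage_windows(), p)
  back <- read_stage_windows(p)
  w0 <- stage_windows()[order(stage_windows()$strain, stage_windows()$stage), ]
  bk <- back[order(back$strain, back$stage), ]
  rownames(w0) <- rownames(bk) <- NULL
  expect_equal(bk, w0)
})

test_that("windows derived from molts trim the relaxation margins", {
  ann <- structure(list(strain = "N2", molt_times = c(14, 25, 33.5),
                        stage_windows = NULL, source = "detected"),
                   class = "molt_annotation")
  w <- windows_from_molts(list(ann), relax_margin = 2)
  expect_equal(w$start, c(1, 16, 27))
  expect_equal(w$end, c(12, 23, 31.5))
})
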