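test_that("profile validation rejects malformed inputs", {
  expect_error(strain_profile("x", c(10, 9, 20), 10, 0.05),
               "strictly increasing")
  expect_error(strain_profile("x", c(10, 20, 45), 10, 0.05), "inside")
  expect_error(strain_profile("x", c(10, 20, 30), 10, -0.05), "c_k")
  expect_error(strain_profile("x", c(10, 20, 30), 10, 0.05,
                              nonlinear_slope_gain = 0.5), "gain")
  expect_error(strain_profile("x", c(10, 20, 30), 10, 0.05,
                              feeding_dip_depth = 0), "feeding_dip_depth")
})

test_that("trajectory feeding minima sit exactly on the planted molts", {
  p <- strain_profile("x", c(14, 25, 34), growth_rate = 20,
                      aspect_slope = 0.05)
  tt <- seq(1, 42, by = 0.05)
  tr <- simulate_trajectory(p, tt)
  for (m in c(14, 25, 34)) {
    near <- abs(tr$hour - m) <= 3
    expect_equal(tr$hour[near][which.min(tr$feeding[near])], m)
  }
  expect_error(simulate_trajectory(p, 43), "span")
  expect_error(simulate_trajectory(p, 0.5), "span")
})

test_that("gain 1 gives a constant finite-difference dW/dL of c_k per stage", {
  p <- strain_profile("x", c(14, 25, 34), growth_rate = c(12, 20, 30, 35),
                      aspect_slope = c(0.2, 0.1, 0.05, 0.08),
                      nonlinear_slope_gain = 1)
  tt <- seq(1, 42, by = 0.001)
  tr <- simulate_trajectory(p, tt)
  dL <- diff(tr$length_um); dW <- diff(tr$width_um)
  stage_mid <- tr$stage[-1]
  same_stage <- tr$stage[-1] == tr$stage[-nrow(tr)]
  for (k in 1:4) {
    sel <- same_stage & stage_mid == k & dL > 1e-9
    expect_true(any(sel))
    expect_equal(dW[sel] / dL[sel], rep(p$aspect_slope[k], sum(sel)),
                 tolerance = 1e-6)
  }
})

test_that("nonlinear ramp matches the closed-form slope-ratio at midpoints", {
  p <- strain_profile("x", c(14, 25, 34), growth_rate = 20,
                      aspect_slope = c(0.2, 0.2, 0.2, 0.2),
                      nonlinear_onset_fraction = 0.5,
                      nonlinear_slope_gain = 1.5)
  tt <- seq(1, 42, by = 0.001)
  tr <- simulate_trajectory(p, tt)
  dL <- diff(tr$length_um); dW <- diff(tr$width_um)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  # analytic ratio inside stage 1 (spans 1..14, onset at 7.5)
  onset <- 1 + 0.5 * 13
  sel <- mid > 2 & mid < 11.5 & dL > 1e-9
  want <- ifelse(mid[sel] <= onset, 0.2,
                 0.2 * (1 + 0.5 * (mid[sel] - onset) / (14 - onset)))
  expect_equal(dW[sel] / dL[sel], want, tolerance = 1e-6)
})

test_that("length is monotone non-decreasing within a stage", {
  for (p in default_strain_profiles()) {
    tr <- simulate_trajectory(p, seq(1, 42, by = 0.1))
    same <- diff(tr$stage) == 0
    expect_true(all(diff(tr$length_um)[same] >= -1e-12))
  }
})

test_that("simulated datasets are deterministic and well-bookkept", {
  cfg <- small_config(3, n_wells = 3, n_animals = 8, contaminant_rate = 0.2)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  # invariants on the records
  expect_true(all(s1$records$tof > 0))
  expect_true(all(s1$records$ext > 0))
  expect_true(all(s1$records$norm_ext > 0))
  expect_true(all(s1$records$red >= 0))
  expect_equal(s1$records$ext, s1$records$tof * s1$records$norm_ext)
  # contaminant-free config labels everything animal
  s0 <- simulate_dataset(small_config(3, n_wells = 3, n_animals = 8))
  expect_true(all(s0$truth$truth_class == "animal"))
})

test_that("changing the well count does not reshuffle other wells", {
  cfg4 <- small_config(9, strains = "N2", n_wells = 4, n_animals = 6)
  cfg2 <- small_config(9, strains = "N2", n_wells = 2, n_animals = 6)
  s4 <- simulate_dataset(cfg4)
  s2 <- simulate_dataset(cfg2)
  w12 <- s4$records$well %in% unique(s2$records$well)
  shared <- s4$records[w12, ]
  rownames(shared) <- NULL
  expect_identical(shared, s2$records)
})

test_that("total record count matches the contamination bookkeeping", {
  cfg <- small_config(5, strains = "N2", n_wells = 10, n_animals = 40,
                      contaminant_rate = 0.2, hours = 1:20)
  sim <- simulate_dataset(cfg)
  n_anim <- 10 * 40 * 20
  lambda_total <- n_anim * 0.2 / (1 - 0.2)  # Poisson contaminant mean
  n_contam <- sum(sim$truth$truth_class == "contaminant")
  expect_equal(nrow(sim$records), n_anim + n_contam)
  expect_lt(abs(n_contam - lambda_total), 4 * sqrt(lambda_total))
})

test_that("well medians of planted truth converge to the trajectory", {
  p <- default_strain_profiles()[["N2"]]
  cfg <- simulation_config(strain_profiles = list("N2" = p),
                           n_wells_per_hour = 2, n_animals_per_well = 400,
                           hours = c(5, 20, 30), contaminant_rate = 0,
                           molt_jitter_sd = c(0, 0, 0), seed = 21)
  sim <- simulate_dataset(cfg)
  tr <- simulate_trajectory(p, c(5, 20, 30))
  for (h in c(5, 20, 30)) {
    med <- median(sim$truth$truth_length_um[sim$truth$hour == h])
    want <- tr$length_um[tr$hour == h]
    # median of n=400 draws with sd 10: SE ~ 10*1.25/20 ~ 0.63
    expect_lt(abs(med - want), 3)
  }
})

test_that("per-strain molt order in the truth matches the profiles", {
  profs <- default_strain_profiles()
  m <- sapply(profs, function(p) p$stage_boundaries)
  # dpy-1 is latest at every molt; both dpy strains are later than N2
  expect_true(all(m[, "dpy-1"] > m[, c("N2", "dpy-5", "lon-3")]))
  expect_true(all(m[, "dpy-5"] > m[, "N2"]))
})

test_that("CSV round trip preserves the record schema", {
  sim <- simulate_dataset(small_config(7, strains = "N2", n_wells = 2,
                                       n_animals = 5, hours = 1:10))
  dir <- withr::local_tempdir()
  paths <- write_simulated_csv(sim, dir)
  back <- read_biosort_csv(paths["raw"])
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$tof, sim$records$tof)
  truth <- utils::read.csv(paths["truth"])
  expect_equal(truth$truth_class, sim$truth$truth_class)
})
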