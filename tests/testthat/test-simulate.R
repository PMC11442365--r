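test_that("uncoupled dyads have no coupled epochs and seeded runs reproduce exactly", {
  sim <- simulate_dyad(sim_config(duration_s = 300, coupling = 0, seed = 501))
  expect_equal(sum(sim$truth$coupled), 0)
  expect_true(all(is.na(sim$truth$lag_s)))

  sim2 <- simulate_dyad(sim_config(duration_s = 300, coupling = 0,
                                   seed = 501))
  expect_identical(as.numeric(sim$patient), as.numeric(sim2$patient))
  expect_identical(as.numeric(sim$clinician), as.numeric(sim2$clinician))
  expect_identical(sim$truth, sim2$truth)
})

test_that("fully coupled patient-led dyads echo every bout at exactly the planted lag", {
  cfg <- sim_config(duration_s = 300, coupling = 1, leader_share = 1,
                    lag_range_s = c(1.2, 1.2), noise_level = 0, seed = 502)
  sim <- simulate_dyad(cfg)
  expect_gt(nrow(sim$truth), 3)
  expect_true(all(sim$truth$coupled))
  expect_true(all(sim$truth$leader == "patient"))
  expect_true(all(sim$truth$lag_s == 1.2))
  fr <- 25
  for (i in seq_len(nrow(sim$truth))) {
    i0 <- round(sim$truth$start_s[i] * fr)
    j0 <- i0 + round(1.2 * fr)
    expect_gt(as.numeric(sim$patient)[i0 + 1], 0)   # leader onset
    expect_gt(as.numeric(sim$clinician)[j0 + 1], 0) # echo exactly 1.2 s later
    expect_equal(as.numeric(sim$clinician)[j0], 0)  # silent one frame before
  }
})

test_that("ground-truth epochs never overlap and lags respect the bounds", {
  sim <- simulate_dyad(sim_config(duration_s = 600, coupling = .8,
                                  seed = 503))
  tr <- sim$truth
  expect_true(all(diff(tr$start_s) > 0))
  expect_true(all(tr$end_s[-nrow(tr)] <= tr$start_s[-1]))
  expect_true(all(tr$lag_s[tr$coupled] >= 0.5 & tr$lag_s[tr$coupled] <= 2.5))
})

test_that("rendered videos reproduce the generating series through MEA", {
  sim <- simulate_dyad(sim_config(duration_s = 60, coupling = 1,
                                  leader_share = 1, seed = 504))
  set.seed(504)
  fs <- render_video(sim$patient, sim$clinician)
  mp <- motion_energy(fs, roi("patient", 10, 10, 50, 70), 3)
  mc <- motion_energy(fs, roi("clinician", 70, 10, 110, 70), 3)
  expect_gt(cor(as.numeric(mp), as.numeric(sim$patient)), 0.95)
  expect_gt(cor(as.numeric(mc), as.numeric(sim$clinician)), 0.95)
})

test_that("a motionless person renders as a static ROI and movement does not leak across ROIs", {
  fr <- 25
  moving <- motion_energy_series(c(rep(0, 50), rep(60, 100), rep(0, 100)),
                                 fr, "patient")
  still <- motion_energy_series(rep(0, 250), fr, "clinician")
  set.seed(505)
  fs <- render_video(moving, still)
  mc <- motion_energy(fs, roi("clinician", 70, 10, 110, 70), 3)
  expect_equal(as.numeric(mc), rep(0, 250))      # locality: no leakage
  mp <- motion_energy(fs, roi("patient", 10, 10, 50, 70), 3)
  expect_gt(cor(as.numeric(mp), as.numeric(moving)), 0.95)

  lay <- list(width = 120L, height = 80L,
              patient = roi("patient", 10, 10, 60, 70),
              clinician = roi("clinician", 50, 10, 110, 70))
  expect_error(render_video(moving, still, lay), "overlap")
})

test_that("circular-shift surrogates keep marginals, move by at least twice the max lag", {
  sim <- simulate_dyad(sim_config(duration_s = 300, coupling = 1,
                                  seed = 506))
  for (s in 1:10) {
    sur <- shuffle_surrogate(sim$patient, sim$clinician, seed = s)
    expect_gte(sur$offset, 2 * 125)
    expect_lte(sur$offset, length(sim$clinician) - 2 * 125)
    expect_equal(gross_body_movement(sur$clinician),
                 gross_body_movement(sim$clinician))
    expect_equal(sort(as.numeric(sur$clinician)),
                 sort(as.numeric(sim$clinician)))
  }
  short <- motion_energy_series(rep(1, 400), 25)
  expect_error(shuffle_surrogate(short, short), "shorter")
})

test_that("simulated cohorts have the requested size, link and reproducibility", {
  sim <- simulate_cohort(n_dyads = 12, effect_size = -0.8, seed = 507,
                         segment_s = 60)
  expect_equal(nrow(sim$cohort), 12)
  expect_length(sim$dyads, 12)
  co <- sim$cohort
  # logistic link: patient-led epoch probability decreases with severity
  expect_true(all(co$p_patient_led[order(co$severity)] ==
                    sort(co$p_patient_led, decreasing = TRUE)))
  expect_true(all(co$p_clinician_led == co$p_clinician_led[1]))
  expect_true(all(co$hamd >= 0 & co$hamd <= 52))
  expect_true(all(co$bdi >= 0 & co$bdi <= 63))
  expect_true(all(co$tdeq_dep >= 1 & co$tdeq_dep <= 7))

  sim2 <- simulate_cohort(n_dyads = 12, effect_size = -0.8, seed = 507,
                          segment_s = 60)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(as.numeric(sim$dyads[[5]]$patient),
                   as.numeric(sim2$dyads[[5]]$patient))

  expect_error(simulate_cohort(n_dyads = 5), "at least 10")
  expect_warning(
    simulate_cohort(n_dyads = 10, effect_size = -3, seed = 1,
                    segment_s = 60,
                    base_config = sim_config(coupling = 0.9,
                                             leader_share = 0.6)),
    "clipped")
})
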