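test_that("infusion rate is zero-order and conserves the dose", {
  dose <- hb_grams_to_umol_heme(4)
  expect_equal(infusion_rate(0.1, dose, 0, 1 / 6), dose / (1 / 6))
  expect_equal(infusion_rate(0.2, dose, 0, 1 / 6), 0)
  expect_equal(infusion_rate(-0.01, dose, 0, 1 / 6), 0)
  int <- stats::integrate(infusion_rate, 0, 1 / 6, dose_umol_heme = dose,
                          start_h = 0, duration_h = 1 / 6)$value +
    stats::integrate(infusion_rate, 1 / 6, 60, dose_umol_heme = dose,
                     start_h = 0, duration_h = 1 / 6)$value
  expect_equal(int, dose, tolerance = 1e-9)
  expect_error(infusion_rate(0.1, -5), "non-negative")
  expect_error(infusion_rate(0.1, 5, duration_h = 0), "positive")
})

test_that("without Hp the free-Hb profile is the closed-form one-compartment solution", {
  k <- 0.2
  cfg <- study_config(hp_dose_g = 0, basal_hp_uM = 0, k_el_free = k,
                      noise_cv = 0, n_subjects = 1, loq_uM = 0)
  sub <- simulate_subject(cfg, 1)
  t <- cfg$schedule_h
  expected <- one_compartment_profile(t, cfg$hb_dose_umol,
                                      cfg$plasma_volume_L, k)
  expect_equal(sub$free$conc_uM, expected, tolerance = 1e-6)
  post <- t >= 0.25
  fit <- stats::lm(log(sub$free$conc_uM[post]) ~ t[post])
  expect_equal(unname(stats::coef(fit)[2]), -k, tolerance = 1e-6)
})

test_that("heme mass balance holds along the whole trajectory", {
  for (cfg in list(
    study_config(noise_cv = 0, n_subjects = 1),
    study_config(hp_dose_g = 4, basal_hp_uM = 90,
                 complex_clearance_mode = "michaelis_menten",
                 noise_cv = 0, n_subjects = 1),
    study_config(hp_dose_g = 0, basal_hp_uM = 280, noise_cv = 0,
                 n_subjects = 1))) {
    traj <- simulate_subject(cfg, 1)$truth$trajectory
    infused <- hemopk:::cumulative_infused(traj$time, cfg$hb_dose_umol,
                                           0, cfg$hb_infusion_min / 60)
    total <- cfg$plasma_volume_L * (traj$hb + traj$complex + traj$elim) +
      (cfg$hb_dose_umol - infused)
    expect_lt(max(abs(total - cfg$hb_dose_umol)) / cfg$hb_dose_umol, 1e-8)
    # sampled free + bound never exceeds dose/V (noise-free)
    expect_true(all(traj$hb + traj$complex <=
                      cfg$hb_dose_umol / cfg$plasma_volume_L * (1 + 1e-10)))
  }
})

test_that("excess Hp drives bound Cmax to the stoichiometric limit", {
  cfg <- study_config(basal_hp_uM = 5000, k_on = 50, noise_cv = 0,
                      n_subjects = 1, loq_uM = 0)
  sub <- simulate_subject(cfg, 1)
  dv <- cfg$hb_dose_umol / cfg$plasma_volume_L
  expect_lt(abs(max(sub$bound$conc_uM) - dv) / dv, 0.10)
  expect_lt(max(sub$free$conc_uM), 0.05 * dv)
})

test_that("bound terminal slope matches the first-order clearance rate", {
  cfg <- study_config(basal_hp_uM = 5000, k_on = 50, noise_cv = 0,
                      n_subjects = 1)
  sub <- simulate_subject(cfg, 1)
  late <- sub$bound$time_h >= 24
  fit <- stats::lm(log(sub$bound$conc_uM[late]) ~ sub$bound$time_h[late])
  expect_equal(unname(-stats::coef(fit)[2]), cfg$k_el_complex,
               tolerance = 0.01)
})

test_that("saturable clearance produces an accelerating log-decline (two phases)", {
  cfg <- study_config(hp_dose_g = 4, basal_hp_uM = 280,
                      complex_clearance_mode = "michaelis_menten",
                      vmax = 13, km = 150, noise_cv = 0, n_subjects = 1)
  sub <- simulate_subject(cfg, 1)
  t <- sub$bound$time_h
  b <- sub$bound$conc_uM
  post <- which(t >= 1 & b > 0)
  slopes <- -diff(log(b[post])) / diff(t[post])
  expect_gt(slopes[length(slopes)], 2 * slopes[1])
  expect_true(all(diff(slopes) > -1e-6))
})

test_that("study simulation is deterministic and noise behaves as configured", {
  cfg <- study_config(n_subjects = 3, noise_cv = 0.1, seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  b1 <- s1$S1$bound$conc_uM
  b2 <- s1$S2$bound$conc_uM
  expect_false(isTRUE(all.equal(b1, b2)))
  cfg0 <- study_config(n_subjects = 3, noise_cv = 0, seed = 42)
  s0 <- simulate_study(cfg0)
  expect_equal(s0$S1$bound$conc_uM, s0$S3$bound$conc_uM)
})

test_that("sub-LOQ samples are censored to missing, baseline zero retained", {
  cfg <- study_config(hp_dose_g = 0, basal_hp_uM = 0, k_el_free = 0.8,
                      noise_cv = 0, n_subjects = 1, loq_uM = 1)
  sub <- simulate_subject(cfg, 1)
  expect_identical(sub$free$conc_uM[1], 0)
  truth <- sub$truth$schedule_free_uM
  expect_true(all(is.na(sub$free$conc_uM[truth > 0 & truth < 1])))
})

test_that("invalid configurations are rejected", {
  expect_error(study_config(hb_dose_g = -1), "negative")
  expect_error(study_config(schedule_h = c(0, 2, 1)), "increasing")
  expect_error(study_config(schedule_h = c(1, 2)), "baseline")
  expect_error(study_config(n_subjects = 0))
  expect_error(study_config(plasma_volume_L = 0), "positive")
})
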