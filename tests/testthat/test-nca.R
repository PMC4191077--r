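prof <- function(t, c) data.frame(time_h = t, conc_uM = c)

test_that("cmax reports the maximum and breaks ties toward the earlier time", {
  expect_equal(cmax(prof(c(0, 0.25, 1), c(0, 300, 200))),
               list(cmax_uM = 300, tmax_h = 0.25))
  expect_equal(cmax(prof(1:4, c(9, 7, 5, 3)))$tmax_h, 1)
  expect_equal(cmax(prof(1:4, c(5, 9, 9, 3)))$tmax_h, 2)
  expect_equal(cmax(prof(1:3, c(NA, 4, 2)))$cmax_uM, 4)
  expect_error(cmax(prof(1:3, c(NA, NA, NA))), "no observations")
})

test_that("trapezoidal AUC matches analytic areas", {
  expect_equal(auc_linear_trapezoid(c(0, 1, 2), c(0, 10, 0)), 10)
  expect_equal(auc_linear_trapezoid(c(0, 4), c(5, 5)), 20)
  t <- seq(0, 20, by = 0.001)
  expect_equal(auc_linear_trapezoid(t, 100 * exp(-0.5 * t)), 100 / 0.5,
               tolerance = 1e-4)
  expect_error(auc_linear_trapezoid(c(0, 1), c(5, NA)), "2 non-missing")
  expect_error(auc_linear_trapezoid(c(1, 1), c(2, 2)), "increasing")
})

test_that("AUC integrates recorded zeros but skips missing samples", {
  expect_equal(auc_linear_trapezoid(c(0, 1, 2, 3), c(0, 10, 0, 0)), 10)
  # a missing (below-LOQ) middle sample is bridged by one trapezoid
  expect_equal(auc_linear_trapezoid(c(0, 1, 2), c(10, NA, 10)), 20)
  # a trailing missing sample does not extend the observed area
  expect_equal(auc_linear_trapezoid(c(0, 1, 2), c(0, 10, NA)), 5)
})

test_that("trapezoidal AUC equals an independent oracle on random profiles", {
  set.seed(21)
  for (i in 1:1000) {
    p <- random_profile(sample(5:20, 1))
    expect_equal(auc_linear_trapezoid(p$t, p$conc),
                 trapz_oracle(p$t, p$conc), tolerance = 1e-12)
  }
})

test_that("terminal slope recovers exact exponentials", {
  t <- c(24, 32, 36, 48, 60)
  ts <- terminal_slope(t, 50 * exp(-0.1 * t))
  expect_equal(ts$k, 0.1, tolerance = 1e-12)
  expect_equal(ts$r_squared, 1, tolerance = 1e-12)

  halving <- terminal_slope(c(24, 36, 48), c(10, 10 * 2^(-0.5), 5),
                            selection = list(n_fixed = 3))
  expect_equal(halving$k, log(2) / 24, tolerance = 1e-12)
})

test_that("terminal slope equals a brute-force log-linear regression", {
  set.seed(22)
  for (i in 1:50) {
    t <- sort(stats::runif(8, 4, 60))
    c <- 100 * exp(-0.15 * t) * exp(stats::rnorm(8, 0, 0.1))
    ts <- terminal_slope(t, c, selection = list(n_fixed = 8))
    oracle <- stats::lm(log(c) ~ t)
    expect_equal(ts$k, -unname(stats::coef(oracle)[2]), tolerance = 1e-12)
    expect_equal(ts$r_squared, summary(oracle)$r.squared, tolerance = 1e-12)
  }
})

test_that("rising terminal data are flagged, not fit", {
  ts <- terminal_slope(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(is.na(ts$k))
  expect_equal(ts$flag, "nonpositive_terminal_slope")
  expect_error(terminal_slope(c(1, 2), c(3, 2)), "3 positive")
})

test_that("extrapolated AUC is C_last over k", {
  expect_equal(auc_extrapolate(10, 0.1), 100)
  expect_equal(auc_extrapolate(0, 0.5), 0)
  expect_equal(100 / (900 + 100) * 100, 10) # extrapolated fraction example
  expect_error(auc_extrapolate(10, 0), "positive")
  expect_error(auc_extrapolate(10, -0.1), "positive")
})

test_that("NCA recovers closed-form one-compartment parameters", {
  t <- seq(0, 40, by = 0.01)[-1]
  profile <- prof(t, 50 * exp(-0.2 * t))
  res <- nca_subject(profile, 100)
  expect_s3_class(res, "hemopk_pk")
  expect_equal(res$cl_L_per_h, 0.2 * 2, tolerance = 0.005)
  expect_equal(res$vc_L, 2, tolerance = 0.005)
  expect_equal(res$t_half_h, log(2) / 0.2, tolerance = 0.005)
  expect_equal(res$k_terminal, 0.2, tolerance = 1e-6)
})

test_that("the four reporting identities hold exactly for analyzed subjects", {
  cfg <- study_config(hp_dose_g = 0, basal_hp_uM = 280, noise_cv = 0.1,
                      n_subjects = 6, seed = 99)
  study <- simulate_study(cfg)
  for (s in study) {
    for (an in c("free", "bound")) {
      p <- nca_subject(s[[an]], cfg$hb_dose_umol)
      if (!inherits(p, "hemopk_pk")) next
      expect_identical(p$auc_0_inf, p$auc_0_clast + p$auc_clast_inf)
      expect_equal(p$cl_L_per_h * p$auc_0_inf, cfg$hb_dose_umol,
                   tolerance = 1e-12)
      expect_equal(p$vc_L * p$cmax_uM, cfg$hb_dose_umol, tolerance = 1e-12)
      expect_equal(p$t_half_h * p$cl_L_per_h, log(2) * p$vc_L,
                   tolerance = 1e-12)
    }
  }
})

test_that("doubling the dose doubles CL and Vc but not the half-life", {
  t <- seq(0, 40, by = 0.05)[-1]
  profile <- prof(t, 50 * exp(-0.2 * t))
  r1 <- nca_subject(profile, 100)
  r2 <- nca_subject(profile, 200)
  expect_equal(r2$cl_L_per_h, 2 * r1$cl_L_per_h)
  expect_equal(r2$vc_L, 2 * r1$vc_L)
  expect_equal(r2$t_half_h, r1$t_half_h)
})

test_that("component failures surface as diagnostic records, not errors", {
  res <- nca_subject(prof(c(0, 1, 2), c(0, 5, NA)), 100)
  expect_s3_class(res, "hemopk_nca_failure")
  expect_true(nchar(res$message) > 0)
  expect_error(nca_subject(prof(1:5, 5:1), 0), "positive")
})

test_that("Vc and CL from printed group means reproduce the reported scale", {
  dose <- hb_grams_to_umol_heme(4)
  vc <- dose / 377.2 # mean Cmax, human Hb arm
  cl <- dose / 1929 # mean AUC0-inf, human Hb arm
  expect_equal(vc, 0.667, tolerance = 0.05)
  expect_equal(cl, 0.1319, tolerance = 0.05)
})

test_that("group aggregation reports mean, SEM and n per parameter", {
  t <- seq(0, 40, by = 0.05)[-1]
  p <- nca_subject(prof(t, 50 * exp(-0.2 * t)), 100)
  agg <- aggregate_group(list(p, p, p))
  expect_true(all(agg$sem == 0))
  expect_true(all(agg$n == 3))

  mk <- function(v) {
    q <- p
    q$cmax_uM <- v
    q
  }
  agg2 <- aggregate_group(list(mk(1), mk(2), mk(3)))
  row <- agg2[agg2$parameter == "cmax_uM", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sem, stats::sd(1:3) / sqrt(3), tolerance = 1e-12)
  expect_equal(row$sem, 0.5774, tolerance = 1e-4)

  one <- aggregate_group(list(p))
  expect_true(all(is.na(one$sem)))
  expect_error(aggregate_group(list()), "empty")

  fail <- structure(list(message = "x"), class = "hemopk_nca_failure")
  agg3 <- aggregate_group(list(p, fail))
  expect_equal(attr(agg3, "n_failed"), 1)
  expect_true(all(agg3$n == 1))
})

test_that("mean of per-subject CL is not dose over mean AUC", {
  aucs <- c(1000, 2000, 4000)
  dose <- 248.2
  mean_of_ratios <- mean(dose / aucs)
  ratio_of_means <- dose / mean(aucs)
  expect_gt(mean_of_ratios, ratio_of_means)
})

test_that("noise-free simulator output yields accurate parameter recovery", {
  k <- 0.2
  cfg <- study_config(hp_dose_g = 0, basal_hp_uM = 0, k_el_free = k,
                      noise_cv = 0, n_subjects = 1)
  sub <- simulate_subject(cfg, 1)
  res <- nca_subject(sub$free, cfg$hb_dose_umol)
  truth_cl <- k * cfg$plasma_volume_L
  expect_lt(abs(res$cl_L_per_h - truth_cl) / truth_cl, 0.02)
  expect_lt(abs(res$k_terminal - k) / k, 0.01)
  expect_lt(abs(res$vc_L - cfg$plasma_volume_L) / cfg$plasma_volume_L, 0.06)
})

test_that("median CL error stays under 10% across replicate noisy studies", {
  k <- 0.2
  errs <- unlist(lapply(1:100, function(rep) {
    cfg <- study_config(hp_dose_g = 0, basal_hp_uM = 0, k_el_free = k,
                        noise_cv = 0.1, n_subjects = 6, seed = 1000 + rep)
    study <- simulate_study(cfg)
    vapply(study, function(s) {
      p <- nca_subject(s$free, cfg$hb_dose_umol)
      abs(p$cl_L_per_h - k * cfg$plasma_volume_L) /
        (k * cfg$plasma_volume_L)
    }, numeric(1))
  }))
  expect_lt(stats::median(errs), 0.10)
})
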