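test_that("effect-site solution matches the constant-input closed form", {
  tt <- seq(0, 24, by = 0.25)
  ce <- effect_site_conc(tt, rep(10, length(tt)), ke0 = 0.4)
  closed <- 10 * (1 - exp(-0.4 * tt))
  expect_rel_error(ce[-1], closed[-1], 0.001)

  # equilibration limit
  prof <- simulate_pk_profile(pk_scenario(dose = 200))
  ce_fast <- effect_site_conc(prof$time_h, prof$cp, ke0 = 1000)
  late <- prof$time_h >= 0.5
  expect_rel_error(ce_fast[late], prof$cp[late], 0.01)

  expect_error(effect_site_conc(tt, rep(1, length(tt)), ke0 = 0), "positive")
  expect_error(effect_site_conc(c(1, 2), c(1, 1), 0.3), "from 0")
})

test_that("effect-site solution matches an independent stiff ODE oracle", {
  sc <- pk_scenario(dose = 300, ke0 = 0.3)
  prof <- simulate_pk_profile(sc)
  amp <- 300e6 * sc$ka / (sc$V_over_F * 1e3 * (sc$ka - sc$ke))
  sol <- deSolve::lsoda(
    y = c(Ce = 0), times = prof$time_h,
    func = function(t, y, p) {
      cp <- amp * (exp(-sc$ke * t) - exp(-sc$ka * t))
      list(sc$ke0 * (cp - y[1]))
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  keep <- prof$time_h >= 0.5
  expect_rel_error(prof$ce[keep], sol[keep, "Ce"], 0.005)
})

test_that("effect-site concentration converges to plasma for settling profiles", {
  # both decay to 0; check relative gap closes late
  prof <- simulate_pk_profile(pk_scenario(dose = 100,
                                          sample_times = seq(0, 60, 0.25)))
  gap <- abs(prof$ce - prof$cp) / pmax(prof$cp, 1e-12)
  expect_lt(tail(prof$ce, 1) / max(prof$ce), 0.02)
})

test_that("the Emax model is half-maximal at EC50 and monotone", {
  expect_equal(emax_occupancy(5.52, 5.52, 0.758), 50)
  expect_equal(emax_occupancy(0, 3, 2), 0)
  expect_equal(emax_occupancy(100, 5.52, 0.758), 90.0, tolerance = 5e-4)

  cc <- seq(0, 50, by = 0.5)
  occ <- emax_occupancy(cc, 4, 1.3)
  expect_true(all(diff(occ) > 0))
  expect_true(all(occ <= 100))
  # scale invariance: joint rescale of C and EC50 leaves occupancy unchanged
  expect_equal(emax_occupancy(7 * cc, 7 * 4, 1.3), occ, tolerance = 1e-12)
  # monotone in Emax
  expect_true(all(emax_occupancy(cc[-1], 4, 1.3, emax = 80) <
                    emax_occupancy(cc[-1], 4, 1.3, emax = 100)))
})

test_that("plasma-mode Emax fitting recovers EC50 with gamma fixed at 1", {
  conc <- exp(seq(log(0.5), log(50), length.out = 22))
  occ <- emax_occupancy(conc, 3.01, 1)
  f <- fit_emax(conc, occ, "plasma")
  expect_rel_error(f$ec50, 3.01, 0.01)
  expect_equal(f$gamma, 1)
  expect_identical(f$emax, 100)
})

test_that("effect-site-mode fitting recovers EC50 and gamma jointly", {
  conc <- exp(seq(log(0.5), log(50), length.out = 22))
  occ <- emax_occupancy(conc, 5.52, 0.758)
  f <- fit_emax(conc, occ, "effect_site")
  expect_rel_error(f$ec50, 5.52, 0.01)
  expect_rel_error(f$gamma, 0.758, 0.01)

  # seeded noisy recovery stays in a loose band
  set.seed(31)
  noisy <- occ + rnorm(22, 0, 0.05 * occ)
  fn <- fit_emax(conc, noisy, "effect_site")
  expect_rel_error(fn$ec50, 5.52, 0.2)
})

test_that("degenerate occupancy data are flagged or rejected", {
  conc <- c(1, 2, 4, 8)
  expect_error(fit_emax(conc, c(0, 0, 0, 0), "plasma"), "unidentifiable")
  f <- fit_emax(rep(3, 4), rep(50, 4), "plasma")
  expect_true(any(grepl("degenerate", f$flags)))
  expect_equal(f$ec50, 3, tolerance = 0.01)
})

test_that("the joint effect-site fit recovers (ke0, EC50, gamma) from peak/trough designs", {
  cohort <- simulate_pkpd_cohort(doses_mg = c(50, 100, 200, 300, 600, 600),
                                 ke0 = 0.3, ec50 = 5.52, gamma = 0.758)
  f <- fit_emax_effect_site_joint(cohort)
  expect_true(f$converged)
  expect_rel_error(f$ke0, 0.3, 0.02)
  expect_rel_error(f$ec50, 5.52, 0.02)
  expect_rel_error(f$gamma, 0.758, 0.02)
})

test_that("plasma and effect-site EC50 agree without lag and split under slow ke0", {
  run <- function(ke0) {
    cohort <- simulate_pkpd_cohort(doses_mg = c(50, 100, 200, 300, 600, 600),
                                   ke0 = ke0, ec50 = 5, gamma = 1)
    cp_obs <- unlist(lapply(cohort, function(s) {
      approx(s$time_h, s$cp, xout = s$obs_time_h)$y
    }))
    occ_obs <- unlist(lapply(cohort, function(s) s$occupancy))
    list(plasma = fit_emax(cp_obs, occ_obs, "plasma")$ec50,
         es = fit_emax_effect_site_joint(
           cohort, start = list(ke0 = 0.3, ec50 = 5, gamma = 1))$ec50)
  }
  fast <- run(50)
  expect_rel_error(fast$plasma, fast$es, 0.05)
  slow <- run(0.1)
  expect_gt(max(slow$es / slow$plasma, slow$plasma / slow$es), 1.2)
})

test_that("hysteresis: trough occupancy exceeds the no-lag plasma prediction", {
  prof <- simulate_pk_profile(pk_scenario(dose = 300, ke0 = 0.3))
  at <- function(x, t) approx(prof$time_h, x, xout = t)$y
  occ_true <- emax_occupancy(at(prof$ce, 24), 5.52, 0.758)
  occ_plasma_pred <- emax_occupancy(at(prof$cp, 24), 5.52, 0.758)
  expect_gt(occ_true, occ_plasma_pred)
})

test_that("single-time occupancy designs flag ke0 as unidentifiable", {
  cohort <- simulate_pkpd_cohort(doses_mg = c(100, 300, 600),
                                 obs_times_h = 2)
  expect_warning(f <- fit_emax_effect_site_joint(cohort), "unidentifiable")
  expect_true(any(grepl("unidentifiable", f$flags)))
})
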