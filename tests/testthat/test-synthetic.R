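test_that("simulated AIF has the bolus shape: zero at t = 0, continuous peak, exponential tail", {
  tt <- seq(0, 120, by = 0.05)
  a <- simulate_aif(times = tt, peak_time = 2, peak_value = 40,
                    decay_amplitudes = c(1, 0, 0), decay_rates = c(0.2, 0.05, 0.01))
  expect_equal(a$conc[1], 0)
  expect_equal(max(a$conc), 40)
  post <- tt > 2
  expect_equal(a$conc[post], 40 * exp(-0.2 * (tt[post] - 2)), tolerance = 1e-10)
})

test_that("AIF integral matches an independent quadrature of its definition", {
  peak_time <- 1.5; peak_value <- 52
  amps <- c(0.85, 0.12, 0.03); rates <- c(0.5, 0.05, 0.004)
  f <- function(t) {
    a <- peak_value * amps / sum(amps)
    ifelse(t <= peak_time, peak_value * t / peak_time,
           a[1] * exp(-rates[1] * (t - peak_time)) +
             a[2] * exp(-rates[2] * (t - peak_time)) +
             a[3] * exp(-rates[3] * (t - peak_time)))
  }
  quad <- integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 1000L)$value
  closed <- petkin:::aif_integral_closed_form(peak_time, peak_value, amps, rates)
  expect_equal(closed, quad, tolerance = 1e-7)
})

test_that("simulated TACs match an independent ODE oracle and degrade to 1TC at k3 = 0", {
  # zero input -> zero tissue
  zero_aif <- input_function(c(0, 1, 245), c(0, 0, 0), fp = 0.48)
  z <- simulate_tac(kinetic_truth("r", 0.5, 0.1), zero_aif, fx$frames)
  expect_true(all(z$activity == 0))

  oracle1 <- oracle_tac(0.5, 0.1, 0, 0, fx$aif, fx$frames)
  expect_rel_error(fx$tac_1tc$activity, oracle1, 1e-3)

  oracle2 <- oracle_tac(0.5, 0.1, 0.05, 0.05, fx$aif, fx$frames)
  expect_rel_error(fx$tac_2tc$activity, oracle2, 1e-3)
})

test_that("late-time tissue/plasma ratio under a constant input reaches V_T", {
  tt <- seq(0, 800, by = 1)
  step_aif <- input_function(tt, c(0, rep(1, length(tt) - 1)), fp = 0.48)
  frames <- data.frame(frame_start = seq(0, 780, by = 20),
                       frame_end = seq(20, 800, by = 20))
  tc <- simulate_tac(kinetic_truth("r", 0.5, 0.1, 0.05, 0.05), step_aif, frames,
                     dt = 0.5)
  ratio_late <- tail(tc$activity, 1) / 1
  expect_equal(ratio_late, 10, tolerance = 1e-3)
})

test_that("simulate_tac is linear in the input function", {
  aif2 <- fx$aif
  aif2$conc <- 2 * aif2$conc
  doubled <- simulate_tac(fx$gt$putamen, aif2, fx$frames)
  expect_equal(doubled$activity, 2 * fx$tac_putamen$activity, tolerance = 1e-12)
})

test_that("frames beyond the AIF support are rejected", {
  short_aif <- simulate_aif(times = seq(0, 100, by = 0.25))
  expect_error(simulate_tac(fx$gt$putamen, short_aif, fx$frames), "support")
})

test_that("frame noise is seeded, unbiased, and vanishes at level zero", {
  expect_identical(add_noise(fx$tac_putamen, 0)$activity,
                   fx$tac_putamen$activity)
  n1 <- add_noise(fx$tac_putamen, 0.1, seed = 7)
  n2 <- add_noise(fx$tac_putamen, 0.1, seed = 7)
  expect_identical(n1$activity, n2$activity)
  expect_false(identical(n1$activity,
                         add_noise(fx$tac_putamen, 0.1, seed = 8)$activity))

  # law of large numbers: per-frame mean relative deviation ~ 0
  reps <- vapply(1:1000, function(i) {
    add_noise(fx$tac_putamen, 0.05, seed = i)$activity
  }, numeric(length(fx$tac_putamen$activity)))
  rel_dev <- rowMeans(reps) / fx$tac_putamen$activity - 1
  durations <- fx$tac_putamen$frame_end - fx$tac_putamen$frame_start
  sd_mc <- 0.05 / sqrt(durations) / sqrt(1000)
  expect_true(all(abs(rel_dev) < 5 * sd_mc))
})

test_that("the default scenario reproduces the study's uptake landmarks", {
  suv_put <- to_suv(fx$tac_putamen)
  i <- which.max(suv_put$activity)
  peak_mid <- (suv_put$frame_start[i] + suv_put$frame_end[i]) / 2
  expect_gt(max(suv_put$activity), 7)
  expect_lt(max(suv_put$activity), 9)
  expect_gt(peak_mid, 20)
  expect_lt(peak_mid, 40)

  suv_cer <- to_suv(fx$tac_cerebellum)
  j <- which.max(suv_cer$activity)
  cer_mid <- (suv_cer$frame_start[j] + suv_cer$frame_end[j]) / 2
  expect_lte(cer_mid, 5)
  # much faster cerebellar washout: larger slow-phase decline than putamen
  late_ratio <- function(x) tail(x$activity, 1) / max(x$activity)
  expect_lt(late_ratio(suv_cer), late_ratio(suv_put) / 2)
})

test_that("occupancy scenarios invert the Lassen relation exactly", {
  # blocked V_T = V_ND + (1 - occ)(V_T - V_ND), via k3 rescaling
  tr <- kinetic_truth("r", 0.3, 0.3, 0.05, 0.01)  # V_ND 1, V_T 6
  b <- petkin:::block_truth(tr, 0.5)
  expect_equal(b$vt, 3.5)
  expect_equal(petkin:::block_truth(tr, 1)$vt, 1)  # full block -> V_ND
  expect_equal(petkin:::block_truth(tr, 0)$vt, tr$vt)

  expect_error(occupancy_scenario(true_occupancy = c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("simulated occupancy studies carry consistent ground truth and dosing", {
  scen <- occupancy_scenario(n_subjects = 1, true_occupancy = c(0.85, 0.5),
                             noise_level = 0, seed = 3L)
  recs <- simulate_occupancy_study(scen)
  expect_length(recs, 3)
  gt <- attr(recs, "ground_truth")
  base <- gt[gt$condition == "baseline", ]
  b1 <- gt[gt$condition == "blocking_1", ]
  expect_equal(b1$true_vt, 1.5 + (1 - 0.85) * (base$true_vt - 1.5))
  # arterial sampling only on baseline and first blocking scan
  conds <- vapply(recs, function(r) r$condition, character(1))
  expect_null(recs[[which(conds == "blocking_2")]]$input_fun)
  expect_false(is.null(recs[[which(conds == "blocking_1")]]$input_fun))
  # occupancy 0 everywhere reproduces baseline TACs exactly (noiseless)
  scen0 <- occupancy_scenario(n_subjects = 1, true_occupancy = c(0, 0),
                              noise_level = 0, seed = 3L)
  recs0 <- simulate_occupancy_study(scen0)
  expect_equal(recs0[[2]]$tacs$putamen$activity / recs0[[2]]$injected_dose,
               recs0[[1]]$tacs$putamen$activity / recs0[[1]]$injected_dose,
               tolerance = 1e-10)
})

test_that("occupancy study generation is bit-for-bit reproducible under a seed", {
  scen <- occupancy_scenario(n_subjects = 2, noise_level = 0.05, seed = 9L)
  a <- simulate_occupancy_study(scen)
  b <- simulate_occupancy_study(scen)
  expect_identical(lapply(a, function(r) r$tacs$putamen$activity),
                   lapply(b, function(r) r$tacs$putamen$activity))
})

test_that("oral PK profiles follow the closed form and the effect site lags plasma", {
  sc <- pk_scenario(dose = 300)
  prof <- simulate_pk_profile(sc)
  expect_equal(prof$cp[1], 0)
  expect_equal(prof$ce[1], 0)
  amp <- 300e6 * sc$ka / (sc$V_over_F * 1e3 * (sc$ka - sc$ke))
  expect_equal(prof$cp, amp * (exp(-sc$ke * prof$time_h) - exp(-sc$ka * prof$time_h)))
  expect_gt(prof$time_h[which.max(prof$ce)], prof$time_h[which.max(prof$cp)])

  # equilibration limit: very fast ke0 makes Ce track Cp
  fast <- simulate_pk_profile(pk_scenario(dose = 300, ke0 = 500))
  late <- fast$time_h >= 1
  expect_rel_error(fast$ce[late], fast$cp[late], 0.01)

  expect_error(pk_scenario(dose = 300, ka = 0.25, ke = 0.25), "differ")
})
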