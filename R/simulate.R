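#' Kinetic ground truth for one region
#'
#' Rate constants of the serial two-tissue compartment model used by the
#' synthetic-data generator. The implied total volume of distribution is
#' `V_T = (K1/k2)(1 + k3/k4)` and the nondisplaceable volume is
#' `V_ND = K1/k2`.
#'
#' @param region Region label.
#' @param K1 Plasma-to-tissue delivery, mL cm^-3 min^-1.
#' @param k2,k3,k4 Tissue rate constants, 1/min. `k3 = k4 = 0` gives a
#'   one-tissue region.
#' @return Object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(region, K1, k2, k3 = 0, k4 = 0) {
  if (K1 <= 0 || k2 <= 0 || k3 < 0 || k4 < 0) stopf("rates must be positive")
  if (k3 > 0 && k4 == 0) stopf("irreversible binding (k4 = 0 with k3 > 0) is not supported")
  if (k3 == 0) k4 <- 0  # no specific compartment: collapse to the 1TC form
  structure(list(region = region, K1 = K1, k2 = k2, k3 = k3, k4 = k4,
                 vt = vt_from_rates(K1, k2, k3, k4)),
            class = "kinetic_truth")
}

#' Default dynamic frame schedule
#'
#' 6 x 0.5, 3 x 1, 2 x 2, 5 x 5 and 9 x 10 min frames, a 30-min break
#' (out-of-camera gap), then 9 x 10 min frames — a long dynamic acquisition
#' with a rest break, ending at 245 min.
#'
#' @return Data frame with columns `frame_start`, `frame_end` (minutes).
#' @export
default_frame_schedule <- function() {
  durs <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 5), rep(10, 9))
  start <- cumsum(c(0, durs[-length(durs)]))
  end <- start + durs
  gap_start <- max(end) + 30
  durs2 <- rep(10, 9)
  start2 <- gap_start + cumsum(c(0, durs2[-length(durs2)]))
  end2 <- start2 + durs2
  data.frame(frame_start = c(start, start2), frame_end = c(end, end2))
}

#' Default regional kinetic ground truth
#'
#' Twelve gray-matter regions sharing a nondisplaceable volume
#' `V_ND = K1/k2 = 1.5 mL/cm^3` with specific binding (`k3/k4`) graded so the
#' regional `V_T` spans roughly 5-13.5 mL/cm^3. The putamen (highest binding)
#' peaks near SUV 8 around 30 min under the default input function, and the
#' cerebellum (`V_T` 6.4 mL/cm^3 with fast exchange) peaks within the first
#' 5 min and washes out quickly.
#'
#' @param v_nd Shared nondisplaceable volume `K1/k2`, mL/cm^3.
#' @return Named list of [kinetic_truth()] objects.
#' @export
default_ground_truth <- function(v_nd = 1.5) {
  # per region: K1 [mL/cm^3/min], k3, k4 [1/min]; k2 = K1 / v_nd
  spec <- list(
    putamen            = c(0.30, 0.160, 0.020),
    caudate_nucleus    = c(0.32, 0.150, 0.020),
    nucleus_accumbens  = c(0.30, 0.135, 0.020),
    pallidum           = c(0.33, 0.120, 0.020),
    thalamus           = c(0.32, 0.115, 0.022),
    frontal_lobe       = c(0.34, 0.105, 0.022),
    occipital_lobe     = c(0.33, 0.100, 0.024),
    parietal_lobe      = c(0.35, 0.095, 0.025),
    temporal_lobe      = c(0.34, 0.090, 0.026),
    anterior_cingulate = c(0.36, 0.085, 0.028),
    hippocampus        = c(0.33, 0.075, 0.030),
    cerebellum         = c(0.75, 0.26133, 0.080))
  out <- lapply(names(spec), function(r) {
    p <- spec[[r]]
    kinetic_truth(r, p[1], p[1] / v_nd, p[2], p[3])
  })
  names(out) <- names(spec)
  out
}

#' Simulate a bolus-injection arterial input function
#'
#' Linear rise from zero to the peak at `peak_time`, then a tri-exponential
#' decay that is continuous at the peak: the amplitude fractions are
#' normalized to sum to 1 and scaled by `peak_value`.
#'
#' @param times Sample times, minutes, starting at 0.
#' @param peak_time Time of the plasma peak, minutes.
#' @param peak_value Peak parent plasma concentration, kBq/mL.
#' @param decay_amplitudes Three non-negative amplitude fractions.
#' @param decay_rates Three positive decay rates, 1/min, in descending order.
#' @param fp Plasma free fraction stored on the result.
#' @return A [input_function()].
#' @export
simulate_aif <- function(times = seq(0, 245, by = 0.25),
                         peak_time = 1.5, peak_value = 52,
                         decay_amplitudes = c(0.85, 0.12, 0.03),
                         decay_rates = c(0.5, 0.05, 0.004),
                         fp = 0.48) {
  if (peak_value <= 0) stopf("peak_value must be positive")
  if (any(decay_rates <= 0) || any(diff(decay_rates) >= 0)) {
    stopf("decay_rates must be positive and descending")
  }
  if (any(decay_amplitudes < 0) || sum(decay_amplitudes) == 0) {
    stopf("decay_amplitudes must be non-negative with positive sum")
  }
  amps <- peak_value * decay_amplitudes / sum(decay_amplitudes)
  conc <- ifelse(
    times <= peak_time,
    peak_value * times / peak_time,
    colSums(amps * exp(-outer(decay_rates, pmax(times - peak_time, 0)))))
  input_function(times, conc, fp = fp)
}

# Closed-form integral over [0, Inf) of the simulated AIF: rise triangle plus
# sum of A_i / r_i. Used as an analytic cross-check of the shape.
aif_integral_closed_form <- function(peak_time, peak_value, decay_amplitudes,
                                     decay_rates) {
  amps <- peak_value * decay_amplitudes / sum(decay_amplitudes)
  0.5 * peak_time * peak_value + sum(amps / decay_rates)
}

#' Simulate a noiseless regional TAC from kinetic ground truth
#'
#' Convolves the two-tissue impulse response with the input function on a
#' fine grid and averages over each frame. With `k3 = 0` this is exactly the
#' one-tissue model.
#'
#' @param truth A [kinetic_truth()].
#' @param input A [input_function()] covering the frame span.
#' @param frames Data frame with `frame_start`, `frame_end` (minutes).
#' @param injected_dose,body_weight Metadata stored on the TAC (MBq, kg).
#' @param dt Fine-grid step for the convolution, minutes.
#' @return A noiseless [tac()].
#' @export
simulate_tac <- function(truth, input, frames = default_frame_schedule(),
                         injected_dose = 330, body_weight = 85.4, dt = 0.05) {
  stopifnot(inherits(truth, "kinetic_truth"))
  act <- model_frame_activity(truth$K1, truth$k2, truth$k3, truth$k4, input,
                              frames$frame_start, frames$frame_end, dt = dt)
  tac(truth$region, frames$frame_start, frames$frame_end, pmax(act, 0),
      injected_dose = injected_dose, body_weight = body_weight)
}

#' Add frame-duration-scaled Gaussian noise to a TAC
#'
#' Zero-mean Gaussian noise with standard deviation
#' `noise_level * activity / sqrt(frame_duration)`, truncated at zero
#' (negative activities are clipped; a small positive bias at very high noise
#' levels is the documented price of the truncation). Reproducible under a
#' fixed seed; the global RNG state is restored on exit.
#'
#' @param x A `pet_tac`.
#' @param noise_level Fractional noise scale (0 = no noise).
#' @param seed Optional integer seed.
#' @return A noisy `pet_tac`.
#' @export
add_noise <- function(x, noise_level, seed = NULL) {
  stopifnot(inherits(x, "pet_tac"))
  if (noise_level < 0) stopf("noise_level must be non-negative")
  if (noise_level == 0) return(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sds <- noise_level * x$activity / sqrt(frame_durations(x))
  x$activity <- pmax(x$activity + stats::rnorm(length(sds), 0, sds), 0)
  x
}

#' Occupancy-study scenario
#'
#' Study conditions for a simulated baseline + two-blocking-scan occupancy
#' design. Occupancy is applied by rescaling `k3` (specific binding) to
#' `k3 (1 - occupancy)` while leaving `K1/k2` fixed, so the nondisplaceable
#' volume is condition-invariant, as the Lassen model assumes; the blocked
#' total volume is then exactly `V_ND + (1 - occupancy)(V_T - V_ND)`.
#'
#' @param regions Named list of [kinetic_truth()] objects sharing `K1/k2`.
#' @param true_v_nd Common nondisplaceable volume, mL/cm^3.
#' @param true_occupancy Length-2 vector: fractional occupancy at the first
#'   (peak) and second (trough) blocking scan, each in \[0, 1\].
#' @param noise_level Frame-noise scale passed to [add_noise()].
#' @param n_subjects Number of subjects.
#' @param drug_dose_mg Oral drug dose recorded on the blocking scans.
#' @param seed Integer seed.
#' @return Object of class `occupancy_scenario`.
#' @export
occupancy_scenario <- function(regions = default_ground_truth(),
                               true_v_nd = 1.5,
                               true_occupancy = c(0.85, 0.5),
                               noise_level = 0.02, n_subjects = 3,
                               drug_dose_mg = 600, seed = 1L) {
  if (any(true_occupancy < 0) || any(true_occupancy > 1)) {
    stopf("occupancy must lie in [0, 1]")
  }
  for (r in regions) {
    if (abs(r$K1 / r$k2 - true_v_nd) > 1e-6 * true_v_nd) {
      stopf("region '%s' has K1/k2 = %.4f, inconsistent with true_v_nd = %.4f",
            r$region, r$K1 / r$k2, true_v_nd)
    }
  }
  structure(list(regions = regions, true_v_nd = true_v_nd,
                 true_occupancy = true_occupancy, noise_level = noise_level,
                 n_subjects = n_subjects, drug_dose_mg = drug_dose_mg,
                 seed = as.integer(seed)),
            class = "occupancy_scenario")
}

# Rescale k3 so the blocked VT equals V_ND + (1 - occ)(VT - V_ND).
block_truth <- function(truth, occupancy) {
  kinetic_truth(truth$region, truth$K1, truth$k2,
                truth$k3 * (1 - occupancy), truth$k4)
}

#' Simulate a full occupancy study
#'
#' Per subject: a baseline scan and two blocking scans. The arterial input
#' function keeps a common shape across scans and scales with the injected
#' dose (drawn per scan), and arterial sampling is recorded for the baseline
#' and first blocking scan only — the second blocking scan's AIF must be
#' reconstructed with [weighted_aif()], as in the study design being
#' emulated.
#'
#' @param scenario An [occupancy_scenario()].
#' @param frames Frame schedule (the 120-min truncation typical of blocking
#'   studies is obtained by passing a truncated schedule).
#' @return List of [study_record()]s, plus a `ground_truth` attribute table.
#' @export
simulate_occupancy_study <- function(scenario,
                                     frames = default_frame_schedule()) {
  stopifnot(inherits(scenario, "occupancy_scenario"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed)
  aif_times <- seq(0, max(frames$frame_end), by = 0.25)
  conditions <- c("baseline", "blocking_1", "blocking_2")
  occ_by_cond <- c(0, scenario$true_occupancy)
  interval_by_cond <- c(NA_real_, 2, 24)
  ref_dose <- 330
  records <- list()
  truth_rows <- list()
  for (s in seq_len(scenario$n_subjects)) {
    sid <- sprintf("S%02d", s)
    doses <- stats::runif(3, 300, 360)
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      scale <- doses[ci] / ref_dose
      aif <- simulate_aif(times = aif_times)
      aif$conc <- aif$conc * scale
      tacs <- lapply(scenario$regions, function(tr) {
        bt <- block_truth(tr, occ_by_cond[ci])
        tc <- simulate_tac(bt, aif, frames, injected_dose = doses[ci])
        add_noise(tc, scenario$noise_level,
                  seed = scenario$seed + 1000L * s + 100L * ci +
                    match(tr$region, names(scenario$regions)))
      })
      names(tacs) <- names(scenario$regions)
      records[[length(records) + 1L]] <- study_record(
        subject_id = sid, condition = cond, tacs = tacs,
        input_fun = if (cond != "blocking_2") aif else NULL,
        injected_dose = doses[ci],
        drug_dose = if (cond == "baseline") NA_real_ else scenario$drug_dose_mg,
        dose_to_scan_interval = interval_by_cond[ci])
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject_id = sid, condition = cond,
        region = names(scenario$regions),
        true_vt = vapply(scenario$regions, function(tr) {
          vt_from_rates(tr$K1, tr$k2, tr$k3 * (1 - occ_by_cond[ci]), tr$k4)
        }, numeric(1L)),
        true_occupancy = occ_by_cond[ci], row.names = NULL)
    }
  }
  attr(records, "ground_truth") <- do.call(rbind, truth_rows)
  attr(records, "true_v_nd") <- scenario$true_v_nd
  records
}

#' Simulate a test-retest cohort
#'
#' Between-subject variability is applied as log-normal multipliers on `K1`
#' and `k3` (coefficient of variation `between_cv`, shared across the two
#' scans of a subject). Within-subject variability has two sources: frame
#' counting noise ([add_noise()]) and a scan-level log-normal multiplier on
#' `K1` (CV `within_cv`) standing in for day-to-day physiology and
#' input-function measurement error — counting noise alone, averaged over a
#' long acquisition, would put the test-retest spread far below what
#' outcome-measure reliability studies actually observe. With between-subject
#' spread above the within-subject spread this yields the high intraclass
#' correlations characteristic of reliable tracers.
#'
#' @param n_subjects Number of subjects (each scanned twice).
#' @param regions Named list of [kinetic_truth()]s.
#' @param noise_level Frame-noise scale.
#' @param between_cv Between-subject CV of the subject multipliers.
#' @param within_cv Scan-level CV of the per-scan `K1` multiplier.
#' @param seed Integer seed.
#' @param frames Frame schedule.
#' @return List of [study_record()]s (conditions `test`, `retest`) with a
#'   `ground_truth` attribute.
#' @export
simulate_trt_study <- function(n_subjects = 6,
                               regions = default_ground_truth(),
                               noise_level = 0.05, between_cv = 0.15,
                               within_cv = 0.07, seed = 1L,
                               frames = default_frame_schedule()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sdlog <- sqrt(log(1 + between_cv^2))
  aif_times <- seq(0, max(frames$frame_end), by = 0.25)
  records <- list()
  truth_rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    m_k1 <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    m_k3 <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    subj_regions <- lapply(regions, function(tr) {
      kinetic_truth(tr$region, tr$K1 * m_k1, tr$k2, tr$k3 * m_k3, tr$k4)
    })
    for (ci in 1:2) {
      cond <- c("test", "retest")[ci]
      dose <- stats::runif(1, 300, 360)
      sdw <- sqrt(log(1 + within_cv^2))
      m_scan <- if (within_cv > 0) stats::rlnorm(1, -sdw^2 / 2, sdw) else 1
      aif <- simulate_aif(times = aif_times)
      aif$conc <- aif$conc * dose / 330
      tacs <- lapply(subj_regions, function(tr) {
        scan_tr <- kinetic_truth(tr$region, tr$K1 * m_scan, tr$k2,
                                 tr$k3, tr$k4)
        tc <- simulate_tac(scan_tr, aif, frames, injected_dose = dose)
        add_noise(tc, noise_level,
                  seed = seed + 1000L * s + 100L * ci +
                    match(tr$region, names(regions)))
      })
      names(tacs) <- names(regions)
      records[[length(records) + 1L]] <- study_record(
        subject_id = sid, condition = cond, tacs = tacs, input_fun = aif,
        injected_dose = dose)
    }
    truth_rows[[s]] <- data.frame(
      subject_id = sid, region = names(regions),
      true_vt = vapply(subj_regions, function(tr) tr$vt, numeric(1L)),
      row.names = NULL)
  }
  attr(records, "ground_truth") <- do.call(rbind, truth_rows)
  records
}

#' Oral one-compartment PK scenario
#'
#' @param dose Oral dose, mg.
#' @param ka First-order absorption rate, 1/h.
#' @param ke First-order elimination rate, 1/h (must differ from `ka`).
#' @param V_over_F Apparent volume of distribution, L.
#' @param ke0 Effect-site equilibration rate, 1/h.
#' @param sample_times Sampling times, hours post-dose.
#' @return Object of class `pk_scenario`.
#' @export
pk_scenario <- function(dose, ka = 1.5, ke = 0.15, V_over_F = 1500,
                        ke0 = 0.3, sample_times = seq(0, 30, by = 0.25)) {
  if (dose <= 0 || ka <= 0 || ke <= 0 || V_over_F <= 0 || ke0 <= 0) {
    stopf("all PK parameters must be positive")
  }
  if (abs(ka - ke) < 1e-9) stopf("ka must differ from ke (degenerate closed form)")
  structure(list(dose = dose, ka = ka, ke = ke, V_over_F = V_over_F,
                 ke0 = ke0, sample_times = as.numeric(sample_times)),
            class = "pk_scenario")
}

#' Simulate an oral-dose plasma and effect-site concentration profile
#'
#' Plasma concentration follows the one-compartment first-order-absorption
#' closed form
#' `Cp(t) = dose ka / (V/F (ka - ke)) (exp(-ke t) - exp(-ka t))` (ng/mL, with
#' dose in mg and V/F in L), and the effect-site concentration is obtained by
#' solving `dCe/dt = ke0 (Cp - Ce)` against this profile on a fine grid.
#'
#' @param scenario A [pk_scenario()].
#' @return Data frame with columns `time_h`, `cp`, `ce` (ng/mL).
#' @export
simulate_pk_profile <- function(scenario) {
  stopifnot(inherits(scenario, "pk_scenario"))
  tt <- scenario$sample_times
  amp <- scenario$dose * 1e6 * scenario$ka /
    (scenario$V_over_F * 1e3 * (scenario$ka - scenario$ke))
  cp_fun <- function(t) amp * (exp(-scenario$ke * t) - exp(-scenario$ka * t))
  fine <- seq(0, max(tt), by = min(0.01, max(diff(sort(unique(tt)))) / 4))
  ce_fine <- effect_site_conc(fine, cp_fun(fine), scenario$ke0)
  data.frame(time_h = tt, cp = cp_fun(tt),
             ce = stats::approx(fine, ce_fine, xout = tt)$y)
}
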