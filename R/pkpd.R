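# Concentration-occupancy modeling: effect-site (ke0) link and sigmoidal
# Emax fitting. All times in this module are hours post-dose; conversions
# from the kinetic modules' minutes go through hours_to_minutes()/
# minutes_to_hours().

#' Effect-site concentration from a plasma profile
#'
#' Solves the first-order effect-site link `dCe/dt = ke0 (Cp - Ce)` with
#' `Ce(0) = 0` by an exact piecewise update that treats Cp as linear between
#' samples — no step-size error beyond the linear-Cp assumption, so the
#' solution is exact for piecewise-linear plasma profiles.
#'
#' @param time_h Sample times, hours, increasing from 0.
#' @param cp Plasma concentration at `time_h`, ng/mL.
#' @param ke0 Equilibration rate constant, 1/h (> 0).
#' @return Effect-site concentration at `time_h`, ng/mL.
#' @export
effect_site_conc <- function(time_h, cp, ke0) {
  if (ke0 <= 0) stopf("ke0 must be positive")
  if (time_h[1L] != 0 || any(diff(time_h) <= 0)) {
    stopf("times must increase strictly from 0")
  }
  n <- length(time_h)
  ce <- numeric(n)
  for (i in seq_len(n - 1L)) {
    dt <- time_h[i + 1L] - time_h[i]
    a <- cp[i]
    b <- (cp[i + 1L] - cp[i]) / dt
    e <- exp(-ke0 * dt)
    ce[i + 1L] <- ce[i] * e + a * (1 - e) + b * (dt - (1 - e) / ke0)
  }
  ce
}

#' Sigmoidal Emax occupancy model
#'
#' `Occupancy(%) = Emax C^gamma / (EC50^gamma + C^gamma)` with `Emax` in
#' percent (default 100, i.e. full occupancy at saturating concentration).
#' At `C = EC50` the model returns exactly `Emax/2` for any `gamma` — the
#' defining property of the half-maximal effective concentration.
#'
#' @param conc Concentration, ng/mL (>= 0).
#' @param ec50 Half-maximal effective concentration, ng/mL (> 0).
#' @param gamma Sigmoidal shape (Hill) factor (> 0), default 1.
#' @param emax Maximal occupancy, percent, default 100.
#' @return Occupancy in percent, monotone in `conc`, bounded by `emax`.
#' @export
emax_occupancy <- function(conc, ec50, gamma = 1, emax = 100) {
  if (any(conc < 0)) stopf("concentration must be non-negative")
  if (ec50 <= 0 || gamma <= 0 || emax <= 0) {
    stopf("ec50, gamma and emax must be positive")
  }
  cg <- conc^gamma
  emax * cg / (ec50^gamma + cg)
}

new_emax_fit <- function(pars, rel_se, mode, rss, converged,
                         flags = character()) {
  structure(list(emax = 100, ec50 = pars[["ec50"]],
                 gamma = getpar2(pars, "gamma", 1),
                 ke0 = if ("ke0" %in% names(pars)) pars[["ke0"]] else NA_real_,
                 relative_se_pct = rel_se, mode = mode, rss = rss,
                 converged = converged, flags = flags),
            class = "emax_fit")
}

getpar2 <- function(p, nm, default) if (nm %in% names(p)) p[[nm]] else default

#' @export
print.emax_fit <- function(x, ...) {
  cat(sprintf("<emax_fit> mode %s: EC50 = %.3f ng/mL, gamma = %.3f%s (Emax fixed 100%%)%s\n",
              x$mode, x$ec50, x$gamma,
              if (is.na(x$ke0)) "" else sprintf(", ke0 = %.3f /h", x$ke0),
              if (!x$converged) " [NOT CONVERGED]" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the sigmoidal Emax model to concentration-occupancy pairs
#'
#' Unweighted nonlinear least squares on occupancy percent with `Emax` fixed
#' at 100%. In plasma mode the Hill factor is fixed at 1 (noncooperative
#' binding) and only `EC50` is free; in effect-site mode both `EC50` and
#' `gamma` are free. Parameters are fitted on the log scale; relative
#' standard errors come from the fit covariance. Occupancies outside
#' \[0, 100\]% (possible under noise) are retained.
#'
#' @param conc Concentrations, ng/mL.
#' @param occupancy Observed occupancies, percent.
#' @param mode `"plasma"` or `"effect_site"`.
#' @param start Named list of start values (`ec50`, and `gamma` in
#'   effect-site mode).
#' @return An `emax_fit`.
#' @export
fit_emax <- function(conc, occupancy, mode = c("plasma", "effect_site"),
                     start = list(ec50 = stats::median(conc[conc > 0]),
                                  gamma = 1)) {
  mode <- match.arg(mode)
  keep <- is.finite(conc) & is.finite(occupancy) & conc > 0
  conc <- conc[keep]
  occupancy <- occupancy[keep]
  if (length(conc) < 3L) stopf("Emax fit needs >= 3 usable points")
  if (all(abs(occupancy) < 1)) {
    stopf("all occupancies ~ 0: EC50 unidentifiable")
  }
  free <- if (mode == "plasma") "ec50" else c("ec50", "gamma")
  resid_fun <- function(logp) {
    p <- exp(logp)
    gamma <- if (mode == "plasma") 1 else p[2L]
    occupancy - emax_occupancy(conc, p[1L], gamma)
  }
  fit <- minpack.lm::nls.lm(
    par = log(unlist(start[free])), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  pars <- stats::setNames(exp(as.numeric(fit$par)), free)
  converged <- fit$info %in% 1:4
  flags <- character()
  if (!converged) {
    flags <- "non-convergence"
    warnf("Emax fit did not converge: %s", fit$message)
  }
  if (length(unique(conc)) == 1L) {
    flags <- c(flags, "single concentration: EC50 degenerate")
  }
  # delta method: SE of exp(logp) relative to estimate equals SE of logp
  rel_se <- rel_se_from_logfit(fit, free)
  new_emax_fit(pars, rel_se, mode, fit$deviance, converged, flags)
}

rel_se_from_logfit <- function(fit, par_names) {
  n <- length(fit$fvec)
  k <- length(fit$par)
  out <- rep(NA_real_, k)
  names(out) <- par_names
  se_log <- tryCatch({
    sigma2 <- fit$deviance / max(n - k, 1L)
    sqrt(pmax(diag(sigma2 * solve(fit$hessian / 2)), 0))
  }, error = function(e) NULL)
  if (!is.null(se_log)) out[] <- 100 * se_log
  out
}

#' Joint effect-site Emax fit (ke0, EC50, gamma)
#'
#' For cohorts where occupancy was measured at known times post-dose (e.g. a
#' peak scan ~2 h and a trough scan ~24 h after dosing) while the drug
#' equilibrates slowly with its effect site, this jointly estimates the
#' equilibration constant `ke0`, `EC50` and `gamma` by minimizing squared
#' occupancy residuals, with model occupancy
#' `emax_occupancy(effect_site_conc(Cp, ke0)(t_obs), EC50, gamma)` and Emax
#' fixed at 100%. `ke0` is searched on the log scale over a deterministic
#' 7-point multi-start grid spanning 1e-3 to 1e2 per hour.
#'
#' @param subjects List; each element a list with `time_h`, `cp` (the plasma
#'   profile) and `obs_time_h`, `occupancy` (the occupancy observations,
#'   percent).
#' @param start Named list of start values (`ke0`, `ec50`, `gamma`).
#' @return An `emax_fit` with `mode = "effect_site"` and `ke0` estimated.
#' @export
fit_emax_effect_site_joint <- function(subjects,
                                       start = list(ke0 = 0.3, ec50 = 5,
                                                    gamma = 1)) {
  all_obs_t <- unlist(lapply(subjects, function(s) s$obs_time_h))
  if (length(unique(round(all_obs_t, 6))) < 2L) {
    warnf("occupancy observed at a single post-dose time: ke0 unidentifiable")
  }
  obs <- unlist(lapply(subjects, function(s) s$occupancy))
  resid_fun <- function(logp) {
    p <- exp(logp)
    pred <- unlist(lapply(subjects, function(s) {
      ce <- effect_site_conc(s$time_h, s$cp, p[1L])
      ce_obs <- stats::approx(s$time_h, ce, xout = s$obs_time_h)$y
      emax_occupancy(ce_obs, p[2L], p[3L])
    }))
    obs - pred
  }
  ke0_grid <- exp(seq(log(1e-3), log(1e2), length.out = 7))
  best <- NULL
  for (k0 in ke0_grid) {
    st <- log(c(ke0 = k0, ec50 = start$ec50, gamma = start$gamma))
    cand <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(best) || cand$deviance < best$deviance)) best <- cand
  }
  if (is.null(best)) stopf("joint effect-site fit failed at every start")
  free <- c("ke0", "ec50", "gamma")
  pars <- stats::setNames(exp(as.numeric(best$par)), free)
  converged <- best$info %in% 1:4
  flags <- if (length(unique(round(all_obs_t, 6))) < 2L) {
    "single observation time: ke0 unidentifiable"
  } else character()
  rel_se <- rel_se_from_logfit(best, free)
  new_emax_fit(pars[c("ec50", "gamma", "ke0")], rel_se, "effect_site",
               best$deviance, converged, flags)
}
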