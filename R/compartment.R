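#' Compartment model fit result
#'
#' @description Returned by [fit_1tc()] and [fit_2tc()]. Holds the model
#' identity, rate constants, the implied total volume of distribution
#' (`V_T = K1/k2` for 1TC, `(K1/k2)(1 + k3/k4)` for 2TC), the weighted
#' residual sum of squares, the Akaike information criterion
#' `AIC = n log(RSS/n) + 2k`, per-parameter standard errors from the fit
#' covariance, and a convergence flag.
#'
#' @name kinetic_fit_result
NULL

getpar <- function(p, nm) if (nm %in% names(p)) p[[nm]] else 0

new_kinetic_fit <- function(model, pars, se, rss, n, weights, converged,
                            flags = character(), data_digest = NULL) {
  k <- length(pars)
  vt <- vt_from_rates(pars[["K1"]], pars[["k2"]],
                      getpar(pars, "k3"), getpar(pars, "k4"))
  structure(list(model = model, pars = pars, se = se,
                 vt = vt, rss = rss, n = n, n_par = k,
                 aic = n * log(rss / n) + 2 * k,
                 weights = weights, converged = converged, flags = flags,
                 data_digest = data_digest),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: V_T = %.3f mL/cm^3, AIC = %.2f%s\n",
              x$model, x$vt, x$aic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  cat("  ", paste(sprintf("%s = %.4g (SE %.2g)", names(x$pars), x$pars,
                          x$se[names(x$pars)]), collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

fit_weights <- function(tc, weights) {
  switch(weights,
         duration = frame_durations(tc),
         uniform = rep(1, length(tc$activity)),
         stopf("unknown weighting scheme '%s'", weights))
}

# Shared weighted-least-squares driver for the compartment models.
# Parameters are fitted on the natural scale with box bounds; when the first
# start fails to converge, a deterministic log-spaced multi-start list is
# tried and the best converged solution kept.
fit_compartment <- function(tc, input, par_names, start, lower, upper,
                            weights, dt, n_multistart = 5L) {
  obs <- tc$activity
  if (all(obs == 0)) stopf("all-zero TAC cannot be fitted")
  w <- fit_weights(tc, weights)
  sw <- sqrt(w)
  fs <- tc$frame_start
  fe <- tc$frame_end
  resid_fun <- function(p) {
    p <- stats::setNames(as.numeric(p), par_names)
    pred <- model_frame_activity(p[["K1"]], p[["k2"]],
                                 getpar(p, "k3"), getpar(p, "k4"),
                                 input, fs, fe, dt = dt)
    sw * (obs - pred)
  }
  run_one <- function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- run_one(start)
  ok <- function(f) !is.null(f) && f$info %in% 1:4
  if (!ok(fit)) {
    # deterministic multi-start: scale every start log-uniformly
    factors <- exp(seq(log(0.1), log(10), length.out = n_multistart))
    for (fac in factors) {
      cand <- run_one(pmin(pmax(start * fac, lower), upper))
      if (ok(cand) && (!ok(fit) || cand$deviance < fit$deviance)) fit <- cand
    }
  }
  if (is.null(fit)) stopf("compartment fit failed at every start")
  pars <- stats::setNames(as.numeric(fit$par), par_names)
  rss <- fit$deviance
  n <- length(obs)
  se <- rep(NA_real_, length(pars))
  names(se) <- par_names
  cov_try <- tryCatch({
    sigma2 <- rss / (n - length(pars))
    covm <- sigma2 * solve(fit$hessian / 2)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) NULL)
  if (!is.null(cov_try)) se <- stats::setNames(cov_try, par_names)
  converged <- fit$info %in% 1:4
  flags <- character()
  if (!converged) {
    flags <- c(flags, sprintf("non-convergence (info %d): %s",
                              fit$info, fit$message))
    warnf("compartment fit did not converge: %s", fit$message)
  }
  at_lower <- par_names[abs(pars - lower) < 1e-12]
  if ("k4" %in% at_lower) {
    flags <- c(flags, "k4 at lower bound: kinetics irreversible-like")
  }
  new_kinetic_fit(if (length(pars) == 2L) "1TC" else "2TC",
                  pars, se, rss, n, weights, converged, flags,
                  data_digest = fnv1a_hash(list(fs, fe, obs)))
}

#' Fit the one-tissue compartment model
#'
#' Weighted nonlinear least squares of the frame-averaged 1TC prediction
#' (impulse response `K1 exp(-k2 t)` convolved with the metabolite-corrected
#' input function) against the observed TAC. Default weights are the frame
#' durations. `V_T = K1/k2`.
#'
#' @param tc A [tac()] with at least 4 frames.
#' @param input A [input_function()] covering the frame span.
#' @param weights `"duration"` (default) or `"uniform"`.
#' @param start Named start values for `K1`, `k2`.
#' @param dt Fine-grid convolution step, minutes.
#' @return A `kinetic_fit` (see [kinetic_fit_result]).
#' @export
fit_1tc <- function(tc, input, weights = "duration",
                    start = c(K1 = 0.1, k2 = 0.1), dt = 0.1) {
  stopifnot(inherits(tc, "pet_tac"), inherits(input, "pet_input"))
  if (length(tc$activity) < 4L) stopf("1TC fit needs at least 4 frames")
  fit_compartment(tc, input, c("K1", "k2"), start,
                  lower = rep(1e-4, 2), upper = rep(10, 2),
                  weights = weights, dt = dt)
}

#' Fit the serial two-tissue compartment model
#'
#' As [fit_1tc()] with four rate constants;
#' `V_T = (K1/k2)(1 + k3/k4)`. When the initial start fails, a deterministic
#' log-spaced multi-start list is used. A fit with `k4` pinned at its lower
#' bound is flagged as irreversible-like.
#'
#' @inheritParams fit_1tc
#' @param start Named start values for `K1`, `k2`, `k3`, `k4`.
#' @return A `kinetic_fit`.
#' @export
fit_2tc <- function(tc, input, weights = "duration",
                    start = c(K1 = 0.1, k2 = 0.1, k3 = 0.01, k4 = 0.01),
                    dt = 0.1) {
  stopifnot(inherits(tc, "pet_tac"), inherits(input, "pet_input"))
  if (length(tc$activity) < 6L) stopf("2TC fit needs at least 6 frames")
  fit_compartment(tc, input, c("K1", "k2", "k3", "k4"), start,
                  lower = rep(1e-4, 4), upper = rep(10, 4),
                  weights = weights, dt = dt)
}

#' Rank compartment fits by AIC
#'
#' `AIC = n log(RSS/n) + 2k` with `n` the number of frames and `k` the number
#' of free rate constants; a smaller value indicates the more appropriate
#' model. All fits must describe the same data.
#'
#' @param fits List of `kinetic_fit` objects sharing the same TAC.
#' @return The list reordered by ascending AIC, with an `aic` attribute.
#' @export
compare_aic <- function(fits) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, logical(1L),
                                           "kinetic_fit")))
  digests <- vapply(fits, function(f) f$data_digest, character(1L))
  if (length(unique(digests)) != 1L) {
    stopf("AIC comparison requires fits of the same data")
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1L))
  out <- fits[order(aics)]
  attr(out, "aic") <- sort(aics)
  out
}

#' Binding potential from total and nondisplaceable volumes (indirect route)
#'
#' `BP_ND = (V_T - V_ND)/V_ND`, the specific-to-nondisplaceable binding
#' ratio. Negative values (possible under noise) are returned with a warning
#' rather than suppressed.
#'
#' @param vt Total volume of distribution, mL/cm^3.
#' @param vnd Nondisplaceable volume of distribution, mL/cm^3 (> 0).
#' @return BP_ND, dimensionless.
#' @export
indirect_bpnd <- function(vt, vnd) {
  if (any(vnd <= 0)) stopf("V_ND must be positive")
  bp <- (vt - vnd) / vnd
  if (any(bp < 0)) warnf("negative BP_ND (V_T < V_ND); returned as-is")
  bp
}
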