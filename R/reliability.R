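#' Signed test-retest variability
#'
#' `TRT(%) = 100 (test - retest) / ((test + retest)/2)`. The sign is
#' preserved; cohort summaries take absolute values.
#'
#' @param test,retest Outcome values (e.g. V_T or BP_ND), same units.
#' @return Signed percent difference normalized to the pair mean.
#' @export
trt <- function(test, retest) {
  if (any(test + retest == 0)) {
    stopf("TRT undefined when test + retest = 0")
  }
  100 * (test - retest) / ((test + retest) / 2)
}

#' Intraclass correlation coefficient (one-way, paired design)
#'
#' `ICC = (BMS - WMS) / (BMS + WMS)` where BMS and WMS are the
#' between-participant and within-participant mean squares of a one-way
#' ANOVA on exactly two measurements per subject. Ranges over \[-1, 1\];
#' values near 1 indicate that variance is dominated by between-participant
#' differences.
#'
#' @param test,retest Numeric vectors of paired measurements (one entry per
#'   subject).
#' @return The ICC.
#' @export
icc <- function(test, retest) {
  if (length(test) != length(retest)) {
    stopf("each subject needs exactly 2 measurements (test and retest)")
  }
  n <- length(test)
  if (n < 2L) stopf("ICC needs at least 2 subjects")
  x <- cbind(test, retest)
  subj_means <- rowMeans(x)
  grand <- mean(x)
  bms <- 2 * sum((subj_means - grand)^2) / (n - 1)
  wms <- sum((x - subj_means)^2) / n
  if (bms + wms == 0) {
    stopf("ICC undefined: total variance is zero (all measurements identical)")
  }
  (bms - wms) / (bms + wms)
}

#' Reliability summary table across subjects
#'
#' Aggregates per-subject outcome pairs into the usual reliability table:
#' mean absolute TRT (with SD) and ICC, per region and method.
#'
#' @param df Data frame with columns `subject_id`, `region`, `method`,
#'   `test`, `retest`.
#' @return Data frame with one row per region/method: `mean_abs_trt`,
#'   `trt_sd`, `icc`.
#' @export
reliability_table <- function(df) {
  need <- c("subject_id", "region", "method", "test", "retest")
  if (!all(need %in% names(df))) {
    stopf("missing columns: %s", paste(setdiff(need, names(df)), collapse = ", "))
  }
  groups <- unique(df[c("region", "method")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- df[df$region == groups$region[i] & df$method == groups$method[i], ]
    tr <- trt(g$test, g$retest)
    data.frame(region = groups$region[i], method = groups$method[i],
               mean_abs_trt = mean(abs(tr)), trt_sd = stats::sd(abs(tr)),
               icc = icc(g$test, g$retest))
  })
  do.call(rbind, rows)
}

#' Time-stability of V_T under truncated acquisitions
#'
#' Refits the chosen quantifier on progressively truncated data (frames whose
#' end falls at or before each `end_time`) and reports the signed percent
#' bias of each truncated V_T relative to the full-duration estimate.
#' Truncations that leave fewer frames than the quantifier's minimum are
#' marked unavailable (`NA`) rather than erroring.
#'
#' @param tc A [tac()].
#' @param input A [input_function()].
#' @param end_times Truncation times, minutes.
#' @param method `"2tc"`, `"1tc"` or `"logan"`.
#' @param ... Passed to the fitting function.
#' @return Data frame with columns `end_time`, `vt`, `bias_pct`.
#' @export
time_stability <- function(tc, input, end_times = c(60, 90, 120, 180),
                           method = c("2tc", "1tc", "logan"), ...) {
  method <- match.arg(method)
  quantify <- switch(method,
    "2tc" = function(t_, min_frames = 6L) {
      if (length(t_$activity) < min_frames) return(NA_real_)
      fit_2tc(t_, input, ...)$vt
    },
    "1tc" = function(t_, min_frames = 4L) {
      if (length(t_$activity) < min_frames) return(NA_real_)
      fit_1tc(t_, input, ...)$vt
    },
    "logan" = function(t_) {
      if (sum(frame_midpoints(t_) >= 30) < 3L) return(NA_real_)
      logan_vt(t_, input, ...)$slope
    })
  truncate_tac <- function(end_time) {
    keep <- tc$frame_end <= end_time + 1e-9
    if (!any(keep)) return(NULL)
    tac(tc$region, tc$frame_start[keep], tc$frame_end[keep],
        tc$activity[keep], tc$injected_dose, tc$body_weight, tc$units)
  }
  vt_full <- quantify(tc)
  vts <- vapply(end_times, function(et) {
    t_ <- truncate_tac(et)
    if (is.null(t_)) return(NA_real_)
    tryCatch(quantify(t_), error = function(e) NA_real_)
  }, numeric(1L))
  data.frame(end_time = end_times, vt = vts,
             bias_pct = 100 * (vts - vt_full) / vt_full)
}
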