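#' Surrogate input function for the second blocking scan
#'
#' When arterial sampling is only performed on the baseline and first
#' blocking scans, the second blocking scan's AIF is modeled as the
#' injected-dose-weighted average
#' `AIF_b2(t) = ID_b2 (AIF_base(t)/ID_base + AIF_b1(t)/ID_b1) / 2`.
#' The two measured AIFs must share a time grid; if they differ, the first
#' blocking AIF is linearly resampled onto the baseline grid (which it must
#' cover).
#'
#' @param aif_baseline,aif_blocking1 Measured [input_function()]s.
#' @param id_baseline,id_blocking1,id_blocking2 Injected doses, MBq.
#' @return The surrogate [input_function()] for the second blocking scan.
#' @export
weighted_aif <- function(aif_baseline, aif_blocking1,
                         id_baseline, id_blocking1, id_blocking2) {
  stopifnot(inherits(aif_baseline, "pet_input"),
            inherits(aif_blocking1, "pet_input"))
  if (any(c(id_baseline, id_blocking1, id_blocking2) <= 0)) {
    stopf("all injected doses must be positive")
  }
  tt <- aif_baseline$time
  if (!isTRUE(all.equal(tt, aif_blocking1$time))) {
    if (max(aif_blocking1$time) < max(tt) - 1e-9) {
      stopf("AIF grids not alignable: blocking-1 AIF does not cover the baseline grid")
    }
    aif_blocking1 <- input_function(
      tt, stats::approx(aif_blocking1$time, aif_blocking1$conc, xout = tt)$y,
      fp = aif_blocking1$fp)
  }
  conc <- id_blocking2 * (aif_baseline$conc / id_baseline +
                            aif_blocking1$conc / id_blocking1) / 2
  input_function(tt, conc, fp = aif_baseline$fp)
}

#' Lassen occupancy plot
#'
#' Ordinary least squares of the baseline-minus-blocked V_T difference on
#' baseline V_T across regions:
#' `V_T_baseline - V_T_blocking = occupancy (V_T_baseline - V_ND)`.
#' The slope is the global fractional occupancy and the x-intercept
#' (`-intercept/slope`) is the nondisplaceable volume V_ND shared across
#' regions. When the slope is indistinguishable from zero the occupancy is
#' reported as ~0 and V_ND is flagged indeterminate (`NA`).
#'
#' @param vt_baseline,vt_blocking Named numeric vectors of regional V_T
#'   (mL/cm^3); at least 3 shared regions with distinct baseline values.
#' @return Object of class `occupancy_fit` with fields `occupancy`
#'   (fraction), `v_nd`, `slope_se`, `regions_used`, and the per-region plot
#'   coordinates in `plot_data`.
#' @export
lassen <- function(vt_baseline, vt_blocking) {
  shared <- intersect(names(vt_baseline), names(vt_blocking))
  if (length(shared) < 3L) {
    stopf("Lassen plot needs >= 3 shared regions (got %d)", length(shared))
  }
  vb <- as.numeric(vt_baseline[shared])
  vk <- as.numeric(vt_blocking[shared])
  if (length(unique(round(vb, 10))) < 2L) {
    stopf("baseline V_T values must not all be identical")
  }
  d <- vb - vk
  fit <- stats::lm(d ~ vb)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # suppressed: lm warns about "essentially perfect fit" on noiseless input
  slope_se <- suppressWarnings(summary(fit)$coefficients[2L, 2L])
  indeterminate <- abs(slope) < 1e-6
  v_nd <- if (indeterminate) NA_real_ else -intercept / slope
  if (indeterminate) {
    warnf("Lassen slope ~ 0: occupancy ~ 0 and V_ND indeterminate")
  }
  structure(list(occupancy = slope, v_nd = v_nd, slope_se = slope_se,
                 intercept = intercept, regions_used = shared,
                 plot_data = data.frame(region = shared, vt_baseline = vb,
                                        vt_blocking = vk, difference = d)),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("<occupancy_fit> occupancy = %.1f%% (SE %.2f), V_ND = %s mL/cm^3, %d regions\n",
              100 * x$occupancy, 100 * x$slope_se,
              if (is.na(x$v_nd)) "indeterminate" else sprintf("%.3f", x$v_nd),
              length(x$regions_used)))
  invisible(x)
}

#' Binding potential from V_T and V_ND (direct ratio form)
#'
#' `BP_ND = V_T / V_ND - 1`, using a V_ND estimated from the Lassen plot of
#' the highest-occupancy scan. Algebraically identical to [indirect_bpnd()];
#' kept separate because the two routes use differently sourced V_ND.
#'
#' @param vt Total volume of distribution, mL/cm^3.
#' @param vnd Nondisplaceable volume, mL/cm^3 (> 0).
#' @return BP_ND, dimensionless.
#' @export
direct_bpnd <- function(vt, vnd) {
  if (any(vnd <= 0)) stopf("V_ND must be positive")
  vt / vnd - 1
}

#' Regional occupancy from baseline and blocking binding potentials
#'
#' `Occupancy(%) = 100 (1 - BP_ND_blocking / BP_ND_baseline)`. Values can
#' exceed 100% or fall below 0% under noise; they are passed through with a
#' warning rather than clipped.
#'
#' @param bpnd_baseline Baseline BP_ND (> 0).
#' @param bpnd_blocking Post-drug BP_ND.
#' @return Occupancy in percent.
#' @export
regional_occupancy <- function(bpnd_baseline, bpnd_blocking) {
  if (any(bpnd_baseline <= 0)) {
    stopf("regional occupancy requires baseline BP_ND > 0")
  }
  occ <- 100 * (1 - bpnd_blocking / bpnd_baseline)
  out_of_range <- occ < 0 | occ > 100
  if (any(out_of_range)) {
    warnf("%d occupancy value(s) outside [0, 100]%%; returned as-is",
          sum(out_of_range))
  }
  occ
}

#' Full occupancy analysis for one subject
#'
#' Combines the global Lassen estimate with the per-region BP_ND route: V_ND
#' from the highest-occupancy (first blocking) scan's Lassen plot is used to
#' derive regional BP_ND at baseline and under blocking, and from those the
#' regional occupancies. When the first blocking scan's Lassen slope is
#' indeterminate, regional BP_ND and occupancies are reported unavailable.
#'
#' @param vt_baseline Named baseline V_T vector.
#' @param vt_blocking Named list of blocking V_T vectors (first = highest
#'   occupancy).
#' @return List with `global` (one `occupancy_fit` per blocking scan),
#'   `v_nd`, and `regional` (data frame of BP_ND and occupancy per region
#'   and scan, or `NULL` when unavailable).
#' @export
occupancy_analysis <- function(vt_baseline, vt_blocking) {
  stopifnot(is.list(vt_blocking), length(vt_blocking) >= 1L)
  global <- lapply(vt_blocking, function(vk) lassen(vt_baseline, vk))
  v_nd <- global[[1L]]$v_nd
  regional <- NULL
  if (!is.na(v_nd) && v_nd > 0) {
    shared <- global[[1L]]$regions_used
    bp_base <- direct_bpnd(as.numeric(vt_baseline[shared]), v_nd)
    ok <- bp_base > 0
    regional <- do.call(rbind, lapply(seq_along(vt_blocking), function(i) {
      vk <- vt_blocking[[i]]
      bp_block <- direct_bpnd(as.numeric(vk[shared]), v_nd)
      occ <- rep(NA_real_, length(shared))
      occ[ok] <- suppressWarnings(
        regional_occupancy(bp_base[ok], bp_block[ok]))
      data.frame(scan = i, region = shared, bpnd_baseline = bp_base,
                 bpnd_blocking = bp_block, occupancy_pct = occ)
    }))
  } else {
    warnf("V_ND unavailable from first blocking scan; regional BP_ND not computed")
  }
  list(global = global, v_nd = v_nd, regional = regional)
}
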