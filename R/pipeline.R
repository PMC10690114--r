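# End-to-end orchestration: simulate -> fit -> reliability/occupancy -> PK-PD
# from a single configuration (an R list or a YAML file). Every output file
# name carries a short hash of the configuration so tables from different
# runs cannot be silently mixed, and the seed threads through every
# stochastic call.

#' Validate and normalize a pipeline configuration
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `seed` (integer), `output_dir`, `stages` (ordered subset of
#'   `simulate`, `fit`, `occupancy`, `reliability`, `pkpd`, `report`),
#'   `study` (`"occupancy"` or `"trt"`), `fit_method` (`"logan"`, `"2tc"`,
#'   `"1tc"`), `t_star`, and scenario blocks `occupancy_study`
#'   (`n_subjects`, `true_occupancy`, `noise_level`, `drug_dose_mg`),
#'   `trt_study` (`n_subjects`, `noise_level`, `between_cv`) and `pkpd`
#'   (`ke0`, `ec50`, `gamma`, `doses_mg`).
#' @return The validated config with defaults filled in.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  defaults <- list(seed = 1L, output_dir = "petkin_out",
                   stages = c("simulate", "fit", "occupancy", "report"),
                   study = "occupancy", fit_method = "logan", t_star = 30)
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  known <- c("simulate", "fit", "occupancy", "reliability", "pkpd", "report")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (!config$study %in% c("occupancy", "trt")) {
    stopf("study must be 'occupancy' or 'trt'")
  }
  if (!config$fit_method %in% c("logan", "2tc", "1tc")) {
    stopf("fit_method must be one of logan, 2tc, 1tc")
  }
  config$seed <- as.integer(config$seed)
  config
}

pipeline_path <- function(config, name) {
  file.path(config$output_dir,
            sprintf("%s_%s.csv", name, attr(config, "hash")))
}

quantify_record <- function(rec, input, config) {
  vt_one <- function(tc) {
    switch(config$fit_method,
           logan = logan_vt(tc, input, t_star = config$t_star)$slope,
           "2tc" = fit_2tc(tc, input)$vt,
           "1tc" = fit_1tc(tc, input)$vt)
  }
  data.frame(subject_id = rec$subject_id, condition = rec$condition,
             region = names(rec$tacs), method = config$fit_method,
             vt = vapply(rec$tacs, vt_one, numeric(1L)), row.names = NULL)
}

#' Run the analysis pipeline from one configuration
#'
#' Stages execute in the configured order; each stage reads and writes
#' delimited tables in the output directory, so every stage is independently
#' re-runnable from files. A failure in any stage halts the run with a
#' diagnostic. Warnings raised inside stages are collected and echoed into
#' the report.
#'
#' @param config Passed to [load_config()].
#' @return Run summary: per-stage status, the output-file manifest, the
#'   config hash and seed, plus in-memory result tables.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  # the hash stamps the scientific configuration; file locations excluded
  hashed <- config[sort(setdiff(names(config), c("output_dir", "paths")))]
  attr(config, "hash") <- fnv1a_hash(hashed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  statuses <- character()
  collected_warnings <- character()
  results <- list()
  records <- NULL
  with_stage <- function(name, expr) {
    withCallingHandlers(expr, warning = function(w) {
      collected_warnings <<- c(collected_warnings,
                               sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  for (stage in config$stages) {
    if (stage == "simulate") with_stage("simulate", {
      if (config$study == "occupancy") {
        oc <- config$occupancy_study %||% list()
        scen <- occupancy_scenario(
          n_subjects = oc$n_subjects %||% 3,
          true_occupancy = unlist(oc$true_occupancy %||% c(0.85, 0.5)),
          noise_level = oc$noise_level %||% 0.02,
          drug_dose_mg = oc$drug_dose_mg %||% 600,
          seed = config$seed)
        records <- simulate_occupancy_study(scen)
      } else {
        tr <- config$trt_study %||% list()
        records <- simulate_trt_study(
          n_subjects = tr$n_subjects %||% 6,
          noise_level = tr$noise_level %||% 0.05,
          between_cv = tr$between_cv %||% 0.15,
          seed = config$seed)
      }
      for (rec in records) {
        f <- file.path(config$output_dir,
                       sprintf("tac_%s_%s_%s.csv", rec$subject_id,
                               rec$condition, attr(config, "hash")))
        write_tac_table(rec$tacs, f)
        manifest <- c(manifest, f)
        if (!is.null(rec$input_fun)) {
          f2 <- file.path(dirname(f), sub("^tac_", "aif_", basename(f)))
          utils::write.csv(data.frame(time = rec$input_fun$time,
                                      conc = rec$input_fun$conc),
                           f2, row.names = FALSE)
          manifest <- c(manifest, f2)
        }
      }
      gt <- attr(records, "ground_truth")
      if (!is.null(gt)) {
        f <- pipeline_path(config, "ground_truth")
        utils::write.csv(gt, f, row.names = FALSE)
        manifest <- c(manifest, f)
      }
      results$records <- records
    })
    if (stage == "fit") with_stage("fit", {
      if (is.null(records)) stopf("fit stage requires the simulate stage's records")
      vt_rows <- lapply(records, function(rec) {
        input <- rec$input_fun
        if (is.null(input)) {
          # second blocking scan: surrogate AIF from the two measured scans
          base <- Find(function(r) r$subject_id == rec$subject_id &&
                         r$condition == "baseline", records)
          b1 <- Find(function(r) r$subject_id == rec$subject_id &&
                       r$condition == "blocking_1", records)
          input <- weighted_aif(base$input_fun, b1$input_fun,
                                base$injected_dose, b1$injected_dose,
                                rec$injected_dose)
        }
        quantify_record(rec, input, config)
      })
      results$vt <- do.call(rbind, vt_rows)
      f <- pipeline_path(config, "vt")
      utils::write.csv(results$vt, f, row.names = FALSE)
      manifest <- c(manifest, f)
    })
    if (stage == "occupancy") with_stage("occupancy", {
      vt <- results$vt
      if (is.null(vt)) stopf("occupancy stage requires the fit stage's V_T table")
      subjects <- unique(vt$subject_id)
      occ_rows <- lapply(subjects, function(sid) {
        sv <- vt[vt$subject_id == sid, ]
        pick <- function(cond) {
          stats::setNames(sv$vt[sv$condition == cond],
                          sv$region[sv$condition == cond])
        }
        ana <- occupancy_analysis(pick("baseline"),
                                  list(pick("blocking_1"),
                                       pick("blocking_2")))
        data.frame(subject_id = sid,
                   condition = c("blocking_1", "blocking_2"),
                   occupancy_pct = 100 * vapply(ana$global, function(g)
                     g$occupancy, numeric(1L)),
                   v_nd = vapply(ana$global, function(g) g$v_nd %||% NA_real_,
                                 numeric(1L)),
                   row.names = NULL)
      })
      results$occupancy <- do.call(rbind, occ_rows)
      f <- pipeline_path(config, "occupancy")
      utils::write.csv(results$occupancy, f, row.names = FALSE)
      manifest <- c(manifest, f)
    })
    if (stage == "reliability") with_stage("reliability", {
      vt <- results$vt
      if (is.null(vt)) stopf("reliability stage requires the fit stage's V_T table")
      wide <- merge(vt[vt$condition == "test",
                       c("subject_id", "region", "method", "vt")],
                    vt[vt$condition == "retest",
                       c("subject_id", "region", "method", "vt")],
                    by = c("subject_id", "region", "method"),
                    suffixes = c("_test", "_retest"))
      names(wide)[names(wide) == "vt_test"] <- "test"
      names(wide)[names(wide) == "vt_retest"] <- "retest"
      results$reliability <- reliability_table(wide)
      f <- pipeline_path(config, "reliability")
      utils::write.csv(results$reliability, f, row.names = FALSE)
      manifest <- c(manifest, f)
    })
    if (stage == "pkpd") with_stage("pkpd", {
      pk <- config$pkpd %||% list()
      doses <- unlist(pk$doses_mg %||% c(50, 100, 200, 300, 600, 600))
      cohort <- simulate_pkpd_cohort(
        doses_mg = doses, ke0 = pk$ke0 %||% 0.3,
        ec50 = pk$ec50 %||% 5.52, gamma = pk$gamma %||% 0.758,
        noise_sd = pk$noise_sd %||% 0, seed = config$seed)
      fit <- fit_emax_effect_site_joint(cohort)
      results$pkpd <- data.frame(ec50 = fit$ec50, gamma = fit$gamma,
                                 ke0 = fit$ke0, converged = fit$converged)
      f <- pipeline_path(config, "pkpd")
      utils::write.csv(results$pkpd, f, row.names = FALSE)
      manifest <- c(manifest, f)
    })
    if (stage == "report") {
      report <- make_report(results, config, collected_warnings)
      f <- file.path(config$output_dir,
                     sprintf("report_%s.md", attr(config, "hash")))
      writeLines(report, f)
      manifest <- c(manifest, f)
    }
    statuses[stage] <- "ok"
  }
  list(statuses = statuses, manifest = manifest,
       config_hash = attr(config, "hash"), seed = config$seed,
       results = results, warnings = collected_warnings)
}

#' Simulate a concentration-occupancy cohort under the effect-site model
#'
#' One subject per dose: an oral one-compartment plasma profile, its
#' effect-site solution under `ke0`, and occupancy observations at the peak
#' (2 h) and trough (24 h) scan times generated from the sigmoidal Emax
#' model with Emax = 100%, plus optional Gaussian noise on the occupancy
#' percent.
#'
#' @param doses_mg Oral doses, one subject each.
#' @param ke0 Effect-site equilibration rate, 1/h.
#' @param ec50 True EC50 on effect-site concentration, ng/mL.
#' @param gamma True Hill factor.
#' @param obs_times_h Occupancy observation times, hours post-dose.
#' @param noise_sd SD of additive Gaussian noise on occupancy, percent.
#' @param seed Integer seed.
#' @return List of subjects in the format [fit_emax_effect_site_joint()]
#'   expects, with the true parameters attached as attributes.
#' @export
simulate_pkpd_cohort <- function(doses_mg = c(50, 100, 200, 300, 600, 600),
                                 ke0 = 0.3, ec50 = 5.52, gamma = 0.758,
                                 obs_times_h = c(2, 24), noise_sd = 0,
                                 seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  subjects <- lapply(doses_mg, function(d) {
    prof <- simulate_pk_profile(pk_scenario(dose = d, ke0 = ke0))
    occ <- emax_occupancy(stats::approx(prof$time_h, prof$ce,
                                        xout = obs_times_h)$y, ec50, gamma)
    if (noise_sd > 0) occ <- occ + stats::rnorm(length(occ), 0, noise_sd)
    list(time_h = prof$time_h, cp = prof$cp,
         obs_time_h = obs_times_h, occupancy = occ, dose_mg = d)
  })
  attr(subjects, "truth") <- list(ke0 = ke0, ec50 = ec50, gamma = gamma)
  subjects
}

#' Render a deterministic markdown run report
#'
#' @param results Result tables from [run_pipeline()].
#' @param config The validated configuration.
#' @param warnings Character vector of warnings collected during the run.
#' @return Character vector of markdown lines.
#' @export
make_report <- function(results, config = list(), warnings = character()) {
  fmt_tab <- function(df) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) sprintf("%.4g", x))
    header <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    rows <- apply(df, 1L, paste, collapse = " | ")
    c(paste("|", header, "|"), paste("|", sep, "|"),
      paste("|", rows, "|"))
  }
  lines <- c("# Pipeline run report", "",
             sprintf("- config hash: %s", attr(config, "hash") %||% "(none)"),
             sprintf("- seed: %s", config$seed %||% "(none)"), "")
  if (!is.null(results$vt)) {
    lines <- c(lines, "## Regional V_T", "", fmt_tab(results$vt), "")
  }
  if (!is.null(results$reliability)) {
    lines <- c(lines, "## Test-retest reliability", "",
               fmt_tab(results$reliability), "")
  }
  if (!is.null(results$occupancy)) {
    lines <- c(lines, "## Lassen occupancy", "",
               fmt_tab(results$occupancy), "")
  }
  if (!is.null(results$pkpd)) {
    lines <- c(lines, "## Concentration-occupancy model", "",
               fmt_tab(results$pkpd), "")
  }
  if (length(warnings)) {
    lines <- c(lines, "## Warnings", "", paste("-", warnings), "")
  }
  lines
}
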