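# End-to-end orchestration: simulate (or load) -> build cohort -> phenotype
# -> associate -> sensitivity -> report.

#' Pipeline run configuration
#'
#' Houses every numeric constant of the analysis: LDL group thresholds,
#' the albumin exclusion rule, the discovery fraction and significance
#' level, and the module toggles.
#'
#' @param seed integer seed used for simulation and the phase split
#' @param input_dir directory with `patients.csv`, `labs.csv`, `codes.csv`,
#'   `meds.csv`; when `NULL` the population is simulated from `sim`
#' @param sim a [sim_config()] (its seed is overridden by `seed`)
#' @param out_dir directory for artifacts; `NULL` writes nothing
#' @param thresholds a [ldl_thresholds()] list
#' @param albumin_threshold g/dl (values below open an exclusion window)
#' @param albumin_window_days half-width of the albumin window
#' @param tg_filter flag Friedewald records with triglycerides > 400 mg/dl
#' @param discovery_fraction fraction of included patients screened in
#'   phase 1
#' @param alpha two-sided significance level
#' @param continuity_correction use Haldane-Anscombe correction in the 2x2
#'   odds ratio
#' @param substitute_433_91 swap 334.9 for 433.91 in the stroke sensitivity
#'   list
#' @param force_validation run phase 2 even when the discovery gate fails
#' @param phecode_map_file,phecode_exclude_file optional external phecode
#'   map CSVs (defaults: the bundled miniature map)
#' @return a list of class `run_config`
#' @export
run_config <- function(seed = 1L, input_dir = NULL, sim = sim_config(),
                       out_dir = NULL, thresholds = ldl_thresholds(),
                       albumin_threshold = 3, albumin_window_days = 30,
                       tg_filter = TRUE, discovery_fraction = 1 / 3,
                       alpha = 0.05, continuity_correction = FALSE,
                       substitute_433_91 = FALSE, force_validation = FALSE,
                       phecode_map_file = NULL,
                       phecode_exclude_file = NULL) {
  check_number(albumin_threshold, "albumin_threshold")
  check_number(albumin_window_days, "albumin_window_days")
  if (!is.numeric(discovery_fraction) || discovery_fraction <= 0 ||
      discovery_fraction >= 1)
    config_error("discovery_fraction", "must lie strictly in (0, 1)")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    config_error("alpha", "must lie strictly in (0, 1)")
  sim$seed <- seed
  cfg <- list(seed = as.integer(seed), input_dir = input_dir, sim = sim,
              out_dir = out_dir, thresholds = thresholds,
              albumin_threshold = albumin_threshold,
              albumin_window_days = albumin_window_days,
              tg_filter = isTRUE(tg_filter),
              discovery_fraction = discovery_fraction, alpha = alpha,
              continuity_correction = isTRUE(continuity_correction),
              substitute_433_91 = isTRUE(substitute_433_91),
              force_validation = isTRUE(force_validation),
              phecode_map_file = phecode_map_file,
              phecode_exclude_file = phecode_exclude_file)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `sim` and
#' `thresholds` may be nested maps of the corresponding constructor
#' arguments. A `seed` argument overrides the file.
#'
#' @param path YAML file
#' @param seed optional seed override
#' @return a `run_config` object
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$thresholds))
    y$thresholds <- do.call(ldl_thresholds, y$thresholds)
  if (!is.null(seed)) y$seed <- as.integer(seed)
  do.call(run_config, y)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

write_artifact_csv <- function(dt, path, hash) {
  writeLines(sprintf("# config_hash: %s", hash), path)
  fwrite(dt, path, append = TRUE, col.names = TRUE)
}

#' Run the full two-phase analysis pipeline
#'
#' Executes simulate/load, per-measurement LDL filtering, group assignment,
#' the seeded discovery/validation split, the phase 1 phecode screen with
#' its Bonferroni gate, and — when the gate passes (or `force_validation`
#' is set) — the phase 2 analysis: the algorithmic T2DM classification, the
#' 2x2 contingency odds ratio, the three prespecified adjusted logistic
#' models, stratified analyses, interaction tests, and the sensitivity
#' suite. Every artifact carries a hash of the run configuration; a rerun
#' with the same configuration reproduces the report byte for byte.
#'
#' @param config a [run_config()] object
#' @return the report: a nested list of all counts and results (also
#'   written to `out_dir` when configured)
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  # the hash captures everything that shapes the results; the output
  # location does not, so reruns into different directories match bytewise
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])

  if (is.null(config$input_dir)) {
    pop <- generate_population(config$sim)
    stage_log("simulate", "generated %d patients (%d lab rows, %d codes)",
              nrow(pop$patients), nrow(pop$labs), nrow(pop$codes))
  } else {
    pop <- read_population(config$input_dir)
    stage_log("load", "read %d patients from %s", nrow(pop$patients),
              config$input_dir)
  }
  validate_tables(pop)

  ldl_records <- filter_ldl_measurements(
    pop$labs, pop$codes, pop$meds, pop$patients,
    albumin_threshold = config$albumin_threshold,
    albumin_window_days = config$albumin_window_days,
    tg_filter = config$tg_filter)
  stage_log("build-cohort", "%d LDL determinations, %d eligible",
            nrow(ldl_records), sum(!ldl_records$excluded))

  cohort <- assign_groups(ldl_records, config$thresholds)
  cohort <- split_phases(cohort, config$seed, config$discovery_fraction)
  attrition <- attrition_report(ldl_records, cohort)
  stage_log("build-cohort", "groups: low %d, normal %d, excluded %d",
            sum(cohort$group == "low"), sum(cohort$group == "normal"),
            sum(cohort$group == "excluded"))

  covariates <- derive_covariates(pop$patients, pop$labs, pop$codes,
                                  pop$meds)
  phecode_map <- load_phecode_map(config$phecode_map_file,
                                  config$phecode_exclude_file)

  disc <- discovery_screen(cohort, pop$codes, covariates, phecode_map,
                           alpha = config$alpha)
  stage_log("phenotype", "discovery screen: min p = %.3g, gate %s",
            suppressWarnings(min(disc$results$p_value, na.rm = TRUE)),
            if (disc$gate) "passed" else "FAILED")

  report <- list(
    config_hash = hash, seed = config$seed,
    n_patients = nrow(pop$patients),
    attrition = attrition,
    discovery = list(threshold = disc$threshold, gate = disc$gate,
                     results = disc$results),
    gate_stop = FALSE
  )

  if (!disc$gate && !config$force_validation) {
    report$gate_stop <- TRUE
    stage_log("associate", "discovery gate failed: stopping before phase 2")
    write_report(report, cohort, ldl_records, NULL, covariates, config,
                 hash)
    return(invisible(report))
  }

  vali <- cohort[phase == "validation"]
  calls <- t2dm_algorithm(pop$codes, pop$labs, pop$meds,
                          patient_ids = vali$patient_id)
  adata <- build_analysis_data(vali, calls, covariates)
  a <- sum(adata$exposure == 1L & adata$outcome == 1L)
  b <- sum(adata$exposure == 1L & adata$outcome == 0L)
  cc <- sum(adata$exposure == 0L & adata$outcome == 1L)
  d <- sum(adata$exposure == 0L & adata$outcome == 0L)
  stage_log("associate",
            "validation 2x2: %d/%d exposed, %d/%d unexposed cases/controls",
            a, b, cc, d)

  contingency <- tryCatch(
    odds_ratio_woolf(a, b, cc, d, alpha = config$alpha,
                     continuity = config$continuity_correction),
    error = function(e) empty_result_row("woolf_2x2",
                                         note = conditionMessage(e)))
  primary <- rbindlist(list(
    fit_or_flag(adata, adjustment_set("unadjusted"), "primary_unadjusted",
                config$alpha),
    fit_or_flag(adata, adjustment_set("demographic"),
                "primary_demographic", config$alpha),
    fit_or_flag(adata, adjustment_set("full"), "primary_full",
                config$alpha)))
  strata <- stratified_analysis(adata, alpha = config$alpha)
  interactions <- rbindlist(lapply(
    c("sex", "race", "bmi_category"), function(v) {
      res <- tryCatch(interaction_test(adata, v), error = function(e)
        list(variable = v, statistic = NA_real_, df = NA_integer_,
             p_value = NA_real_, n_total = NA_integer_))
      data.table(variable = res$variable, statistic = res$statistic,
                 df = res$df, p_value = res$p_value,
                 n_total = res$n_total %||% NA_integer_)
    }))
  sensitivity <- sensitivity_suite(
    adata, ldl_records, pop$codes, pop$labs, pop$meds, pop$patients,
    phecode_map, window_days = config$albumin_window_days,
    substitute_433_91 = config$substitute_433_91, alpha = config$alpha)
  stage_log("sensitivity", "%d sensitivity fits", nrow(sensitivity))

  report$validation <- list(
    table_2x2 = list(a = a, b = b, c = cc, d = d),
    contingency = contingency, primary = primary, strata = strata,
    interactions = interactions, sensitivity = sensitivity,
    n_cases = a + cc, n_controls = b + d, n_analytic = a + b + cc + d,
    n_validation_low = nrow(vali[group == "low"]),
    n_validation_normal = nrow(vali[group == "normal"]),
    # prevalences as conventionally printed: cases over the whole phase
    # group, including patients on whom the algorithm abstained
    prevalence_low_pct = 100 * a / max(nrow(vali[group == "low"]), 1),
    prevalence_normal_pct = 100 * cc / max(nrow(vali[group == "normal"]), 1)
  )
  write_report(report, cohort, ldl_records, adata, covariates, config,
               hash)
  invisible(report)
}

fit_or_flag <- function(adata, adjust, label, alpha) {
  tryCatch(fit_logistic(adata, adjust = adjust, alpha = alpha,
                        label = label),
           error = function(e) empty_result_row(label,
                                                note = conditionMessage(e)))
}

write_report <- function(report, cohort, ldl_records, adata, covariates,
                         config, hash) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_artifact_csv(cohort, file.path(config$out_dir, "cohort.csv"), hash)
  write_artifact_csv(ldl_records,
                     file.path(config$out_dir, "ldl_records.csv"), hash)
  write_artifact_csv(covariates,
                     file.path(config$out_dir, "covariates.csv"), hash)
  results <- rbindlist(c(
    list(report$discovery$results[, !"phenotype_id"]),
    if (!is.null(report$validation))
      list(report$validation$contingency, report$validation$primary,
           report$validation$strata,
           report$validation$sensitivity[, !"n_dropped"])),
    use.names = TRUE, fill = TRUE)
  write_artifact_csv(results, file.path(config$out_dir, "results.csv"),
                     hash)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(NULL)
}
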