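# Monte-Carlo harnesses: parameter recovery of the exposure odds ratio and
# type-I calibration of the interaction test on synthetic populations with
# known truth.

#' Estimate the exposure odds ratio on one synthetic population
#'
#' Generates a population with a known true low-vs-normal log odds ratio,
#' runs the cohort-construction and phenotyping stages, and fits the
#' requested logistic model of algorithmic T2DM status on the derived LDL
#' group. The whole included cohort is analysed (no phase split), since the
#' goal is recovery of the generating parameter, not the two-phase design.
#'
#' @param n_patients population size
#' @param seed simulation seed
#' @param true_or true odds ratio of the low group (natural scale)
#' @param adjustment an [adjustment_set()] name
#' @param contamination passed to [sim_config()]
#' @param sim_args extra [sim_config()] arguments
#' @return one-row data.table: fit result plus `true_or` and `covers`
#'   (does the CI cover the truth?)
#' @export
recover_exposure_or <- function(n_patients = 20000, seed = 1,
                                true_or = 2, adjustment = "full",
                                contamination = NULL, sim_args = list()) {
  cfg <- do.call(sim_config, c(list(
    n_patients = n_patients, seed = seed,
    true_log_or_low_ldl = log(true_or),
    contamination = contamination), sim_args))
  pop <- generate_population(cfg)
  ldl <- filter_ldl_measurements(pop$labs, pop$codes, pop$meds,
                                 pop$patients)
  cohort <- assign_groups(ldl)
  covars <- derive_covariates(pop$patients, pop$labs, pop$codes, pop$meds)
  inc <- cohort[group %in% c("low", "normal")]
  calls <- t2dm_algorithm(pop$codes, pop$labs, pop$meds,
                          patient_ids = inc$patient_id)
  adata <- build_analysis_data(inc, calls, covars)
  row <- fit_logistic(adata, adjust = adjustment_set(adjustment),
                      label = paste0("recovery_", adjustment))
  row[, true_or := true_or]
  row[, covers := converged & ci_low <= true_or & ci_high >= true_or]
  row[]
}

#' Coverage study of the adjusted exposure odds ratio
#'
#' Repeats [recover_exposure_or()] over consecutive seeds and tallies how
#' often the Wald 95% CI covers the generating odds ratio. With a
#' correctly specified model the count should fall in the usual binomial
#' band around the nominal 95%.
#'
#' @param n_seeds number of replicates
#' @param n_patients population size per replicate
#' @param true_or generating odds ratio
#' @param base_seed seed of the first replicate (replicate i uses
#'   `base_seed + i - 1`)
#' @param adjustment an [adjustment_set()] name
#' @param contamination passed to [sim_config()]
#' @return data.table of per-replicate results, with attribute `n_covered`
#' @export
or_recovery_study <- function(n_seeds = 100, n_patients = 20000,
                              true_or = 2, base_seed = 1,
                              adjustment = "full", contamination = NULL) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    r <- recover_exposure_or(n_patients, seed = base_seed + i - 1,
                             true_or = true_or, adjustment = adjustment,
                             contamination = contamination)
    r[, seed := base_seed + i - 1]
    r
  })
  out <- rbindlist(rows)
  setattr(out, "n_covered", sum(out$covers, na.rm = TRUE))
  out[]
}

#' Type-I calibration of the interaction test
#'
#' The generator places no interaction between the exposure and any
#' covariate on the logit scale, so the Wald interaction p-value should be
#' approximately uniform; this harness returns the p-values over replicate
#' simulations so the rejection rate at a given level can be checked.
#'
#' @param n_seeds number of replicates
#' @param n_patients population size per replicate
#' @param variable interaction variable (see [interaction_test()])
#' @param base_seed seed of the first replicate
#' @param true_or generating exposure odds ratio
#' @return numeric vector of p-values (NA where a replicate failed)
#' @export
interaction_calibration <- function(n_seeds = 200, n_patients = 3000,
                                    variable = "sex", base_seed = 1,
                                    true_or = 2) {
  vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(n_patients = n_patients, seed = base_seed + i - 1,
                      true_log_or_low_ldl = log(true_or))
    pop <- generate_population(cfg)
    ldl <- filter_ldl_measurements(pop$labs, pop$codes, pop$meds,
                                   pop$patients)
    cohort <- assign_groups(ldl)
    covars <- derive_covariates(pop$patients, pop$labs, pop$codes,
                                pop$meds)
    inc <- cohort[group %in% c("low", "normal")]
    calls <- t2dm_algorithm(pop$codes, pop$labs, pop$meds,
                            patient_ids = inc$patient_id)
    adata <- build_analysis_data(inc, calls, covars)
    tryCatch(interaction_test(adata, variable)$p_value,
             error = function(e) NA_real_)
  }, numeric(1))
}
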