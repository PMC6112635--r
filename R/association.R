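# Association analysis: 2x2 contingency odds ratios, adjusted logistic
# regression, the phase 1 discovery screen with its Bonferroni gate, and
# the phase 2 stratified / interaction / sensitivity analyses.

#' The six type 2 diabetes phecodes screened in the discovery phase
#' @export
T2DM_PHECODES <- c("250.2", "250.21", "250.22", "250.23", "250.24", "250.25")

#' Named adjustment sets for the logistic models
#'
#' `unadjusted` is empty; `demographic` adjusts for age, race, sex, and BMI;
#' `full` additionally adjusts for EHR length and median HDL-C and
#' triglyceride concentrations. `phase1` (age, race, sex) is the discovery
#' screen's set.
#'
#' @param name one of "unadjusted", "phase1", "demographic", "full"
#' @return character vector of covariate column names
#' @export
adjustment_set <- function(name = c("unadjusted", "phase1", "demographic",
                                    "full")) {
  name <- match.arg(name)
  switch(name,
         unadjusted = character(),
         phase1 = c("age_years", "race", "sex"),
         demographic = c("age_years", "race", "sex", "bmi_median"),
         full = c("age_years", "race", "sex", "bmi_median",
                  "ehr_length_years", "hdl_median", "tg_median"))
}

empty_result_row <- function(model, stratum = NA_character_,
                             note = NA_character_) {
  data.table(model = model, stratum = stratum, or_estimate = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
             n_cases = NA_integer_, n_controls = NA_integer_,
             n_total = NA_integer_, converged = FALSE, note = note)
}

#' Woolf odds ratio for a 2x2 contingency table
#'
#' OR = (a d) / (b c) with a normal-approximation (Woolf) confidence
#' interval on the log scale, variance 1/a + 1/b + 1/c + 1/d, and a
#' two-sided p-value from the normal approximation on log OR.
#'
#' @param a exposed cases
#' @param b exposed controls
#' @param c unexposed cases
#' @param d unexposed controls
#' @param alpha two-sided significance level (default 0.05 for a 95% CI)
#' @param continuity add 0.5 to every cell (Haldane-Anscombe); off by
#'   default, required to handle zero cells
#' @return one-row data.table: `model`, `or_estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `n_cases`, `n_controls`, `n_total`, `converged`
#' @export
#' @examples
#' odds_ratio_woolf(518, 2896, 2968, 26657)
odds_ratio_woolf <- function(a, b, c, d, alpha = 0.05, continuity = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("cell counts must be finite and non-negative", call. = FALSE)
  if (any(cells == 0) && !continuity)
    stop(paste("zero cell in 2x2 table: the odds ratio is undefined;",
               "consider continuity = TRUE (adds 0.5 to each cell)"),
         call. = FALSE)
  if (continuity) cells <- cells + 0.5
  lor <- log(cells[["a"]]) + log(cells[["d"]]) -
    log(cells[["b"]]) - log(cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - alpha / 2)
  data.table(model = "woolf_2x2", stratum = NA_character_,
             or_estimate = exp(lor),
             ci_low = exp(lor - z * se), ci_high = exp(lor + z * se),
             p_value = 2 * pnorm(-abs(lor / se)),
             n_cases = as.integer(a + c), n_controls = as.integer(b + d),
             n_total = as.integer(a + b + c + d),
             converged = TRUE, note = NA_character_)
}

#' Expand a 2x2 table into one row per individual
#'
#' @param a,b,c,d cell counts (exposed cases, exposed controls, unexposed
#'   cases, unexposed controls)
#' @return data.table with binary `outcome` and `exposure` columns
#' @export
expand_2x2 <- function(a, b, c, d) {
  data.table(
    outcome = rep(c(1L, 0L, 1L, 0L), c(a, b, c, d)),
    exposure = rep(c(1L, 1L, 0L, 0L), c(a, b, c, d))
  )
}

#' Maximum-likelihood logistic regression for an exposure odds ratio
#'
#' Fits the binomial logit model by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 50 iterations) on the complete
#' cases of the requested columns, and reports the exposure coefficient as
#' an odds ratio with a Wald confidence interval and p-value from the
#' inverse observed information. Detected complete separation or
#' non-convergence yields a flagged row (`converged = FALSE`) with no
#' estimates; a single-class outcome is an error.
#'
#' @param data data.frame with the outcome, exposure, and covariate columns
#' @param outcome,exposure column names; the outcome must be binary 0/1 and
#'   the exposure binary or two-level
#' @param adjust character vector of covariate column names (see
#'   [adjustment_set()])
#' @param alpha two-sided level for the Wald CI
#' @param label model label recorded in the result
#' @param stratum optional stratum label recorded in the result
#' @return one-row data.table in the [odds_ratio_woolf()] layout
#' @export
fit_logistic <- function(data, outcome = "outcome", exposure = "exposure",
                         adjust = character(), alpha = 0.05,
                         label = "logistic", stratum = NA_character_) {
  data <- as.data.table(data)
  cols <- c(outcome, exposure, adjust)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  dd <- data[, ..cols]
  dd <- dd[complete.cases(dd)]
  y <- dd[[outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: only one class present (complete separation)",
         call. = FALSE)
  n_par <- length(cols)
  if (nrow(dd) < 10L * n_par)
    warning(sprintf("only %d complete cases for %d parameters",
                    nrow(dd), n_par))
  # stable factor codings: reference female / European ancestry
  if ("sex" %in% names(dd))
    dd[, sex := factor(sex, levels = c("female", "male"))]
  if ("race" %in% names(dd))
    dd[, race := factor(race, levels = c("european_ancestry",
                                         "african_ancestry", "other"))]
  dd <- droplevels(dd)
  # covariates constant in this (possibly stratified) sample carry no
  # information and break factor contrasts; drop them from the fit
  constant <- vapply(adjust, function(cl) length(unique(dd[[cl]])) < 2L,
                     logical(1))
  adjust <- adjust[!constant]

  fml <- stats::reformulate(c(exposure, adjust), response = outcome)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dd,
        control = list(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- coef(fit)
  exp_name <- if (exposure %in% names(co)) exposure else
    grep(paste0("^", exposure), names(co), value = TRUE)[1]
  beta <- unname(co[exp_name])
  if (!fit$converged || sep_warn || is.na(beta) || abs(beta) > 15) {
    return(empty_result_row(label, stratum,
                            note = "non-convergence or complete separation"))
  }
  se <- sqrt(vcov(fit)[exp_name, exp_name])
  z <- qnorm(1 - alpha / 2)
  data.table(model = label, stratum = stratum,
             or_estimate = exp(beta),
             ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
             p_value = 2 * pnorm(-abs(beta / se)),
             n_cases = as.integer(sum(y == 1)),
             n_controls = as.integer(sum(y == 0)),
             n_total = as.integer(nrow(dd)),
             converged = TRUE, note = NA_character_)
}

#' Assemble the per-patient analysis table
#'
#' Joins cohort assignments, phenotype calls, and covariates into one row
#' per patient with a binary `exposure` (low = 1, normal = 0) and binary
#' `outcome` (case = 1, control = 0); phenotype-excluded patients are
#' dropped.
#'
#' @param cohort [assign_groups()]/[split_phases()] output
#' @param calls phenotype calls (one phenotype)
#' @param covariates [derive_covariates()] output
#' @return data.table ready for [fit_logistic()]
#' @export
build_analysis_data <- function(cohort, calls, covariates) {
  cohort <- as_dt(cohort); calls <- as.data.table(calls)
  covariates <- as.data.table(covariates)
  dd <- merge(cohort[group %in% c("low", "normal")],
              calls[status %in% c("case", "control"),
                    .(patient_id, status)], by = "patient_id")
  dd <- merge(dd, covariates, by = "patient_id", all.x = TRUE)
  dd[, exposure := as.integer(group == "low")]
  dd[, outcome := as.integer(status == "case")]
  dd[]
}

#' Phase 1 discovery screen over the six diabetes phecodes
#'
#' Fits the age/race/sex-adjusted logistic model of each phecode's
#' case/control status on the low-vs-normal exposure among discovery-phase
#' patients, applies the Bonferroni threshold alpha / 6, and reports the
#' gate decision: proceed to validation only if at least one phecode is
#' significant.
#'
#' @param cohort cohort assignments with phases
#' @param codes ICD-9 code events
#' @param covariates [derive_covariates()] output
#' @param phecode_map a [load_phecode_map()] object
#' @param alpha family-wise level before Bonferroni division (default 0.05)
#' @return list: `results` (six-row data.table), `threshold`, `gate`
#' @export
discovery_screen <- function(cohort, codes, covariates, phecode_map,
                             alpha = 0.05) {
  cohort <- as_dt(cohort)
  disc <- cohort[phase == "discovery"]
  if (nrow(disc) == 0L) stop("no discovery-phase patients", call. = FALSE)
  threshold <- alpha / length(T2DM_PHECODES)
  rows <- lapply(T2DM_PHECODES, function(pc) {
    calls <- assign_phecode_status(codes, phecode_map, pc,
                                   patient_ids = disc$patient_id)
    dd <- build_analysis_data(disc, calls, covariates)
    if (sum(dd$outcome == 1L) == 0L)
      return(empty_result_row(paste0("phecode_", pc),
                              note = "zero cases"))
    tryCatch(
      fit_logistic(dd, adjust = adjustment_set("phase1"),
                   label = paste0("phecode_", pc)),
      error = function(e) empty_result_row(paste0("phecode_", pc),
                                           note = conditionMessage(e)))
  })
  results <- rbindlist(rows)
  results[, phenotype_id := T2DM_PHECODES]
  pmin_ok <- suppressWarnings(min(results$p_value, na.rm = TRUE))
  list(results = results[], threshold = threshold,
       gate = is.finite(pmin_ok) && pmin_ok < threshold)
}

#' WHO body-mass-index category
#'
#' Boundaries: normal 18.5 to <25, overweight 25 to <30 (25.0 is
#' overweight), obese 30 or more (30.0 is obese); below 18.5 is
#' underweight.
#'
#' @param bmi numeric vector, kg/m^2
#' @return character vector of categories (NA stays NA)
#' @export
bmi_category <- function(bmi) {
  fcase(is.na(bmi), NA_character_,
        bmi < 18.5, "underweight",
        bmi < 25, "normal",
        bmi < 30, "overweight",
        default = "obese")
}

#' Prespecified stratified analyses of the validation cohort
#'
#' Refits the fully adjusted model within strata of sex (female, male),
#' race (European, African ancestry), BMI category (normal, overweight,
#' obese; underweight excluded from the BMI strata), and within an exposure
#' refinement that splits the low group at a median LDL-C of 40 mg/dl
#' (`<40` strict; `40-60` inclusive at both ends), each compared to the
#' whole normal group. The stratifying variable is removed from that
#' stratum's adjustment set.
#'
#' @param adata analysis table from [build_analysis_data()]
#' @param alpha two-sided level for Wald CIs
#' @return data.table of per-stratum results
#' @export
stratified_analysis <- function(adata, alpha = 0.05) {
  adata <- copy(as.data.table(adata))
  full <- adjustment_set("full")
  fit_stratum <- function(dd, label, adjust) {
    if (nrow(dd) == 0L || length(unique(dd$outcome)) < 2L)
      return(empty_result_row("stratified", label,
                              note = "stratum with <2 outcome classes"))
    tryCatch(
      fit_logistic(dd, adjust = adjust, alpha = alpha,
                   label = "stratified", stratum = label),
      error = function(e) empty_result_row("stratified", label,
                                           note = conditionMessage(e)))
  }
  rows <- list()
  for (s in c("female", "male"))
    rows[[paste0("sex_", s)]] <-
      fit_stratum(adata[sex == s], paste0("sex:", s), setdiff(full, "sex"))
  for (r in c("european_ancestry", "african_ancestry"))
    rows[[paste0("race_", r)]] <-
      fit_stratum(adata[race == r], paste0("race:", r),
                  setdiff(full, "race"))
  adata[, bmi_cat := bmi_category(bmi_median)]
  for (bc in c("normal", "overweight", "obese"))
    rows[[paste0("bmi_", bc)]] <-
      fit_stratum(adata[bmi_cat == bc], paste0("bmi:", bc),
                  setdiff(full, "bmi_median"))
  # exposure refinement: each low sub-stratum vs the whole normal group
  rows[["ldl_lt40"]] <- fit_stratum(
    adata[exposure == 0L | (exposure == 1L & median_ldl < 40)],
    "ldl:<40", full)
  rows[["ldl_40_60"]] <- fit_stratum(
    adata[exposure == 0L |
            (exposure == 1L & median_ldl >= 40 & median_ldl <= 60)],
    "ldl:40-60", full)
  rbindlist(rows)
}

#' Interaction between the exposure and a covariate
#'
#' Adds exposure-by-variable product term(s) to the fully adjusted model and
#' performs a Wald test on them (a chi-square test with as many degrees of
#' freedom as product terms, so multi-level factors are tested jointly).
#'
#' @param adata analysis table from [build_analysis_data()]
#' @param variable one of "sex", "race", "bmi_category"
#' @return list: `p_value`, `statistic`, `df`, `terms`, `variable`
#' @export
interaction_test <- function(adata, variable = c("sex", "race",
                                                 "bmi_category")) {
  variable <- match.arg(variable)
  adata <- copy(as.data.table(adata))
  if (variable == "bmi_category") {
    adata[, bmi_category := factor(bmi_category(bmi_median),
                                   levels = c("normal", "overweight",
                                              "obese"))]
    adata <- adata[!is.na(bmi_category)]
    vcol <- "bmi_category"
  } else vcol <- variable
  full <- adjustment_set("full")
  adjust <- setdiff(full, c(vcol, if (vcol == "bmi_category") "bmi_median"))
  cols <- c("outcome", "exposure", vcol, adjust)
  dd <- adata[, ..cols]
  dd <- dd[complete.cases(dd)]
  if ("sex" %in% names(dd))
    dd[, sex := factor(sex, levels = c("female", "male"))]
  if ("race" %in% names(dd))
    dd[, race := factor(race, levels = c("european_ancestry",
                                         "african_ancestry", "other"))]
  dd <- droplevels(dd)
  if (length(unique(dd[[vcol]])) < 2L)
    stop(sprintf("variable '%s' has a single level", variable),
         call. = FALSE)
  adjust <- adjust[vapply(adjust,
                          function(cl) length(unique(dd[[cl]])) >= 2L,
                          logical(1))]
  if (length(unique(dd$outcome)) < 2L)
    stop("degenerate outcome: only one class present", call. = FALSE)
  fml <- stats::reformulate(c("exposure", vcol, adjust,
                              paste0("exposure:", vcol)),
                            response = "outcome")
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dd,
                              control = list(epsilon = 1e-8, maxit = 50)))
  if (!fit$converged)
    stop("interaction model did not converge", call. = FALSE)
  co <- coef(fit)
  terms <- grep("^exposure:", names(co), value = TRUE)
  b <- co[terms]
  keep_t <- terms[!is.na(b)]
  if (!length(keep_t))
    stop("interaction term(s) inestimable", call. = FALSE)
  b <- co[keep_t]
  V <- vcov(fit)[keep_t, keep_t, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V) %*% b)
  df <- length(keep_t)
  list(variable = variable, statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), terms = keep_t,
       n_total = nrow(dd))
}

#' Sensitivity analyses of the validation result
#'
#' Re-runs the fully adjusted primary model after each restriction:
#' \itemize{
#' \item (1) at least 2 eligible LDL-C measurements;
#' \item (2a) no code mapping to phecode group 250.* or 411.* dated up to 30
#'   days after the patient's first eligible LDL-C measurement (a potential
#'   pre-existing indication for statin therapy);
#' \item (2b) additionally no advanced renal disease (phecode 585.31 /
#'   585.32 / 585.34 or any eGFR of 29 ml/min or less in the same window)
#'   and no transplant code (V42.0/.1/.2/.5/.6/.7/.81/.82);
#' \item (2c) additionally no stroke / transient cerebral ischemia /
#'   peripheral vascular disease code (434.91, 334.9, 435, 435.8, 435.9);
#' \item (3) no ezetimibe mention ever;
#' \item (4) age 18 or older at the median-LDL date.
#' }
#' Filters 2a-2c are cumulative by construction, so their cohorts nest.
#' The listed code 334.9 can be swapped for 433.91 with
#' `substitute_433_91 = TRUE`.
#'
#' @param adata analysis table from [build_analysis_data()]
#' @param ldl_records [filter_ldl_measurements()] output (for first
#'   eligible LDL dates)
#' @param codes,labs,meds,patients input tables
#' @param phecode_map a [load_phecode_map()] object
#' @param window_days look-back tolerance after the first eligible LDL-C
#' @param substitute_433_91 replace 334.9 by 433.91 in the stroke list
#' @param alpha two-sided level
#' @return data.table with one row per filter (`stratum` = filter label)
#'   plus an `n_dropped` column
#' @export
sensitivity_suite <- function(adata, ldl_records, codes, labs, meds,
                              patients, phecode_map, window_days = 30,
                              substitute_433_91 = FALSE, alpha = 0.05) {
  adata <- as.data.table(adata)
  codes <- as_dt(codes); labs <- as_dt(labs); meds <- as_dt(meds)
  patients <- as_dt(patients)
  ldl_records <- as_dt(ldl_records)
  full <- adjustment_set("full")

  first_ldl <- ldl_records[excluded == FALSE,
                           .(first_qualified_ldl = min(date)),
                           by = patient_id]
  win <- merge(adata[, .(patient_id)], first_ldl, by = "patient_id")

  mapped <- merge(codes, phecode_map$map, by = "icd9",
                  allow.cartesian = TRUE)
  in_window <- function(events) {
    # events: patient_id + date; TRUE rows dated <= first eligible LDL + window
    ev <- merge(events, win, by = "patient_id")
    unique(ev[date <= first_qualified_ldl + window_days, patient_id])
  }

  statin_ind <- in_window(mapped[startsWith(phecode, "250.") |
                                   phecode %chin% c("250.1", "250.2") |
                                   startsWith(phecode, "411.") |
                                   phecode == "411",
                                 .(patient_id, date)])
  renal_pc <- in_window(mapped[phecode %chin% c("585.31", "585.32", "585.34"),
                               .(patient_id, date)])
  renal_lab <- in_window(labs[lab_type == "egfr" & value <= 29,
                              .(patient_id, date)])
  transplant <- in_window(codes[icd9 %chin% c("V42.0", "V42.1", "V42.2",
                                              "V42.5", "V42.6", "V42.7",
                                              "V42.81", "V42.82"),
                                .(patient_id, date)])
  stroke_codes <- c("434.91", if (substitute_433_91) "433.91" else "334.9",
                    "435", "435.8", "435.9")
  stroke <- in_window(codes[icd9 %chin% stroke_codes, .(patient_id, date)])

  ez_ever <- unique(meds[drug_class == "ezetimibe", patient_id])
  age_at_med <- merge(as_dt(adata[, .(patient_id, median_ldl_date)]),
                      patients[, .(patient_id, birth_date)],
                      by = "patient_id")
  under18 <- age_at_med[
    as.numeric(median_ldl_date - birth_date) / DAYS_PER_YEAR < 18,
    patient_id]

  drop_2a <- statin_ind
  drop_2b <- union(drop_2a, c(renal_pc, renal_lab, transplant))
  drop_2c <- union(drop_2b, stroke)
  filters <- list(
    "1_min2_ldl" = adata$patient_id[adata$n_ldl < 2],
    "2a_no_statin_indication" = drop_2a,
    "2b_no_renal_transplant" = drop_2b,
    "2c_no_stroke_pvd" = drop_2c,
    "3_no_ezetimibe" = ez_ever,
    "4_adults_only" = under18
  )
  rows <- lapply(names(filters), function(fl) {
    dd <- adata[!patient_id %chin% filters[[fl]]]
    n_dropped <- nrow(adata) - nrow(dd)
    row <- if (nrow(dd) == 0L || length(unique(dd$outcome)) < 2L) {
      empty_result_row("sensitivity", fl, note = "empty or degenerate cohort")
    } else {
      tryCatch(
        fit_logistic(dd, adjust = full, alpha = alpha,
                     label = "sensitivity", stratum = fl),
        error = function(e) empty_result_row("sensitivity", fl,
                                             note = conditionMessage(e)))
    }
    row[, n_dropped := n_dropped]
    row
  })
  out <- rbindlist(rows)
  # per-filter identities of the dropped patients (restricted to the
  # analysis table), for attrition reporting and testing
  setattr(out, "dropped",
          lapply(filters, function(ids)
            intersect(adata$patient_id, ids)))
  out[]
}
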