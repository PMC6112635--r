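# Synthetic EHR generator
#
# Emulates a de-identified hospital EHR extract: longitudinal lipid panels,
# supporting labs (albumin, eGFR, glucose, HbA1c, BMI), ICD-9 code streams,
# and structured medication mentions, with a latent type 2 diabetes (T2DM)
# liability whose log-odds depends on LDL group, age, sex, race, and BMI.
# The exposure effect (low vs normal LDL group) is a configurable log odds
# ratio so the downstream pipeline can be tested for parameter recovery.

#' Simulation configuration for the synthetic EHR generator
#'
#' Builds a validated configuration object. The defaults define the study
#' conditions the generator emulates: lipid, BMI, age, and record-length
#' distributions calibrated to the demographic table of a large
#' medical-center cohort (low-group median derived LDL-C near 52 mg/dl,
#' normal-group near 109 mg/dl, median EHR length near 6.6 years), a low-LDL
#' group fraction matching the observed 8,943 / 80,286 split, and a true
#' exposure odds ratio of 2 for T2DM.
#'
#' @param n_patients number of patients to simulate (>= 0)
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   tables
#' @param true_log_or_low_ldl natural-log odds ratio of T2DM for the low vs
#'   normal LDL group
#' @param baseline_t2dm_logit intercept of the T2DM liability on the logit
#'   scale (applies to a female, European-ancestry patient at age 0 and
#'   BMI 0; covariate effects act on raw scales)
#' @param covariate_effects named numeric vector of log-odds coefficients:
#'   `age` (per year), `male`, `african_ancestry`, `bmi` (per kg/m^2)
#' @param frac_low_ldl proportion of patients assigned to the low-LDL latent
#'   group
#' @param panel_visits_lambda Poisson rate for extra lipid panels per patient
#'   (every patient gets at least one)
#' @param frac_direct_ldl proportion of lipid panels that also carry a
#'   directly measured LDL-C value
#' @param window_years length of the simulated calendar window
#' @param end_date last calendar date of the window
#' @param contamination named list of contamination rates, each a proportion:
#'   `statin` (patients with statin mentions), `inpatient` (lipid panels
#'   flagged inpatient), `low_albumin` (patients with an albumin < 3 g/dl
#'   near a panel), `under5` (patients with a lipid panel before age 5),
#'   `no_glucose` (non-diabetic patients with no glucose measurement, so the
#'   T2DM algorithm must abstain), `t1dm` (type-1-pattern patients),
#'   `cardio_codes`, `stroke_codes`, `transplant_codes`, `ckd_codes`
#'   (sensitivity-filter code carriers), `low_egfr` (patients with an
#'   eGFR <= 29 ml/min), `ezetimibe` (patients with an ezetimibe mention).
#'   Passing a single number sets every rate to that value; rates omitted
#'   from a list keep their defaults.
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_patients = 20000L,
                       seed = 1L,
                       true_log_or_low_ldl = log(2),
                       baseline_t2dm_logit = -7.55,
                       covariate_effects = c(age = 0.04, male = 0.3,
                                             african_ancestry = 0.4,
                                             bmi = 0.09),
                       frac_low_ldl = 8943 / 80286,
                       panel_visits_lambda = 2.2,
                       frac_direct_ldl = 0.05,
                       window_years = 20,
                       end_date = as.Date("2017-12-31"),
                       contamination = NULL) {
  default_contam <- list(
    statin = 0.10, inpatient = 0.05, low_albumin = 0.03, under5 = 0.02,
    no_glucose = 0.05, t1dm = 0.01, cardio_codes = 0.05, stroke_codes = 0.015,
    transplant_codes = 0.01, ckd_codes = 0.01, low_egfr = 0.02,
    ezetimibe = 0.02
  )
  if (is.null(contamination)) {
    contamination <- default_contam
  } else if (is.numeric(contamination) && length(contamination) == 1L) {
    contamination <- setNames(as.list(rep(contamination,
                                          length(default_contam))),
                              names(default_contam))
  } else {
    unknown <- setdiff(names(contamination), names(default_contam))
    if (length(unknown))
      config_error("contamination",
                   paste("unknown rate(s):", paste(unknown, collapse = ", ")))
    contamination <- utils::modifyList(default_contam,
                                       as.list(contamination))
  }
  cfg <- list(
    n_patients = n_patients, seed = seed,
    true_log_or_low_ldl = true_log_or_low_ldl,
    baseline_t2dm_logit = baseline_t2dm_logit,
    covariate_effects = covariate_effects,
    frac_low_ldl = frac_low_ldl,
    panel_visits_lambda = panel_visits_lambda,
    frac_direct_ldl = frac_direct_ldl,
    window_years = window_years,
    end_date = as.Date(end_date),
    contamination = contamination
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != floor(cfg$n_patients))
    config_error("n_patients", "must be a single non-negative integer")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    config_error("seed", "must be a single integer")
  check_number(cfg$true_log_or_low_ldl, "true_log_or_low_ldl")
  check_number(cfg$baseline_t2dm_logit, "baseline_t2dm_logit")
  eff <- cfg$covariate_effects
  need_eff <- c("age", "male", "african_ancestry", "bmi")
  if (!is.numeric(eff) || !all(need_eff %in% names(eff)))
    config_error("covariate_effects",
                 paste("must be a named numeric vector with entries",
                       paste(need_eff, collapse = ", ")))
  check_proportion(cfg$frac_low_ldl, "frac_low_ldl")
  check_number(cfg$panel_visits_lambda, "panel_visits_lambda")
  if (cfg$panel_visits_lambda < 0)
    config_error("panel_visits_lambda", "must be non-negative")
  check_proportion(cfg$frac_direct_ldl, "frac_direct_ldl")
  check_number(cfg$window_years, "window_years")
  if (cfg$window_years <= 0)
    config_error("window_years", "must be positive")
  for (nm in names(cfg$contamination))
    check_proportion(cfg$contamination[[nm]],
                     paste0("contamination$", nm))
  invisible(cfg)
}

# Group-specific distribution anchors (medians and log-scale spreads)
# calibrated so per-patient median derived LDL-C, HDL-C, triglycerides, BMI,
# age and EHR length reproduce the target cohort's medians and IQRs.
.sim_anchors <- list(
  low = list(ldl_med = 52, ldl_sd_b = 0.180, ldl_sd_w = 0.060,
             hdl_med = 51, hdl_sd_b = 0.38,
             tg_med = 88, tg_sd_b = 0.68,
             age_med = 33.0, age_sd = 0.72,
             bmi_med = 24.5, bmi_sd = 0.271,
             p_male = 0.458, p_eur = 0.614, p_afr = 0.209),
  normal = list(ldl_med = 109, ldl_sd_b = 0.110, ldl_sd_w = 0.060,
                hdl_med = 51, hdl_sd_b = 0.30,
                tg_med = 101, tg_sd_b = 0.51,
                age_med = 42.8, age_sd = 0.45,
                bmi_med = 27.1, bmi_sd = 0.232,
                p_male = 0.422, p_eur = 0.700, p_afr = 0.130)
)
.HDL_SD_W <- 0.12
.TG_SD_W <- 0.15
.EHR_SPAN_MED <- 6.6
.EHR_SPAN_SD <- 0.61

#' Generate a synthetic EHR population
#'
#' Produces the four longitudinal tables the pipeline consumes (patients,
#' labs, ICD-9 code events, medication mentions) plus a `truth` table with
#' the latent LDL group and T2DM status of every patient, for
#' parameter-recovery testing. Lipid panels carry total cholesterol, HDL-C
#' and triglycerides; LDL-C is never written directly (except for the
#' configured fraction of direct assays), so the pipeline must derive it
#' with the Friedewald formula. T2DM-positive patients receive at least two
#' type 2 diabetes ICD-9 codes on distinct days plus an abnormal glucose
#' (and often a diabetes medication); T2DM-negative patients receive a
#' normal glucose and no diabetes codes or medications, unless a
#' contamination pathway deliberately degrades them so the downstream
#' filters and the abstaining classifier are exercised.
#'
#' @param config a [sim_config()] object
#' @return a list with elements `patients`, `labs`, `codes`, `meds`
#'   (data.tables in the documented schemas) and `truth`
#' @export
generate_population <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- as.integer(config$n_patients)
  if (n == 0L) {
    out <- empty_tables()
    out$truth <- data.table(patient_id = character(),
                            ldl_group_true = character(),
                            t2dm_true = integer(),
                            age_years = numeric(), bmi_latent = numeric())
    return(out)
  }
  set.seed(config$seed)
  con <- config$contamination
  an <- .sim_anchors

  ids <- sprintf("P%06d", seq_len(n))
  grp <- ifelse(runif(n) < config$frac_low_ldl, "low", "normal")
  is_low <- grp == "low"
  pick <- function(field) {
    ifelse(is_low, an$low[[field]], an$normal[[field]])
  }

  male <- runif(n) < pick("p_male")
  u_race <- runif(n)
  race <- ifelse(u_race < pick("p_eur"), "european_ancestry",
                 ifelse(u_race < pick("p_eur") + pick("p_afr"),
                        "african_ancestry", "other"))
  sex <- ifelse(male, "male", "female")

  age <- pmin(pmax(rlnorm(n, log(pick("age_med")), pick("age_sd")), 8), 90)
  span <- pmin(rlnorm(n, log(.EHR_SPAN_MED), .EHR_SPAN_SD),
               config$window_years * 0.98, age - 1)
  span <- pmax(span, 0.05)
  last_date <- config$end_date -
    round(runif(n, 0, config$window_years - span) * DAYS_PER_YEAR)
  first_date <- last_date - round(span * DAYS_PER_YEAR)
  birth_date <- last_date - round(age * DAYS_PER_YEAR)

  bmi_lat <- rlnorm(n, log(pick("bmi_med")), pick("bmi_sd"))
  ldl_lat <- rlnorm(n, log(pick("ldl_med")), pick("ldl_sd_b"))
  hdl_lat <- rlnorm(n, log(pick("hdl_med")), pick("hdl_sd_b"))
  tg_lat <- rlnorm(n, log(pick("tg_med")), pick("tg_sd_b"))

  eff <- config$covariate_effects
  lin <- config$baseline_t2dm_logit +
    config$true_log_or_low_ldl * is_low +
    eff[["age"]] * age + eff[["male"]] * male +
    eff[["african_ancestry"]] * (race == "african_ancestry") +
    eff[["bmi"]] * bmi_lat
  t2dm <- rbinom(n, 1L, plogis(lin))

  patients <- data.table(patient_id = ids, birth_date = birth_date,
                         sex = sex, race = race)
  truth <- data.table(patient_id = ids, ldl_group_true = grp,
                      t2dm_true = t2dm, age_years = age,
                      bmi_latent = bmi_lat)

  rand_dates <- function(idx, k = NULL) {
    # uniform event dates inside each patient's record window
    if (is.null(k)) k <- rep(1L, length(idx))
    i <- rep(idx, k)
    first_date[i] + round(runif(length(i)) *
                            as.numeric(last_date[i] - first_date[i]))
  }

  ## --- lipid panels -------------------------------------------------------
  n_panels <- 1L + rpois(n, config$panel_visits_lambda)
  pi <- rep(seq_len(n), n_panels)          # patient index per panel
  m <- length(pi)
  panel_date <- rand_dates(seq_len(n), n_panels)
  ldl_v <- ldl_lat[pi] * exp(rnorm(m, 0, pick("ldl_sd_w")[pi]))
  hdl_v <- round(hdl_lat[pi] * exp(rnorm(m, 0, .HDL_SD_W)))
  tg_v <- round(tg_lat[pi] * exp(rnorm(m, 0, .TG_SD_W)))
  hdl_v <- pmax(hdl_v, 10)
  tg_v <- pmax(tg_v, 20)
  tc_v <- round(ldl_v + hdl_v + tg_v / 5)
  inpat <- runif(m) < con$inpatient
  direct <- runif(m) < config$frac_direct_ldl

  panel_labs <- function(idx, dates, tc, hdl, tg, inp, direct_sel, ldl) {
    out <- rbindlist(list(
      data.table(patient_id = ids[idx], date = dates,
                 lab_type = "total_cholesterol", value = tc, inpatient = inp),
      data.table(patient_id = ids[idx], date = dates,
                 lab_type = "hdl_c", value = hdl, inpatient = inp),
      data.table(patient_id = ids[idx], date = dates,
                 lab_type = "triglycerides", value = tg, inpatient = inp)
    ))
    if (any(direct_sel)) {
      out <- rbind(out, data.table(
        patient_id = ids[idx][direct_sel], date = dates[direct_sel],
        lab_type = "ldl_c_direct", value = round(ldl[direct_sel]),
        inpatient = inp[direct_sel]))
    }
    out
  }
  labs_list <- list(panel_labs(pi, panel_date, tc_v, hdl_v, tg_v,
                               inpat, direct, ldl_v))

  # pre-age-5 contamination: one extra (outpatient) panel in early childhood
  u5 <- which(runif(n) < con$under5)
  if (length(u5)) {
    d5 <- birth_date[u5] + round(runif(length(u5), 1, 4.5) * DAYS_PER_YEAR)
    k5 <- length(u5)
    ldl5 <- ldl_lat[u5]
    hdl5 <- round(hdl_lat[u5])
    tg5 <- round(tg_lat[u5])
    labs_list <- c(labs_list, list(panel_labs(
      u5, d5, round(ldl5 + hdl5 + tg5 / 5), hdl5, tg5,
      rep(FALSE, k5), rep(FALSE, k5), ldl5)))
  }

  ## --- supporting labs ----------------------------------------------------
  add_lab <- function(idx, type, values, dates = NULL) {
    if (!length(idx)) return(NULL)
    if (is.null(dates)) dates <- rand_dates(idx)
    data.table(patient_id = ids[idx], date = dates, lab_type = type,
               value = values, inpatient = FALSE)
  }

  cases <- which(t2dm == 1L)
  no_glu <- which(t2dm == 0L & runif(n) < con$no_glucose)
  ctrl_glu <- setdiff(which(t2dm == 0L), no_glu)
  labs_list <- c(labs_list, list(
    add_lab(cases, "glucose", round(runif(length(cases), 130, 220))),
    add_lab(cases, "glucose", round(runif(length(cases), 126, 200))),
    add_lab(ctrl_glu, "glucose", round(runif(length(ctrl_glu), 75, 99)))
  ))
  hba_cases <- cases[runif(length(cases)) < 0.5]
  hba_ctrl <- ctrl_glu[runif(length(ctrl_glu)) < 0.2]
  labs_list <- c(labs_list, list(
    add_lab(hba_cases, "hba1c", round(runif(length(hba_cases), 6.5, 9), 1)),
    add_lab(hba_ctrl, "hba1c", round(runif(length(hba_ctrl), 4.8, 5.6), 1))
  ))

  bmi_idx <- rep(seq_len(n), 2L)
  labs_list <- c(labs_list, list(add_lab(
    bmi_idx, "bmi",
    round(bmi_lat[bmi_idx] * exp(rnorm(2L * n, 0, 0.02)), 1))))

  labs_list <- c(labs_list, list(
    add_lab(seq_len(n), "albumin", round(runif(n, 3.5, 5.0), 1))))
  alb_low <- which(runif(n) < con$low_albumin)
  if (length(alb_low)) {
    # place the low albumin within +/- 25 days of the patient's first panel
    first_panel <- panel_date[!duplicated(pi)][alb_low]
    labs_list <- c(labs_list, list(add_lab(
      alb_low, "albumin", round(runif(length(alb_low), 2.0, 2.9), 1),
      dates = first_panel + sample(-25:25, length(alb_low), replace = TRUE))))
  }

  low_egfr <- which(runif(n) < con$low_egfr)
  egfr_val <- round(runif(n, 60, 120))
  egfr_val[low_egfr] <- round(runif(length(low_egfr), 10, 29))
  labs_list <- c(labs_list, list(add_lab(seq_len(n), "egfr", egfr_val)))

  labs <- rbindlist(labs_list, use.names = TRUE)

  ## --- ICD-9 codes --------------------------------------------------------
  codes_list <- list(
    # anchor codes pin the record window ends, so age-at-last-code and EHR
    # length are well defined for every patient
    data.table(patient_id = ids, date = first_date, icd9 = "V70.0"),
    data.table(patient_id = ids, date = last_date, icd9 = "401.1")
  )
  offset_date <- function(idx, frac) {
    first_date[idx] + round(frac * as.numeric(last_date[idx] -
                                                first_date[idx]))
  }
  if (length(cases)) {
    k <- length(cases)
    t2_code <- function(kk) ifelse(runif(kk) < 0.8, "250.00", "250.02")
    codes_list <- c(codes_list, list(
      data.table(patient_id = ids[cases], date = offset_date(cases, 0.25),
                 icd9 = t2_code(k)),
      data.table(patient_id = ids[cases], date = offset_date(cases, 0.75),
                 icd9 = t2_code(k))
    ))
    extra <- rpois(k, 0.8)
    if (any(extra > 0)) {
      ei <- rep(cases, extra)
      codes_list <- c(codes_list, list(
        data.table(patient_id = ids[ei], date = rand_dates(ei),
                   icd9 = t2_code(length(ei)))))
    }
    manif <- cases[runif(k) < 0.25]
    if (length(manif)) {
      fam <- sample(c("250.40", "250.50", "250.60", "250.70", "250.80"),
                    length(manif), replace = TRUE)
      codes_list <- c(codes_list, list(
        data.table(patient_id = ids[manif], date = offset_date(manif, 0.4),
                   icd9 = fam),
        data.table(patient_id = ids[manif], date = offset_date(manif, 0.6),
                   icd9 = fam)))
    }
  }
  noncases <- which(t2dm == 0L)
  t1 <- noncases[runif(length(noncases)) < con$t1dm]
  if (length(t1)) {
    codes_list <- c(codes_list, list(
      data.table(patient_id = ids[t1], date = offset_date(t1, 0.3),
                 icd9 = "250.01"),
      data.table(patient_id = ids[t1], date = offset_date(t1, 0.7),
                 icd9 = "250.01")))
  }
  add_codes <- function(rate, pool) {
    idx <- which(runif(n) < rate)
    if (!length(idx)) return(NULL)
    data.table(patient_id = ids[idx], date = rand_dates(idx),
               icd9 = sample(pool, length(idx), replace = TRUE))
  }
  codes_list <- c(codes_list, list(
    add_codes(con$cardio_codes, c("410.90", "411.1", "411.81")),
    add_codes(con$stroke_codes, c("434.91", "435.9", "435.8")),
    add_codes(con$transplant_codes, c("V42.0", "V42.1", "V42.7")),
    add_codes(con$ckd_codes, c("585.5", "585.6"))
  ))
  codes <- rbindlist(codes_list, use.names = TRUE)

  ## --- medications --------------------------------------------------------
  meds_list <- list()
  add_meds <- function(idx, cls, names_pool, dates = NULL) {
    if (!length(idx)) return(NULL)
    if (is.null(dates)) dates <- rand_dates(idx)
    data.table(patient_id = ids[idx], date = dates, drug_class = cls,
               drug_name = sample(names_pool, length(idx), replace = TRUE))
  }
  statin_pat <- which(runif(n) < con$statin)
  if (length(statin_pat)) {
    # first statin mention sits mid-record so panels both before and after
    # exist, exercising the post-statin filter
    sd1 <- offset_date(statin_pat, runif(length(statin_pat), 0.3, 0.9))
    meds_list <- c(meds_list, list(add_meds(
      statin_pat, "statin", c("atorvastatin", "simvastatin", "rosuvastatin"),
      dates = sd1)))
  }
  ez <- which(runif(n) < con$ezetimibe)
  meds_list <- c(meds_list, list(add_meds(ez, "ezetimibe", "ezetimibe")))
  if (length(cases)) {
    oral <- cases[runif(length(cases)) < 0.7]
    insn <- cases[runif(length(cases)) < 0.3]
    meds_list <- c(meds_list, list(
      add_meds(oral, "oral_t2dm_agent", c("metformin", "glipizide")),
      add_meds(insn, "insulin", c("insulin glargine", "insulin lispro"))))
  }
  meds_list <- c(meds_list, list(add_meds(t1, "insulin", "insulin lispro")))
  meds <- rbindlist(meds_list, use.names = TRUE)
  if (nrow(meds) == 0L) meds <- empty_tables()$meds

  setorder(labs, patient_id, date, lab_type, value)
  setorder(codes, patient_id, date, icd9)
  setorder(meds, patient_id, date, drug_class, drug_name)
  list(patients = patients, labs = labs, codes = codes, meds = meds,
       truth = truth)
}

#' Write a generated population to CSV files
#'
#' @param pop result of [generate_population()]
#' @param dir output directory (created if needed)
#' @param truth also write the latent `truth.csv` (synthetic ground truth;
#'   not part of the analysis schema)
#' @return invisibly, the paths written
#' @export
write_population <- function(pop, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("patients", "labs", "codes", "meds")
  if (truth && !is.null(pop$truth)) nm <- c(nm, "truth")
  paths <- file.path(dir, paste0(nm, ".csv"))
  for (i in seq_along(nm))
    fwrite(pop[[nm[i]]], paths[i])
  invisible(paths)
}

#' Read a population from CSV files written by [write_population()]
#' @param dir directory containing `patients.csv`, `labs.csv`, `codes.csv`,
#'   `meds.csv` (and optionally `truth.csv`)
#' @return a population list in the [generate_population()] format
#' @export
read_population <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    x <- as_dt(fread(p))
    if ("icd9" %in% names(x)) x[, icd9 := as.character(icd9)]
    if ("inpatient" %in% names(x)) x[, inpatient := as.logical(inpatient)]
    x
  }
  pop <- list(patients = rd("patients.csv"), labs = rd("labs.csv"),
              codes = rd("codes.csv"), meds = rd("meds.csv"))
  validate_tables(pop)
  tr <- rd("truth.csv")
  if (!is.null(tr)) pop$truth <- tr
  pop
}

#' Per-group population summary: medians, IQRs and category counts
#'
#' Reports, per LDL group, the median and interquartile range of derived
#' LDL-C, HDL-C, triglycerides, BMI, age, and EHR length (all per-patient
#' medians or derived values), plus N (%) for sex and race — the layout of a
#' standard cohort demographics table.
#'
#' @param pop a population list from [generate_population()]
#' @param groups a data.frame with `patient_id` and `group` columns; defaults
#'   to the generator's latent group
#' @return a data.table with columns `group`, `characteristic`, `level`,
#'   `n`, `pct`, `median`, `q25`, `q75`
#' @export
summarize_population <- function(pop, groups = NULL) {
  validate_tables(pop)
  if (nrow(pop$patients) == 0L)
    stop("cannot summarize an empty population", call. = FALSE)
  if (is.null(groups)) {
    if (is.null(pop$truth))
      stop("no 'groups' given and population has no truth table",
           call. = FALSE)
    groups <- pop$truth[, .(patient_id, group = ldl_group_true)]
  }
  groups <- as.data.table(groups)[, .(patient_id, group)]

  labs <- as_dt(pop$labs)
  wide <- dcast(labs[lab_type %in% c("total_cholesterol", "hdl_c",
                                     "triglycerides")],
                patient_id + date ~ lab_type, value.var = "value",
                fun.aggregate = function(x) x[1])
  wide <- wide[!is.na(total_cholesterol) & !is.na(hdl_c) &
                 !is.na(triglycerides)]
  wide[, ldl := friedewald_ldl(total_cholesterol, hdl_c, triglycerides)]
  per_pat <- wide[, .(ldl = median(ldl)), by = patient_id]
  med_lab <- function(type) {
    labs[lab_type == type, .(v = median(value)), by = patient_id]
  }
  pats <- as_dt(pop$patients)
  ev <- rbind(labs[, .(patient_id, date)],
              as_dt(pop$codes)[, .(patient_id, date)],
              as_dt(pop$meds)[, .(patient_id, date)])
  span <- ev[, .(first = min(date), last = max(date)), by = patient_id]
  span <- merge(span, pats[, .(patient_id, birth_date)], by = "patient_id")
  span[, `:=`(ehr_years = as.numeric(last - first) / DAYS_PER_YEAR,
              age = as.numeric(last - birth_date) / DAYS_PER_YEAR)]

  base <- merge(groups, pats, by = "patient_id")
  num_vars <- list(
    ldl_c = per_pat[, .(patient_id, v = ldl)],
    hdl_c = med_lab("hdl_c")[, .(patient_id, v)],
    triglycerides = med_lab("triglycerides")[, .(patient_id, v)],
    bmi = med_lab("bmi")[, .(patient_id, v)],
    age = span[, .(patient_id, v = age)],
    ehr_length = span[, .(patient_id, v = ehr_years)]
  )
  rows <- list()
  for (g in unique(base$group)) {
    gid <- base[group == g, patient_id]
    if (!length(gid)) {
      warning(sprintf("group '%s' has zero members", g))
      next
    }
    for (nm in names(num_vars)) {
      v <- num_vars[[nm]][patient_id %chin% gid, v]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.table(
        group = g, characteristic = nm, level = NA_character_,
        n = length(v), pct = NA_real_,
        median = if (length(v)) median(v) else NA_real_,
        q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
        q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_)
    }
    gb <- base[group == g]
    for (var in c("sex", "race")) {
      tab <- gb[, .N, by = var]
      setnames(tab, var, "level")
      rows[[length(rows) + 1L]] <- tab[, .(
        group = g, characteristic = var, level,
        n = N, pct = 100 * N / nrow(gb),
        median = NA_real_, q25 = NA_real_, q75 = NA_real_)]
    }
  }
  rbindlist(rows)
}
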