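# Phenotyping: phecode-based case/control/exclusion assignment, the
# algorithmic type 2 diabetes classifier, and covariate derivation.

#' Load a phecode map
#'
#' Reads the ICD-9-to-phecode mapping and the per-phecode exclusion ranges.
#' The bundled default is a deliberately miniature fixture covering the
#' diabetes family (parent phecode 250.2 and children 250.21-250.25, plus
#' the type 1 counterparts), ischemic heart disease (411.*), chronic kidney
#' disease stages (585.3x) and hypertension — enough to drive the pipeline
#' and its sensitivity filters; it is not the full production table. Any
#' external map in the same two-file CSV schema can be supplied instead.
#'
#' The hierarchy is implied by string prefix: phecode 250.2 is the parent of
#' 250.21..250.25. Every mapped phecode must carry an exclusion-range entry
#' (possibly empty, i.e. NA bounds).
#'
#' @param map_file CSV with columns `icd9,phecode`
#' @param exclude_file CSV with columns `phecode,exclude_low,exclude_high`
#' @return list of class `phecode_map` with elements `map` and `exclude`
#' @export
load_phecode_map <- function(map_file = NULL, exclude_file = NULL) {
  if (is.null(map_file))
    map_file <- system.file("extdata", "phecode_icd9.csv",
                            package = "lowldl", mustWork = TRUE)
  if (is.null(exclude_file))
    exclude_file <- system.file("extdata", "phecode_exclude.csv",
                                package = "lowldl", mustWork = TRUE)
  map <- fread(map_file, colClasses = list(character = c("icd9", "phecode")))
  excl <- fread(exclude_file, colClasses = list(character = "phecode"))
  if (!all(c("icd9", "phecode") %in% names(map)))
    stop("phecode map must have columns icd9, phecode", call. = FALSE)
  if (!all(c("phecode", "exclude_low", "exclude_high") %in% names(excl)))
    stop("exclusion table must have columns phecode, exclude_low, exclude_high",
         call. = FALSE)
  missing_excl <- setdiff(unique(map$phecode), unique(excl$phecode))
  if (length(missing_excl))
    stop(sprintf("phecode(s) lacking an exclusion-range entry: %s",
                 paste(missing_excl, collapse = ", ")), call. = FALSE)
  bad <- excl[!is.na(exclude_low) & !is.na(exclude_high) &
                exclude_low > exclude_high]
  if (nrow(bad))
    stop("malformed exclusion interval(s): low > high", call. = FALSE)
  structure(list(map = map, exclude = excl), class = "phecode_map")
}

#' @noRd
phecode_descendants <- function(map, phenotype_id) {
  all_codes <- unique(c(map$map$phecode, map$exclude$phecode))
  all_codes[all_codes == phenotype_id |
              startsWith(all_codes, phenotype_id)]
}

#' Case/control/exclusion status for one phecode
#'
#' A patient is a case when ICD-9 codes mapping to the phecode (or any of
#' its descendants) occur on two or more distinct calendar days; a patient
#' with exactly one such day is excluded; a patient with no such days but
#' with at least one code mapping into the phecode's exclusion ranges is
#' excluded from the control pool; everyone else is a control.
#'
#' @param codes ICD-9 code-event table (`patient_id`, `date`, `icd9`)
#' @param phecode_map a [load_phecode_map()] object
#' @param phenotype_id phecode string, e.g. `"250.2"`
#' @param patient_ids the patient universe to classify; defaults to the
#'   patients appearing in `codes`
#' @return data.table: `patient_id`, `phenotype_id`, `status`
#'   (case/control/excluded), `n_code_days`
#' @export
assign_phecode_status <- function(codes, phecode_map, phenotype_id,
                                  patient_ids = NULL) {
  stopifnot(inherits(phecode_map, "phecode_map"))
  known <- unique(c(phecode_map$map$phecode, phecode_map$exclude$phecode))
  if (!phenotype_id %in% known)
    stop(sprintf("unknown phenotype_id '%s'", phenotype_id), call. = FALSE)
  codes <- as_dt(codes)
  if (is.null(patient_ids)) patient_ids <- unique(codes$patient_id)

  targets <- phecode_descendants(phecode_map, phenotype_id)
  mapped <- merge(codes, phecode_map$map, by = "icd9",
                  allow.cartesian = TRUE)
  tgt_days <- mapped[phecode %in% targets,
                     .(n_code_days = uniqueN(date)), by = patient_id]

  ranges <- phecode_map$exclude[phecode == phenotype_id &
                                  !is.na(exclude_low)]
  if (nrow(ranges)) {
    pnum <- suppressWarnings(as.numeric(mapped$phecode))
    hit <- rep(FALSE, nrow(mapped))
    for (i in seq_len(nrow(ranges)))
      hit <- hit | (!is.na(pnum) & pnum >= ranges$exclude_low[i] &
                      pnum <= ranges$exclude_high[i])
    excl_pat <- unique(mapped$patient_id[hit])
  } else excl_pat <- character()

  out <- data.table(patient_id = patient_ids)
  out <- merge(out, tgt_days, by = "patient_id", all.x = TRUE)
  out[is.na(n_code_days), n_code_days := 0L]
  out[, phenotype_id := phenotype_id]
  out[, status := "control"]
  out[n_code_days == 0L & patient_id %chin% excl_pat, status := "excluded"]
  out[n_code_days == 1L, status := "excluded"]
  out[n_code_days >= 2L, status := "case"]
  setcolorder(out, c("patient_id", "phenotype_id", "status", "n_code_days"))
  setorder(out, patient_id)
  out[]
}

#' Algorithmic type 2 diabetes classification
#'
#' A rule-based classifier combining diagnosis codes, diabetes medications,
#' and glucose/HbA1c laboratory values, with abstention for unclassifiable
#' patients. It mirrors the structure of high-specificity electronic T2DM
#' phenotyping algorithms: a case needs at least one type 2 diabetes ICD-9
#' code (250.x0/250.x2) together with supporting treatment or laboratory
#' evidence (a diabetes medication, a glucose of 126 mg/dl or more, or an
#' HbA1c of 6.5% or more), and must not show a type-1-only pattern (only
#' 250.x1/250.x3 codes, on insulin without an oral agent). A control needs a
#' record free of diabetes-range codes and diabetes medications plus at
#' least one normal glucose below 100 mg/dl. Everyone else — including
#' patients with no glucose measurement at all — is excluded as
#' unclassifiable.
#'
#' @param codes,labs,meds input tables
#' @param patient_ids patient universe; defaults to all patients appearing
#'   in any of the three tables
#' @return data.table: `patient_id`, `phenotype_id` ("t2dm_algorithm"),
#'   `status`, `n_code_days` (distinct days with type 2 codes)
#' @export
t2dm_algorithm <- function(codes, labs, meds, patient_ids = NULL) {
  codes <- as_dt(codes); labs <- as_dt(labs); meds <- as_dt(meds)
  if (is.null(patient_ids))
    patient_ids <- unique(c(codes$patient_id, labs$patient_id,
                            meds$patient_id))

  t2 <- codes[grepl("^250\\.[0-9][02]$", icd9),
              .(n_code_days = uniqueN(date)), by = patient_id]
  t1_pat <- unique(codes[grepl("^250\\.[0-9][13]$", icd9), patient_id])
  dm_code_pat <- unique(codes[startsWith(icd9, "250."), patient_id])

  oral_pat <- unique(meds[drug_class == "oral_t2dm_agent", patient_id])
  insulin_pat <- unique(meds[drug_class == "insulin", patient_id])
  dm_med_pat <- union(oral_pat, insulin_pat)

  abn_pat <- unique(c(
    labs[lab_type == "glucose" & value >= 126, patient_id],
    labs[lab_type == "hba1c" & value >= 6.5, patient_id]))
  normal_glu_pat <- unique(labs[lab_type == "glucose" & value < 100,
                                patient_id])

  out <- data.table(patient_id = patient_ids)
  out <- merge(out, t2, by = "patient_id", all.x = TRUE)
  out[is.na(n_code_days), n_code_days := 0L]
  has_t2 <- out$n_code_days > 0L
  has_t1 <- out$patient_id %chin% t1_pat
  has_dm_code <- out$patient_id %chin% dm_code_pat
  has_dm_med <- out$patient_id %chin% dm_med_pat
  has_oral <- out$patient_id %chin% oral_pat
  has_insulin <- out$patient_id %chin% insulin_pat
  abnormal <- out$patient_id %chin% abn_pat
  normal_glu <- out$patient_id %chin% normal_glu_pat

  t1_only <- has_t1 & !has_t2 & has_insulin & !has_oral
  is_case <- has_t2 & (has_dm_med | abnormal) & !t1_only
  is_control <- !has_dm_code & !has_dm_med & normal_glu

  out[, phenotype_id := "t2dm_algorithm"]
  out[, status := "excluded"]
  out[is_control, status := "control"]
  out[is_case, status := "case"]
  setcolorder(out, c("patient_id", "phenotype_id", "status", "n_code_days"))
  setorder(out, patient_id)
  out[]
}

#' Derive per-patient analysis covariates
#'
#' Age is the age at the most recent ICD-9 code assignment; EHR length runs
#' from the first to the last recorded event (labs, codes, and medication
#' mentions when supplied), in years; BMI, HDL-C, and triglycerides are
#' per-patient medians over all available values. Missing quantities are
#' emitted as `NA` — model fits are complete-case per fit.
#'
#' @param patients,labs,codes input tables
#' @param meds optional medication table, included in the event span
#' @return data.table: `patient_id`, `age_years`, `sex`, `race`,
#'   `bmi_median`, `hdl_median`, `tg_median`, `ehr_length_years`
#' @export
derive_covariates <- function(patients, labs, codes, meds = NULL) {
  patients <- as_dt(patients); labs <- as_dt(labs); codes <- as_dt(codes)

  last_code <- codes[, .(last_code = max(date)), by = patient_id]
  ev <- rbind(labs[, .(patient_id, date)], codes[, .(patient_id, date)])
  if (!is.null(meds) && nrow(meds))
    ev <- rbind(ev, as_dt(meds)[, .(patient_id, date)])
  span <- ev[, .(first_ev = min(date), last_ev = max(date)), by = patient_id]

  med_of <- function(type, col) {
    x <- labs[lab_type == type, .(v = median(value)), by = patient_id]
    setnames(x, "v", col)
  }
  out <- patients[, .(patient_id, birth_date, sex, race)]
  out <- Reduce(function(a, b) merge(a, b, by = "patient_id", all.x = TRUE),
                list(out, last_code, span,
                     med_of("bmi", "bmi_median"),
                     med_of("hdl_c", "hdl_median"),
                     med_of("triglycerides", "tg_median")))
  n_no_code <- sum(is.na(out$last_code))
  if (n_no_code > 0)
    warning(sprintf("%d patient(s) have no ICD-9 codes; age is NA",
                    n_no_code))
  out[, age_years := as.numeric(last_code - birth_date) / DAYS_PER_YEAR]
  out[, ehr_length_years :=
        fifelse(is.na(first_ev), NA_real_,
                as.numeric(last_ev - first_ev) / DAYS_PER_YEAR)]
  out[, c("birth_date", "last_code", "first_ev", "last_ev") := NULL]
  setcolorder(out, c("patient_id", "age_years", "sex", "race", "bmi_median",
                     "hdl_median", "tg_median", "ehr_length_years"))
  setorder(out, patient_id)
  out[]
}
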