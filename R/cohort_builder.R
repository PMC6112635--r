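# Cohort construction: per-measurement eligibility filtering, Friedewald
# LDL-C derivation, median-based low/normal group assignment, and the seeded
# discovery/validation split.

#' Friedewald estimate of LDL cholesterol
#'
#' LDL-C = total cholesterol - HDL-C - triglycerides / 5, all in mg/dl.
#' The estimate can be negative at very low total cholesterol; negative
#' values are returned as-is (downstream rules handle them explicitly).
#' The formula is unreliable when triglycerides exceed 400 mg/dl; flagging
#' such records is the responsibility of [filter_ldl_measurements()].
#'
#' @param total_cholesterol,hdl_c,triglycerides numeric vectors, mg/dl
#' @return numeric vector of estimated LDL-C, mg/dl
#' @export
#' @examples
#' friedewald_ldl(200, 50, 150)  # 120
friedewald_ldl <- function(total_cholesterol, hdl_c, triglycerides) {
  stopifnot(is.numeric(total_cholesterol), is.numeric(hdl_c),
            is.numeric(triglycerides))
  if (any(!is.finite(c(total_cholesterol, hdl_c, triglycerides))))
    stop("Friedewald inputs must be finite", call. = FALSE)
  if (any(total_cholesterol < 0 | hdl_c < 0 | triglycerides < 0))
    stop("Friedewald inputs must be non-negative", call. = FALSE)
  total_cholesterol - hdl_c - triglycerides / 5
}

#' Per-measurement LDL-C eligibility filtering
#'
#' Builds one record per candidate LDL-C determination (a direct assay, or a
#' complete same-day lipid panel evaluated with the Friedewald formula) and
#' applies the exclusion rules in a fixed precedence order, recording the
#' first matching reason:
#' inpatient, then age under 5 years, then within `albumin_window_days` of a
#' serum albumin below `albumin_threshold` g/dl, then on/after the first
#' statin mention, then (Friedewald records only, when `tg_filter` is on)
#' triglycerides above 400 mg/dl. A direct LDL-C assay on a date overrides
#' the Friedewald value for that date.
#'
#' @param labs,codes,meds,patients input tables in the generator schemas
#' @param albumin_threshold g/dl; albumin values strictly below it open an
#'   exclusion window
#' @param albumin_window_days half-width of the symmetric albumin window
#' @param tg_filter flag Friedewald records with triglycerides > 400 mg/dl
#' @return data.table with columns `patient_id`, `date`, `ldl_value`,
#'   `source` (friedewald/direct), `excluded`, `exclusion_reason`
#' @export
filter_ldl_measurements <- function(labs, codes, meds, patients,
                                    albumin_threshold = 3,
                                    albumin_window_days = 30,
                                    tg_filter = TRUE) {
  labs <- as_dt(labs); meds <- as_dt(meds); patients <- as_dt(patients)

  lip <- labs[lab_type %in% c("total_cholesterol", "hdl_c", "triglycerides")]
  panels <- dcast(lip, patient_id + date ~ lab_type, value.var = "value",
                  fun.aggregate = function(x) x[1])
  for (cc in c("total_cholesterol", "hdl_c", "triglycerides"))
    if (!cc %in% names(panels)) panels[, (cc) := NA_real_]
  inpat <- lip[, .(inpatient = any(inpatient)), by = .(patient_id, date)]
  panels <- merge(panels, inpat, by = c("patient_id", "date"))

  direct <- labs[lab_type == "ldl_c_direct",
                 .(ldl_direct = value[1], inpat_direct = any(inpatient)),
                 by = .(patient_id, date)]
  panels <- merge(panels, direct, by = c("patient_id", "date"), all = TRUE)

  complete_fw <- !is.na(panels$total_cholesterol) & !is.na(panels$hdl_c) &
    !is.na(panels$triglycerides)
  has_direct <- !is.na(panels$ldl_direct)
  skipped <- sum(!complete_fw & !has_direct)
  if (skipped > 0)
    message(sprintf(
      "filter_ldl_measurements: skipped %d determination(s) with incomplete panels and no direct assay",
      skipped))
  panels <- panels[complete_fw | has_direct]
  complete_fw <- complete_fw[complete_fw | has_direct]
  has_direct <- !is.na(panels$ldl_direct)

  rec <- panels[, .(patient_id, date)]
  rec[, source := ifelse(has_direct, "direct", "friedewald")]
  fw_val <- rep(NA_real_, nrow(panels))
  fw_val[complete_fw] <- friedewald_ldl(
    panels$total_cholesterol[complete_fw], panels$hdl_c[complete_fw],
    panels$triglycerides[complete_fw])
  rec[, ldl_value := ifelse(has_direct, panels$ldl_direct, fw_val)]
  rec[, inpatient := fifelse(has_direct & !is.na(panels$inpat_direct),
                             panels$inpat_direct,
                             fifelse(is.na(panels$inpatient), FALSE,
                                     panels$inpatient))]
  rec[, tg := panels$triglycerides]

  rec <- merge(rec, patients[, .(patient_id, birth_date)],
               by = "patient_id", all.x = TRUE)
  rec[, age_at_lab := as.numeric(date - birth_date) / DAYS_PER_YEAR]

  low_alb <- labs[lab_type == "albumin" & value < albumin_threshold,
                  .(patient_id, albumin_date = date)]
  if (nrow(low_alb)) {
    hits <- low_alb[rec, on = "patient_id", allow.cartesian = TRUE,
                    nomatch = NULL][
      abs(as.numeric(albumin_date - date)) <= albumin_window_days]
    alb_flag <- unique(hits[, .(patient_id, date)])[, alb := TRUE]
    rec <- merge(rec, alb_flag, by = c("patient_id", "date"), all.x = TRUE)
    rec[is.na(alb), alb := FALSE]
  } else rec[, alb := FALSE]

  statin_rows <- meds[drug_class == "statin"]
  statin1 <- if (nrow(statin_rows)) {
    statin_rows[, .(first_statin = min(date)), by = patient_id]
  } else {
    data.table(patient_id = character(),
               first_statin = as.Date(character()))
  }
  rec <- merge(rec, statin1, by = "patient_id", all.x = TRUE)
  rec[, post_statin := !is.na(first_statin) & date >= first_statin]

  # fixed precedence; the first matching reason is recorded
  rec[, exclusion_reason := "none"]
  rec[source == "friedewald" & tg_filter & !is.na(tg) & tg > 400,
      exclusion_reason := "tg_over_400"]
  rec[post_statin == TRUE, exclusion_reason := "post_statin"]
  rec[alb == TRUE, exclusion_reason := "low_albumin_window"]
  rec[!is.na(age_at_lab) & age_at_lab < 5, exclusion_reason := "age_under_5"]
  rec[inpatient == TRUE, exclusion_reason := "inpatient"]
  rec[, excluded := exclusion_reason != "none"]

  out <- rec[, .(patient_id, date, ldl_value, source, excluded,
                 exclusion_reason)]
  setorder(out, patient_id, date)
  out[]
}

#' LDL group thresholds (mg/dl)
#'
#' `low_median`: the low group requires a median at or below this;
#' `low_ceiling`: no measurement of a low-group patient may reach this;
#' `normal_min`/`normal_max`: inclusive median band of the normal group;
#' `normal_floor`/`normal_ceiling`: every measurement of a normal-group
#' patient must lie strictly between these.
#' @param low_median,low_ceiling,normal_min,normal_max,normal_floor,normal_ceiling
#'   numeric thresholds in mg/dl
#' @return a named list
#' @export
ldl_thresholds <- function(low_median = 60, low_ceiling = 80,
                           normal_min = 90, normal_max = 130,
                           normal_floor = 80, normal_ceiling = 150) {
  th <- list(low_median = low_median, low_ceiling = low_ceiling,
             normal_min = normal_min, normal_max = normal_max,
             normal_floor = normal_floor, normal_ceiling = normal_ceiling)
  for (nm in names(th)) check_number(th[[nm]], nm)
  if (!(low_median <= low_ceiling && low_ceiling <= normal_min &&
        normal_min <= normal_max && normal_max <= normal_ceiling))
    config_error("ldl_thresholds",
                 "thresholds must satisfy low_median <= low_ceiling <= normal_min <= normal_max <= normal_ceiling")
  th
}

#' Assign patients to LDL groups from their eligible measurements
#'
#' Per patient, the median is taken over non-excluded LDL records (even
#' counts average the two central values). Rules, applied in order: no
#' eligible measurement; negative median; median at or below the low
#' threshold (low group if no measurement ever reached `low_ceiling`, else
#' excluded `low_with_high_reading`); median in the gap between the low and
#' normal bands (`median_in_gap`); median inside the inclusive normal band
#' (normal group if every measurement lies strictly between `normal_floor`
#' and `normal_ceiling`, else `normal_out_of_band`); median above the band
#' (`normal_out_of_band`). `median_ldl_date` is the date of the eligible
#' measurement whose value is closest to the median (earliest on ties).
#'
#' @param ldl_records output of [filter_ldl_measurements()]
#' @param thresholds a [ldl_thresholds()] list
#' @return data.table, one row per patient: `patient_id`, `median_ldl`,
#'   `max_ldl`, `min_ldl`, `n_ldl`, `group` (low/normal/excluded),
#'   `exclusion_reason`, `median_ldl_date`
#' @export
assign_groups <- function(ldl_records, thresholds = ldl_thresholds()) {
  ldl_records <- as_dt(ldl_records)
  if (nrow(ldl_records) == 0L)
    return(data.table(patient_id = character(), median_ldl = numeric(),
                      max_ldl = numeric(), min_ldl = numeric(),
                      n_ldl = integer(), group = character(),
                      exclusion_reason = character(),
                      median_ldl_date = as.Date(character())))
  th <- thresholds
  elig <- ldl_records[excluded == FALSE]
  stats <- if (nrow(elig)) {
    elig[, {
      med <- median(ldl_value)
      d <- abs(ldl_value - med)
      closest <- which(d == min(d))
      .(median_ldl = med, max_ldl = max(ldl_value),
        min_ldl = min(ldl_value), n_ldl = .N,
        median_ldl_date = min(date[closest]))
    }, by = patient_id]
  } else {
    data.table(patient_id = character(), median_ldl = numeric(),
               max_ldl = numeric(), min_ldl = numeric(), n_ldl = integer(),
               median_ldl_date = as.Date(character()))
  }

  all_pat <- unique(ldl_records$patient_id)
  out <- merge(data.table(patient_id = all_pat), stats, by = "patient_id",
               all.x = TRUE)
  out[, `:=`(group = "excluded", exclusion_reason = "no_eligible_ldl")]
  out[is.na(n_ldl), n_ldl := 0L]
  has <- out$n_ldl > 0L
  med <- out$median_ldl
  out[has & med < 0,
      `:=`(group = "excluded", exclusion_reason = "negative_median")]
  out[has & med >= 0 & med <= th$low_median & max_ldl < th$low_ceiling,
      `:=`(group = "low", exclusion_reason = "none")]
  out[has & med >= 0 & med <= th$low_median & max_ldl >= th$low_ceiling,
      `:=`(group = "excluded", exclusion_reason = "low_with_high_reading")]
  out[has & med > th$low_median & med < th$normal_min,
      `:=`(group = "excluded", exclusion_reason = "median_in_gap")]
  in_band <- has & med >= th$normal_min & med <= th$normal_max
  out[in_band & max_ldl < th$normal_ceiling & min_ldl > th$normal_floor,
      `:=`(group = "normal", exclusion_reason = "none")]
  out[in_band & !(max_ldl < th$normal_ceiling & min_ldl > th$normal_floor),
      `:=`(group = "excluded", exclusion_reason = "normal_out_of_band")]
  out[has & med > th$normal_max,
      `:=`(group = "excluded", exclusion_reason = "normal_out_of_band")]
  setorder(out, patient_id)
  setcolorder(out, c("patient_id", "median_ldl", "max_ldl", "min_ldl",
                     "n_ldl", "group", "exclusion_reason",
                     "median_ldl_date"))
  out[]
}

#' Split included patients into discovery and validation phases
#'
#' Seeded uniform shuffle of the patients carrying a group label (low and
#' normal pooled); the first floor(N * discovery_fraction) go to discovery,
#' the rest to validation. Excluded patients get `NA` phase.
#'
#' @param assignments output of [assign_groups()]
#' @param seed integer seed controlling the shuffle
#' @param discovery_fraction fraction assigned to discovery (default 1/3)
#' @return `assignments` with a `phase` column added
#' @export
split_phases <- function(assignments, seed, discovery_fraction = 1 / 3) {
  if (!is.numeric(discovery_fraction) || discovery_fraction <= 0 ||
      discovery_fraction >= 1)
    config_error("discovery_fraction", "must lie strictly in (0, 1)")
  assignments <- copy(as_dt(assignments))
  if (nrow(assignments) == 0L) stop("empty assignments", call. = FALSE)
  assignments[, phase := NA_character_]
  inc <- which(assignments$group %in% c("low", "normal"))
  if (length(inc)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    perm <- inc[sample.int(length(inc))]
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    n_disc <- floor(length(inc) * discovery_fraction)
    assignments[perm, phase := c(rep("discovery", n_disc),
                                 rep("validation", length(inc) - n_disc))]
  }
  assignments[]
}

#' Attrition counts for the cohort-construction flowchart
#'
#' @param ldl_records output of [filter_ldl_measurements()]
#' @param assignments output of [assign_groups()] (optionally with phases)
#' @return a nested list of counts: measurements by exclusion reason,
#'   patients by group, group exclusion reasons, and phase sizes
#' @export
attrition_report <- function(ldl_records, assignments) {
  ldl_records <- as_dt(ldl_records); assignments <- as_dt(assignments)
  meas <- as.list(table(ldl_records$exclusion_reason))
  grp <- as.list(table(assignments$group))
  rsn <- as.list(table(assignments[group == "excluded", exclusion_reason]))
  out <- list(
    n_measurements = nrow(ldl_records),
    n_measurements_eligible = sum(!ldl_records$excluded),
    measurement_exclusions = meas,
    n_patients = nrow(assignments),
    patients_by_group = grp,
    patient_exclusions = rsn
  )
  if ("phase" %in% names(assignments))
    out$patients_by_phase <- as.list(table(assignments$phase, useNA = "no"))
  out
}
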