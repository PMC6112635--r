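library(data.table)

# --- tiny table builders ----------------------------------------------------

mk_patients <- function(ids, birth = as.Date("1970-01-01"),
                        sex = "female", race = "european_ancestry") {
  data.table(patient_id = ids, birth_date = as.Date(birth),
             sex = rep_len(sex, length(ids)),
             race = rep_len(race, length(ids)))
}

mk_panel <- function(id, date, tc, hdl, tg, inpatient = FALSE) {
  data.table(patient_id = id, date = as.Date(date),
             lab_type = c("total_cholesterol", "hdl_c", "triglycerides"),
             value = c(tc, hdl, tg), inpatient = inpatient)
}

mk_lab <- function(id, date, type, value, inpatient = FALSE) {
  data.table(patient_id = id, date = as.Date(date), lab_type = type,
             value = value, inpatient = inpatient)
}

mk_codes <- function(id, dates, icd9) {
  data.table(patient_id = id, date = as.Date(dates), icd9 = icd9)
}

mk_meds <- function(id, dates, drug_class, drug_name = drug_class) {
  data.table(patient_id = id, date = as.Date(dates),
             drug_class = drug_class, drug_name = drug_name)
}

empty_labs <- function() lowldl:::empty_tables()$labs
empty_codes <- function() lowldl:::empty_tables()$codes
empty_meds <- function() lowldl:::empty_tables()$meds

# panels whose Friedewald LDL equals `ldl` exactly (tc = ldl + hdl + tg/5)
mk_ldl_panels <- function(id, dates, ldl, hdl = 50, tg = 100,
                          inpatient = FALSE) {
  rbindlist(Map(function(d, l) mk_panel(id, d, l + hdl + tg / 5, hdl, tg,
                                        inpatient),
                dates, ldl))
}

# --- independent brute-force oracle for group assignment --------------------
# Re-derives per-patient medians by explicit sorting and checks every rule
# literally, one patient at a time. Kept deliberately naive and separate
# from the vectorized implementation it cross-checks.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_assign_one <- function(values) {
  if (length(values) == 0)
    return(list(group = "excluded", reason = "no_eligible_ldl",
                median = NA_real_))
  med <- oracle_median(values)
  hi <- max(values); lo <- min(values)
  if (med < 0)
    return(list(group = "excluded", reason = "negative_median",
                median = med))
  if (med <= 60) {
    if (hi < 80)
      return(list(group = "low", reason = "none", median = med))
    return(list(group = "excluded", reason = "low_with_high_reading",
                median = med))
  }
  if (med < 90)
    return(list(group = "excluded", reason = "median_in_gap", median = med))
  if (med <= 130) {
    if (hi < 150 && lo > 80)
      return(list(group = "normal", reason = "none", median = med))
    return(list(group = "excluded", reason = "normal_out_of_band",
                median = med))
  }
  list(group = "excluded", reason = "normal_out_of_band", median = med)
}

oracle_assign <- function(ldl_records) {
  recs <- as.data.table(ldl_records)
  ids <- sort(unique(recs$patient_id))
  elig <- recs[excluded == FALSE]
  vals_by_pat <- split(elig$ldl_value, elig$patient_id)
  out <- lapply(ids, function(pid) {
    r <- oracle_assign_one(vals_by_pat[[pid]] %||% numeric(0))
    data.table(patient_id = pid, group = r$group,
               exclusion_reason = r$reason, median_ldl = r$median)
  })
  rbindlist(out)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random ldl_records for oracle cross-checks: boundary-heavy value mix
random_ldl_records <- function(n_patients, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_patients), function(i) {
    k <- sample(1:20, 1)
    boundary <- sample(c(-1, 0, 40, 60, 60.5, 79, 80, 89, 90, 130, 130.5,
                         149, 150), k, replace = TRUE)
    smooth <- runif(k, -10, 170)
    vals <- ifelse(runif(k) < 0.3, boundary, smooth)
    data.table(patient_id = sprintf("R%05d", i),
               date = as.Date("2010-01-01") + sample(0:3650, k,
                                                     replace = TRUE),
               ldl_value = vals, source = "friedewald",
               excluded = runif(k) < 0.2)
  })
  recs <- rbindlist(rows)
  recs[, exclusion_reason := ifelse(excluded, "inpatient", "none")]
  recs
}

# a small population whose gate reliably passes, cached per test session
small_pop <- local({
  cache <- NULL
  function(n = 4000, seed = 42) {
    if (is.null(cache)) cache <<- generate_population(
      sim_config(n_patients = n, seed = seed))
    cache
  }
})
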