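pmap <- load_phecode_map()

test_that("the bundled phecode map loads and is validated", {
  expect_s3_class(pmap, "phecode_map")
  expect_true(all(T2DM_PHECODES %in% pmap$exclude$phecode))
  # a map with a phecode lacking an exclusion entry is rejected
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeLines(c("icd9,phecode", "123.4,123.4"), f1)
  writeLines(c("phecode,exclude_low,exclude_high"), f2)
  expect_error(load_phecode_map(f1, f2), "exclusion-range")
})

test_that("phecode status follows the two-distinct-days rule", {
  two_days <- mk_codes("A", c("2015-01-01", "2015-03-01"), "250.00")
  r <- assign_phecode_status(two_days, pmap, "250.2")
  expect_identical(r$status, "case")
  expect_identical(r$n_code_days, 2L)

  single <- mk_codes("A", "2015-01-01", "250.00")
  expect_identical(assign_phecode_status(single, pmap, "250.2")$status,
                   "excluded")

  same_day <- mk_codes("A", c("2015-01-01", "2015-01-01"), "250.00")
  expect_identical(assign_phecode_status(same_day, pmap, "250.2")$status,
                   "excluded")  # one distinct day only

  benign <- mk_codes("A", c("2015-01-01", "2015-02-01"), "401.1")
  expect_identical(assign_phecode_status(benign, pmap, "250.2")$status,
                   "control")

  # type 1 codes land in the exclusion range of the type 2 phecode
  t1 <- mk_codes("A", c("2015-01-01", "2015-02-01"), "250.01")
  expect_identical(assign_phecode_status(t1, pmap, "250.2")$status,
                   "excluded")

  expect_error(assign_phecode_status(two_days, pmap, "999.9"), "999.9")

  # a patient in the universe with no codes at all is a control
  r2 <- assign_phecode_status(two_days, pmap, "250.2",
                              patient_ids = c("A", "B"))
  expect_identical(r2[patient_id == "B", status], "control")
})

test_that("a case for a child phecode is a case for its parent", {
  renal <- mk_codes("A", c("2015-01-01", "2015-06-01"), "250.40")
  expect_identical(assign_phecode_status(renal, pmap, "250.21")$status,
                   "case")
  expect_identical(assign_phecode_status(renal, pmap, "250.2")$status,
                   "case")
})

test_that("phecode calls are a trichotomy and respect hierarchy and monotonicity", {
  set.seed(77)
  pool <- c("250.00", "250.02", "250.40", "250.50", "250.01", "401.1",
            "410.90", "V70.0", "585.5")
  ids <- sprintf("Z%04d", 1:150)
  codes <- rbindlist(lapply(ids, function(id) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    mk_codes(id, as.Date("2012-01-01") + sample(0:2000, k, replace = TRUE),
             sample(pool, k, replace = TRUE))
  }))
  for (pc in c("250.2", "250.21", "250.22")) {
    calls <- assign_phecode_status(codes, pmap, pc, patient_ids = ids)
    expect_identical(nrow(calls), length(ids))
    expect_identical(anyDuplicated(calls$patient_id), 0L)
    expect_true(all(calls$status %in% c("case", "control", "excluded")))
    expect_true(all(calls[status == "case", n_code_days] >= 2L))
  }
  child <- assign_phecode_status(codes, pmap, "250.21", patient_ids = ids)
  parent <- assign_phecode_status(codes, pmap, "250.2", patient_ids = ids)
  child_cases <- child[status == "case", patient_id]
  expect_true(all(parent[patient_id %in% child_cases, status] == "case"))

  # adding events never demotes a case to control
  extra <- rbind(codes, mk_codes(sample(ids, 40, replace = TRUE),
                                 as.Date("2016-01-01") +
                                   sample(0:300, 40, replace = TRUE),
                                 sample(pool, 40, replace = TRUE)))
  parent2 <- assign_phecode_status(extra, pmap, "250.2", patient_ids = ids)
  was_case <- parent[status == "case", patient_id]
  expect_false(any(parent2[patient_id %in% was_case, status] == "control"))
})

test_that("the T2DM algorithm classifies the canonical patterns", {
  codes <- mk_codes("A", c("2015-01-01", "2015-03-01"), "250.00")
  labs <- mk_lab("A", "2015-02-01", "glucose", 140)
  meds <- mk_meds("A", "2015-02-15", "oral_t2dm_agent", "metformin")
  expect_identical(t2dm_algorithm(codes, labs, meds)$status, "case")

  # control: clean record plus a normal glucose
  expect_identical(
    t2dm_algorithm(empty_codes(), mk_lab("B", "2015-01-01", "glucose", 90),
                   empty_meds())$status, "control")

  # no glucose at all -> unclassifiable
  expect_identical(
    t2dm_algorithm(empty_codes(), mk_lab("C", "2015-01-01", "hba1c", 5.0),
                   empty_meds(), patient_ids = "C")$status, "excluded")

  # codes without any supporting treatment or laboratory evidence
  expect_identical(
    t2dm_algorithm(codes, mk_lab("A", "2015-02-01", "glucose", 90),
                   empty_meds())$status, "excluded")

  # type-1-only pattern: insulin without an oral agent, 250.x1 codes only
  t1codes <- mk_codes("D", c("2015-01-01", "2015-03-01"), "250.01")
  t1meds <- mk_meds("D", "2015-02-01", "insulin", "insulin lispro")
  t1labs <- mk_lab("D", "2015-02-01", "glucose", 150)
  expect_identical(t2dm_algorithm(t1codes, t1labs, t1meds)$status,
                   "excluded")

  # HbA1c of 6.5 or more is supporting evidence on its own
  expect_identical(
    t2dm_algorithm(codes, mk_lab("A", "2015-02-01", "hba1c", 6.5),
                   empty_meds())$status, "case")
})

test_that("the abstaining algorithm beats the naive one-code rule on PPV", {
  pop <- small_pop()
  calls <- t2dm_algorithm(pop$codes, pop$labs, pop$meds,
                          patient_ids = pop$patients$patient_id)
  truth <- merge(calls, pop$truth[, .(patient_id, t2dm_true)],
                 by = "patient_id")
  ppv_algo <- truth[status == "case", mean(t2dm_true == 1)]
  naive_cases <- unique(pop$codes[startsWith(icd9, "250."), patient_id])
  ppv_naive <- mean(pop$truth[patient_id %in% naive_cases, t2dm_true] == 1)
  expect_gt(ppv_algo, ppv_naive)
  expect_gt(ppv_algo, 0.98)
})

test_that("covariates: medians, EHR length, and age at last code", {
  pats <- mk_patients(c("A", "B"), birth = "1980-06-15")
  labs <- rbind(
    mk_lab("A", c("2010-01-01", "2011-01-01", "2012-01-01"), "bmi",
           c(22, 30, 25)),
    mk_lab("A", "2010-01-01", "hdl_c", 55),
    mk_lab("B", "2010-01-01", "bmi", 27))
  codes <- rbind(mk_codes("A", c("2008-01-01", "2014-06-15"), "V70.0"),
                 mk_codes("B", "2010-01-01", "V70.0"))
  cov <- derive_covariates(pats, labs, codes)
  a <- cov[patient_id == "A"]
  expect_equal(a$bmi_median, 25)
  expect_equal(a$hdl_median, 55)
  expect_true(is.na(a$tg_median))
  expect_equal(a$age_years,
               as.numeric(as.Date("2014-06-15") - as.Date("1980-06-15")) /
                 365.25)
  expect_equal(a$ehr_length_years,
               as.numeric(as.Date("2014-06-15") - as.Date("2008-01-01")) /
                 365.25)
  # single-record patient has zero EHR length
  b <- cov[patient_id == "B"]
  expect_equal(b$ehr_length_years, 0)

  # a patient with no codes gets NA age and a warning
  pats2 <- mk_patients(c("A", "C"))
  labs2 <- mk_lab("C", "2010-01-01", "bmi", 20)
  expect_warning(cov2 <- derive_covariates(pats2, labs2,
                                           mk_codes("A", "2010-01-01",
                                                    "V70.0")),
                 "no ICD-9 codes")
  expect_true(is.na(cov2[patient_id == "C", age_years]))
})
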