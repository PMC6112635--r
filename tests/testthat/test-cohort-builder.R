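test_that("Friedewald arithmetic matches its definition", {
  expect_equal(friedewald_ldl(200, 50, 150), 120)
  expect_equal(friedewald_ldl(100, 60, 250), -10)  # negative is allowed
  expect_equal(friedewald_ldl(0, 0, 0), 0)
  expect_equal(friedewald_ldl(c(200, 100), c(50, 60), c(150, 250)),
               c(120, -10))
  expect_error(friedewald_ldl(-1, 50, 100), "non-negative")
  expect_error(friedewald_ldl(NA_real_, 50, 100), "finite")
})

test_that("measurement exclusions fire with the documented precedence", {
  pats <- mk_patients("A", birth = "1980-01-01")
  no_codes <- empty_codes(); no_meds <- empty_meds()

  # inpatient outranks a same-day statin overlap
  labs <- mk_panel("A", "2010-01-10", 200, 50, 150, inpatient = TRUE)
  meds <- mk_meds("A", "2010-01-01", "statin", "atorvastatin")
  rec <- filter_ldl_measurements(labs, no_codes, meds, pats)
  expect_identical(rec$exclusion_reason, "inpatient")

  # age under 5: 4 years 11 months
  pats5 <- mk_patients("A", birth = "2005-03-01")
  labs5 <- mk_panel("A", "2010-02-01", 200, 50, 150)
  rec5 <- filter_ldl_measurements(labs5, no_codes, no_meds, pats5)
  expect_identical(rec5$exclusion_reason, "age_under_5")
  # ... and exactly 5 years is eligible
  labs5b <- mk_panel("A", "2010-03-02", 200, 50, 150)
  expect_identical(
    filter_ldl_measurements(labs5b, no_codes, no_meds,
                            pats5)$exclusion_reason, "none")

  # albumin 2.5 g/dl ten days before the panel
  labsA <- rbind(mk_panel("A", "2010-05-11", 200, 50, 150),
                 mk_lab("A", "2010-05-01", "albumin", 2.5))
  recA <- filter_ldl_measurements(labsA, no_codes, no_meds, pats)
  expect_identical(recA$exclusion_reason, "low_albumin_window")
  # the window is symmetric: 30 days out is excluded, 31 is not
  labsB <- rbind(mk_panel("A", "2010-05-01", 200, 50, 150),
                 mk_lab("A", "2010-05-31", "albumin", 2.9))
  expect_identical(
    filter_ldl_measurements(labsB, no_codes, no_meds,
                            pats)$exclusion_reason, "low_albumin_window")
  labsC <- rbind(mk_panel("A", "2010-05-01", 200, 50, 150),
                 mk_lab("A", "2010-06-01", "albumin", 2.9))
  expect_identical(
    filter_ldl_measurements(labsC, no_codes, no_meds,
                            pats)$exclusion_reason, "none")

  # day after the first statin mention (and on the day itself)
  labsS <- mk_panel("A", "2010-07-02", 200, 50, 150)
  medsS <- mk_meds("A", "2010-07-01", "statin", "simvastatin")
  expect_identical(
    filter_ldl_measurements(labsS, no_codes, medsS,
                            pats)$exclusion_reason, "post_statin")
  labsS2 <- mk_panel("A", "2010-06-30", 200, 50, 150)
  expect_identical(
    filter_ldl_measurements(labsS2, no_codes, medsS,
                            pats)$exclusion_reason, "none")

  # triglycerides above 400 invalidate Friedewald unless the filter is off
  labsT <- mk_panel("A", "2010-08-01", 300, 50, 401)
  expect_identical(
    filter_ldl_measurements(labsT, no_codes, no_meds,
                            pats)$exclusion_reason, "tg_over_400")
  expect_identical(
    filter_ldl_measurements(labsT, no_codes, no_meds, pats,
                            tg_filter = FALSE)$exclusion_reason, "none")
})

test_that("direct LDL assays override Friedewald and incomplete panels are skipped", {
  pats <- mk_patients("A")
  labs <- rbind(mk_panel("A", "2010-01-01", 200, 50, 150),
                mk_lab("A", "2010-01-01", "ldl_c_direct", 118),
                mk_lab("A", "2010-02-01", "hdl_c", 50))  # lone component
  expect_message(
    rec <- filter_ldl_measurements(labs, empty_codes(), empty_meds(), pats),
    "skipped 1")
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$source, "direct")
  expect_equal(rec$ldl_value, 118)
})

test_that("group assignment follows the median and band rules", {
  recs <- function(vals) data.table(
    patient_id = "A", date = as.Date("2010-01-01") + seq_along(vals),
    ldl_value = vals, source = "friedewald", excluded = FALSE,
    exclusion_reason = "none")
  g <- function(vals) assign_groups(recs(vals))

  r <- g(52)
  expect_identical(r$group, "low")
  expect_equal(r$median_ldl, 52)

  r <- g(c(55, 85))  # median 70 in the gap (recorded before the max rule)
  expect_identical(r$group, "excluded")
  expect_identical(r$exclusion_reason, "median_in_gap")
  expect_equal(r$median_ldl, 70)

  r <- g(c(100, 109, 119))
  expect_identical(r$group, "normal")
  expect_equal(r$median_ldl, 109)

  expect_identical(g(c(50, 50, 85))$exclusion_reason,
                   "low_with_high_reading")
  expect_identical(g(c(100, 110, 155))$exclusion_reason,
                   "normal_out_of_band")
  expect_identical(g(c(100, 110, 81))$group, "normal")
  expect_identical(g(c(100, 110, 80))$exclusion_reason,
                   "normal_out_of_band")  # floor is strict
  expect_identical(g(140)$exclusion_reason, "normal_out_of_band")
  expect_identical(g(-5)$exclusion_reason, "negative_median")
  expect_identical(g(60)$group, "low")        # inclusive low median
  expect_identical(g(c(90, 130))$group, "normal")  # inclusive band, even n

  # all records excluded -> no eligible LDL
  ex <- recs(c(50, 60))
  ex[, `:=`(excluded = TRUE, exclusion_reason = "inpatient")]
  r <- assign_groups(ex)
  expect_identical(r$exclusion_reason, "no_eligible_ldl")
  expect_identical(r$n_ldl, 0L)
})

test_that("the median date is the closest-in-value measurement, earliest on ties", {
  recs <- data.table(
    patient_id = "A",
    date = as.Date(c("2010-01-01", "2010-02-01", "2010-03-01")),
    ldl_value = c(50, 60, 55), source = "friedewald", excluded = FALSE,
    exclusion_reason = "none")
  expect_identical(assign_groups(recs)$median_ldl_date,
                   as.Date("2010-03-01"))
  tie <- recs[1:2]  # median 55, both 5 away -> earliest
  expect_identical(assign_groups(tie)$median_ldl_date,
                   as.Date("2010-01-01"))
})

test_that("group assignment matches the brute-force rule checker", {
  recs <- random_ldl_records(300, seed = 2024)
  got <- assign_groups(recs)
  want <- oracle_assign(recs)
  merged <- merge(got, want, by = "patient_id",
                  suffixes = c("_impl", "_oracle"))
  expect_identical(nrow(merged), length(unique(recs$patient_id)))
  expect_identical(merged$group_impl, merged$group_oracle)
  expect_identical(merged$exclusion_reason_impl,
                   merged$exclusion_reason_oracle)
  expect_equal(merged$median_ldl_impl, merged$median_ldl_oracle)
})

test_that("adding a statin mention never increases eligible records", {
  set.seed(31)
  pats <- mk_patients("A", birth = "1960-01-01")
  for (i in 1:25) {
    k <- sample(1:8, 1)
    dates <- as.Date("2005-01-01") + sample(0:3000, k)
    labs <- rbindlist(lapply(dates, function(d)
      mk_panel("A", d, runif(1, 120, 220), 50, 150)))
    base <- filter_ldl_measurements(labs, empty_codes(), empty_meds(), pats)
    statin_day <- as.Date("2005-01-01") + sample(0:3000, 1)
    with_statin <- filter_ldl_measurements(
      labs, empty_codes(), mk_meds("A", statin_day, "statin"), pats)
    expect_lte(sum(!with_statin$excluded), sum(!base$excluded))
  }
})

test_that("phase split uses floor(N/3), is deterministic, and pools groups", {
  mk_assign <- function(n) data.table(
    patient_id = sprintf("P%05d", seq_len(n)),
    median_ldl = 52, max_ldl = 52, min_ldl = 52, n_ldl = 1L,
    group = rep(c("low", "normal"), length.out = n),
    exclusion_reason = "none", median_ldl_date = as.Date("2010-01-01"))

  s3 <- split_phases(mk_assign(3), seed = 1)
  expect_identical(sum(s3$phase == "discovery"), 1L)
  expect_identical(sum(s3$phase == "validation"), 2L)

  big <- split_phases(mk_assign(26753), seed = 1)
  expect_identical(sum(big$phase == "discovery"), 8917L)  # floor(26753/3)
  # the split is over the pooled groups, so both groups appear in each phase
  expect_true(all(table(big$group, big$phase) > 0))

  a <- split_phases(mk_assign(500), seed = 9)
  b <- split_phases(mk_assign(500), seed = 9)
  expect_identical(a$phase, b$phase)
  c2 <- split_phases(mk_assign(500), seed = 10)
  expect_false(identical(a$phase, c2$phase))

  # excluded patients carry NA phase
  ex <- mk_assign(4)
  ex[1, `:=`(group = "excluded", exclusion_reason = "median_in_gap")]
  sx <- split_phases(ex, seed = 1)
  expect_true(is.na(sx[group == "excluded", phase]))
})

test_that("retained group measurements respect the band limits end to end", {
  pop <- small_pop()
  rec <- filter_ldl_measurements(pop$labs, pop$codes, pop$meds,
                                 pop$patients)
  grp <- assign_groups(rec)
  expect_identical(anyDuplicated(grp$patient_id), 0L)
  elig <- merge(rec[excluded == FALSE], grp[, .(patient_id, group)],
                by = "patient_id")
  expect_true(all(elig[group == "low", ldl_value] < 80))
  expect_true(all(elig[group == "normal", ldl_value] > 80 &
                    elig[group == "normal", ldl_value] < 150))
})
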