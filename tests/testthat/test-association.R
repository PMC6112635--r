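# shared small synthetic analysis set, built once
adata_fix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pop <- small_pop()
    rec <- filter_ldl_measurements(pop$labs, pop$codes, pop$meds,
                                   pop$patients)
    cohort <- assign_groups(rec)
    covars <- derive_covariates(pop$patients, pop$labs, pop$codes,
                                pop$meds)
    inc <- cohort[group %in% c("low", "normal")]
    calls <- t2dm_algorithm(pop$codes, pop$labs, pop$meds,
                            patient_ids = inc$patient_id)
    cache <<- list(pop = pop, rec = rec, cohort = cohort, covars = covars,
                   adata = build_analysis_data(inc, calls, covars))
    cache
  }
})

test_that("the Woolf odds ratio reproduces the published validation table", {
  r <- odds_ratio_woolf(518, 2896, 2968, 26657)
  expect_equal(round(r$or_estimate, 2), 1.61)
  expect_equal(round(r$ci_low, 2), 1.45)
  expect_equal(round(r$ci_high, 2), 1.78)
  expect_lt(r$p_value, 2e-16)
  expect_identical(r$n_total, 33039L)
})

test_that("the Woolf interval is symmetric on the log scale and matches the closed form", {
  r <- odds_ratio_woolf(10, 10, 10, 10)
  expect_equal(r$or_estimate, 1)
  expect_equal(log(r$ci_low), -log(r$ci_high))

  # independent closed-form recomputation
  r2 <- odds_ratio_woolf(5, 5, 5, 5)
  lor <- log((5 * 5) / (5 * 5))
  se <- sqrt(1 / 5 + 1 / 5 + 1 / 5 + 1 / 5)
  expect_equal(r2$or_estimate, exp(lor), tolerance = 1e-12)
  expect_equal(r2$ci_low, exp(lor - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r2$ci_high, exp(lor + qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r2$p_value, 2 * pnorm(-abs(lor / se)), tolerance = 1e-12)
})

test_that("zero cells error unless the continuity correction is requested", {
  expect_error(odds_ratio_woolf(0, 10, 10, 10), "continuity")
  r <- odds_ratio_woolf(0, 10, 10, 10, continuity = TRUE)
  expect_equal(r$or_estimate, (0.5 * 10.5) / (10.5 * 10.5))
})

test_that("single-predictor logistic regression equals the cross-product ratio", {
  dd <- expand_2x2(518, 2896, 2968, 26657)
  w <- odds_ratio_woolf(518, 2896, 2968, 26657)
  f <- fit_logistic(dd)
  expect_true(f$converged)
  expect_equal(f$or_estimate, w$or_estimate, tolerance = 1e-6)
  expect_equal(f$ci_low, w$ci_low, tolerance = 1e-5)
  expect_equal(f$ci_high, w$ci_high, tolerance = 1e-5)
})

test_that("degenerate outcomes raise a separation error", {
  dd <- data.table(outcome = rep(0L, 50), exposure = rep(c(0L, 1L), 25))
  expect_error(fit_logistic(dd), "separation")
})

test_that("BMI and LDL stratum boundaries follow the stated conventions", {
  expect_identical(bmi_category(c(18.4, 18.5, 24.9, 25, 29.9, 30, NA)),
                   c("underweight", "normal", "normal", "overweight",
                     "overweight", "obese", NA))
})

test_that("the Bonferroni threshold and gate come from the six phecodes", {
  fx <- adata_fix()
  cohort <- split_phases(fx$cohort, seed = 11)
  scr <- discovery_screen(cohort, fx$pop$codes, fx$covars,
                          load_phecode_map())
  expect_equal(scr$threshold, 0.05 / 6)
  expect_equal(round(scr$threshold, 4), 0.0083)
  expect_identical(nrow(scr$results), 6L)
  expect_identical(scr$results$phenotype_id, T2DM_PHECODES)
  pmin_obs <- suppressWarnings(min(scr$results$p_value, na.rm = TRUE))
  expect_identical(scr$gate, pmin_obs < scr$threshold)
})

test_that("stratified fits partition the sample as documented", {
  fx <- adata_fix()
  adata <- fx$adata
  full <- suppressWarnings(fit_logistic(adata,
                                        adjust = adjustment_set("full")))
  st <- suppressWarnings(stratified_analysis(adata))
  n_of <- function(lab) st[stratum == lab, n_total]
  expect_equal(n_of("sex:female") + n_of("sex:male"), full$n_total)
  n_other <- adata[race == "other", .N]
  expect_equal(n_of("race:european_ancestry") +
                 n_of("race:african_ancestry"), full$n_total - n_other)
  n_under <- adata[!is.na(bmi_median) & bmi_median < 18.5, .N]
  expect_equal(n_of("bmi:normal") + n_of("bmi:overweight") +
                 n_of("bmi:obese"), full$n_total - n_under)
  n_normal_grp <- adata[exposure == 0L, .N]
  expect_equal(n_of("ldl:<40") + n_of("ldl:40-60"),
               full$n_total + n_normal_grp)
})

test_that("LDL refinement splits the low group at 40 mg/dl", {
  set.seed(5)
  n_norm <- 120; n_lt <- 30; n_in <- 50
  mk <- function(n, expo, ldl) data.table(
    patient_id = sprintf("S%03d", seq_len(n)) , exposure = expo,
    outcome = rbinom(n, 1, 0.3), median_ldl = ldl,
    age_years = runif(n, 20, 70), sex = sample(c("female", "male"), n, TRUE),
    race = "european_ancestry", bmi_median = runif(n, 20, 35),
    ehr_length_years = runif(n, 1, 15), hdl_median = runif(n, 40, 60),
    tg_median = runif(n, 60, 150))
  adata <- rbind(mk(n_norm, 0L, 110), mk(n_lt, 1L, 39.9),
                 mk(n_in, 1L, 40.0))
  st <- suppressWarnings(stratified_analysis(adata))
  expect_equal(st[stratum == "ldl:<40", n_total], n_norm + n_lt)
  expect_equal(st[stratum == "ldl:40-60", n_total], n_norm + n_in)
})

test_that("the interaction test needs at least two levels", {
  fx <- adata_fix()
  expect_error(interaction_test(fx$adata[sex == "female"], "sex"),
               "single level")
  res <- interaction_test(fx$adata, "sex")
  expect_identical(res$df, 1L)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  res_race <- interaction_test(fx$adata, "race")
  expect_identical(res_race$df, 2L)
})

test_that("sensitivity filters drop exactly the documented patients", {
  fx <- adata_fix()
  pmap <- load_phecode_map()
  base <- suppressWarnings(sensitivity_suite(
    fx$adata, fx$rec, fx$pop$codes, fx$pop$labs, fx$pop$meds,
    fx$pop$patients, pmap))
  dropped <- attr(base, "dropped")

  # filter 1 removes precisely the single-measurement patients
  expect_setequal(dropped[["1_min2_ldl"]],
                  fx$adata[n_ldl < 2, patient_id])
  # cumulative nesting of the statin-indication family
  expect_true(all(dropped[["2a_no_statin_indication"]] %in%
                    dropped[["2b_no_renal_transplant"]]))
  expect_true(all(dropped[["2b_no_renal_transplant"]] %in%
                    dropped[["2c_no_stroke_pvd"]]))

  # pick patients untouched by any natural filter, then inject conditions
  clean <- setdiff(fx$adata$patient_id, unique(unlist(dropped)))
  p <- clean[1:5]
  first_ldl <- fx$rec[excluded == FALSE, .(d0 = min(date)), by = patient_id]
  d0 <- function(id) first_ldl[patient_id == id, d0]

  labs2 <- rbind(fx$pop$labs,
                 mk_lab(p[1], d0(p[1]), "egfr", 29),
                 mk_lab(p[2], d0(p[2]), "egfr", 30))
  codes2 <- rbind(fx$pop$codes,
                  mk_codes(p[3], d0(p[3]) + 35, "410.90"),
                  mk_codes(p[4], d0(p[4]) + 25, "410.90"))
  meds2 <- rbind(fx$pop$meds, mk_meds(p[5], d0(p[5]), "ezetimibe"))
  s2 <- suppressWarnings(sensitivity_suite(
    fx$adata, fx$rec, codes2, labs2, meds2, fx$pop$patients, pmap))
  dr2 <- attr(s2, "dropped")
  expect_true(p[1] %in% dr2[["2b_no_renal_transplant"]])   # eGFR 29
  expect_false(p[2] %in% dr2[["2b_no_renal_transplant"]])  # eGFR 30
  expect_false(p[3] %in% dr2[["2a_no_statin_indication"]]) # MI at day 35
  expect_true(p[4] %in% dr2[["2a_no_statin_indication"]])  # MI at day 25
  expect_true(p[5] %in% dr2[["3_no_ezetimibe"]])

  # the under-18 filter keys on age at the median-LDL date
  born <- merge(fx$adata[, .(patient_id, median_ldl_date)],
                fx$pop$patients[, .(patient_id, birth_date)],
                by = "patient_id")
  expect_setequal(
    dropped[["4_adults_only"]],
    born[as.numeric(median_ldl_date - birth_date) / 365.25 < 18,
         patient_id])
})
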