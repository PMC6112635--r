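#!/usr/bin/env Rscript
# Stage 3: phenotyping.
#
# Phase 1: case/control/excluded status for the six T2DM phecodes among
# discovery patients, with the age/race/sex-adjusted screen and its
# Bonferroni gate (0.05 / 6 = 0.0083). Phase 2: the algorithmic T2DM
# classifier (codes + medications + glucose/HbA1c, abstaining when
# unclassifiable) on the validation patients, plus analysis covariates.

suppressMessages({library(lowldl); library(data.table)})
pop <- read_population("results/data")
cohort <- fread("results/cohort.csv")
cohort[, median_ldl_date := as.Date(median_ldl_date)]

covars <- derive_covariates(pop$patients, pop$labs, pop$codes, pop$meds)
fwrite(covars, "results/covariates.csv")

pmap <- load_phecode_map()
scr <- discovery_screen(cohort, pop$codes, covars, pmap)
fwrite(scr$results, "results/discovery_screen.csv")
jsonlite::write_json(list(threshold = scr$threshold, gate = scr$gate),
                     "results/discovery_gate.json", auto_unbox = TRUE)
cat("Discovery screen (age/race/sex adjusted):\n")
print(scr$results[, .(phenotype_id, or_estimate = round(or_estimate, 2),
                      p_value = signif(p_value, 3), n_cases)],
      row.names = FALSE)
cat(sprintf("Bonferroni threshold %.4f; gate %s.\n", scr$threshold,
            if (scr$gate) "PASSED - proceed to validation" else "FAILED"))

vali <- cohort[phase == "validation"]
calls <- t2dm_algorithm(pop$codes, pop$labs, pop$meds,
                        patient_ids = vali$patient_id)
fwrite(calls, "results/phenotypes.csv")
cat(sprintf("\nValidation T2DM algorithm: %d cases, %d controls, %d unclassifiable of %d.\n",
            sum(calls$status == "case"), sum(calls$status == "control"),
            sum(calls$status == "excluded"), nrow(calls)))
cat("Wrote results/discovery_screen.csv, results/phenotypes.csv, results/covariates.csv\n")
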