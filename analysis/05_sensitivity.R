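#!/usr/bin/env Rscript
# Stage 5: sensitivity analyses.
#
# Re-runs the fully adjusted validation model after each restriction:
# >= 2 LDL-C measurements; no prior statin indication (diabetes/ischemic
# heart disease codes within 30 days of the first eligible LDL-C); further
# no advanced renal disease (phecodes 585.3x or eGFR <= 29) or transplant;
# further no stroke/TIA/PVD codes; no ezetimibe ever; adults only at the
# median-LDL date.

suppressMessages({library(lowldl); library(data.table)})
pop <- read_population("results/data")
cohort <- fread("results/cohort.csv")
cohort[, median_ldl_date := as.Date(median_ldl_date)]
rec <- fread("results/ldl_records.csv")
rec[, date := as.Date(date)]
calls <- fread("results/phenotypes.csv")
covars <- fread("results/covariates.csv")

adata <- build_analysis_data(cohort[phase == "validation"], calls, covars)
sens <- sensitivity_suite(adata, rec, pop$codes, pop$labs, pop$meds,
                          pop$patients, load_phecode_map())
fwrite(sens, "results/sensitivity.csv")

cat("Sensitivity analyses (fully adjusted model after each restriction):\n")
print(sens[, .(filter = stratum, or = round(or_estimate, 2),
               ci = sprintf("%.2f-%.2f", ci_low, ci_high),
               p = signif(p_value, 3), n_total, n_dropped)],
      row.names = FALSE)
cat("\nWrote results/sensitivity.csv\n")
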