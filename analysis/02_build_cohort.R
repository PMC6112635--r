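#!/usr/bin/env Rscript
# Stage 2: LDL-C eligibility filtering and cohort assignment.
#
# Derives Friedewald LDL-C per lipid panel, applies the measurement
# exclusions (inpatient, age < 5, albumin < 3 g/dl within 30 days,
# post-statin, triglycerides > 400), assigns low / normal / excluded groups
# from per-patient medians, and splits included patients 1/3 discovery vs
# 2/3 validation.

suppressMessages({library(lowldl); library(data.table); library(jsonlite)})
SEED <- 1L
pop <- read_population("results/data")

rec <- filter_ldl_measurements(pop$labs, pop$codes, pop$meds, pop$patients)
cohort <- assign_groups(rec)
cohort <- split_phases(cohort, seed = SEED)
att <- attrition_report(rec, cohort)

fwrite(rec, "results/ldl_records.csv")
fwrite(cohort, "results/cohort.csv")
write_json(att, "results/attrition.json", auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("%d LDL determinations; %d eligible after filtering.\n",
            att$n_measurements, att$n_measurements_eligible))
cat("Measurement exclusions:\n")
for (nm in names(att$measurement_exclusions))
  cat(sprintf("  %-20s %6d\n", nm, att$measurement_exclusions[[nm]]))
cat(sprintf("\nGroups: low %s, normal %s, excluded %s.\n",
            att$patients_by_group$low, att$patients_by_group$normal,
            att$patients_by_group$excluded))
cat(sprintf("Phases: discovery %s, validation %s.\n",
            att$patients_by_phase$discovery,
            att$patients_by_phase$validation))
cat("Wrote results/cohort.csv, results/ldl_records.csv, results/attrition.json\n")
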