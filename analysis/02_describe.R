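#!/usr/bin/env Rscript
# Step 2 — inclusion criteria and descriptive analysis.
#
# Reads the cohort produced by 01_simulate.R, applies the two inclusion
# criteria (>= 1 INR result and >= 1 VKA administration day), and
# writes the descriptive summary of the analyzed subcohort.

suppressMessages({library(spcddi); library(jsonlite)})

data_dir <- "results/data"
cohort <- read_cohort(file.path(data_dir, "stays.csv"),
                      file.path(data_dir, "administrations.csv"),
                      file.path(data_dir, "labs.csv"))
cat("Read:", nrow(cohort$stays), "stays\n")

inc <- apply_inclusion_criteria(cohort)
cat(sprintf("Included: %d of %d stays (%.2f%%)\n",
            inc$n_retained, inc$n_total, inc$retained_pct))

d <- describe_cohort(inc$cohort)
print(d)

dir.create("results", showWarnings = FALSE)
write_json(list(
  n_total = inc$n_total, n_retained = inc$n_retained,
  retained_pct = inc$retained_pct,
  age_mean = d$age_mean, age_sd = d$age_sd,
  los_median = d$los_median, los_iqr = d$los_iqr,
  deaths_n = d$deaths_n, deaths_pct = d$deaths_pct,
  sex = d$sex, vka_molecule = d$vka_molecule
), "results/descriptives.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/descriptives.json\n")
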