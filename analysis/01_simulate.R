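#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study cohort.
#
# The real multi-hospital EHR database behind the VKA alert-filtering
# analysis is not public, so the workflow runs on a synthetic cohort
# with the same structure: 4047 analyzed stays, fluindione-dominant VKA
# mix, daily drug administrations and labs. Eight companion drugs from
# the rulebook are injected with known ground-truth effects (a mix of
# null, protective and risk odds ratios) so that every later step can
# be checked against truth.json.

suppressMessages(library(spcddi))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

drugs <- data.frame(
  label = c("tramadol", "amiodarone", "acetaminophen", "furosemide",
            "rifampicin", "omeprazole", "ciprofloxacin", "allopurinol"),
  atc_code = c("N02AX02", "C01BD01", "N02BE01", "C03CA01",
               "J04AB02", "A02BC01", "J01MA02", "M04AA01"),
  direction = c("potentiates_vka", "potentiates_vka", "potentiates_vka",
                "inhibits_vka", "inhibits_vka", "potentiates_vka",
                "potentiates_vka", "potentiates_vka"),
  exposure_prevalence = c(0.12, 0.10, 0.15, 0.20, 0.03, 0.06, 0.04, 0.05),
  true_log_or_initiation = log(c(0.65, 1.0, 0.7, 0.4, 1.0, 1.0, 2.2, 0.6)),
  true_log_or_discontinuation = log(c(0.6, 1.0, 0.8, 1.0, 1.0, 0.5, 1.0, 1.0)))

cfg <- sim_config(n_stays = 4047, seed = 20210120, drug_specs = drugs)
sim <- simulate_cohort(cfg, out_dir = out_dir)

cat("Simulated cohort written to", out_dir, "\n")
print(sim$cohort)
cat("\nRealized exposure counts (ground truth):\n")
print(sim$truth$exposure_counts)
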