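#!/usr/bin/env Rscript
# Step 3 — per-rule odds-ratio cascade.
#
# Loads the shipped rulebook (149 literature entries -> 141 curated
# (drug, direction) entries -> 282 initiation/discontinuation rules),
# builds each rule's exposed/nonexposed observation windows over the
# analyzed subcohort, and estimates the unadjusted (Fisher exact),
# adjusted and stepwise odds ratios for every rule with at least 3
# exposed stays.

suppressMessages({library(spcddi); library(data.table)})

data_dir <- "results/data"
cohort <- read_cohort(file.path(data_dir, "stays.csv"),
                      file.path(data_dir, "administrations.csv"),
                      file.path(data_dir, "labs.csv"))
inc <- apply_inclusion_criteria(cohort)

entries <- load_rulebook(synthetic_rulebook_path())
cur <- curate_rulebook(entries)
rules <- expand_rules(cur$entries)
cat(sprintf("Rulebook: %d raw, %d excluded (no ATC), %d merged -> %d entries, %d rules\n",
            cur$report$n_loaded, cur$report$n_excluded_unmappable,
            cur$report$n_merged, cur$report$n_curated, nrow(rules)))

t0 <- Sys.time()
est <- estimate_all_rules(inc$cohort, rules)
cat(sprintf("Estimated %d rules in %s\n", length(est),
            format(round(Sys.time() - t0, 1))))

tab <- estimates_table(est)
cat(sprintf("%d rules estimated, %d with fewer than 3 exposed stays\n",
            sum(tab$status == "estimated"),
            sum(tab$status == "insufficient_data")))
cat("\nEstimated rules:\n")
print(tab[status == "estimated",
          .(label, phase, outcome, n, or_unadjusted, or_adjusted, or_stepwise)])

fwrite(tab, "results/estimates.csv")
cat("Wrote results/estimates.csv\n")
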