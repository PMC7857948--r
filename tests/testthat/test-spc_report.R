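# Minimal hand-built rule_estimate objects for decision-layer tests.
mk_estimate <- function(rule_id = "r1", n_exposed = 10L, status = "estimated",
                        or = c(0.5, 0.3, 0.8), method = "logistic_stepwise",
                        computable = TRUE, phase = "initiation") {
  e <- list(rule_id = rule_id, label = rule_id, phase = phase,
            expected_outcome = "INR_GE_HIGH", group = "other",
            n_exposed = n_exposed,
            table = c(a = 2L, b = n_exposed - 2L, c = 5L, d = 20L),
            status = status)
  if (status == "estimated") {
    res <- spcddi:::or_result(method, point = or[1], lower95 = or[2],
                              upper95 = or[3], computable = computable)
    e$or_unadjusted <- spcddi:::or_result("fisher_unadjusted", point = or[1],
                                          lower95 = or[2], upper95 = or[3])
    e$or_adjusted <- res
    e$or_stepwise <- res
  }
  class(e) <- "rule_estimate"
  e
}

test_that("rule classification follows the confidence-limit invariants", {
  cfg <- ddi_config()
  # too few exposed stays: alert stays on regardless of any estimate
  d <- classify_rule(mk_estimate(n_exposed = 2L, status = "insufficient_data"), cfg)
  expect_equal(d$classification, "insufficient_data")
  expect_true(d$alert_active)
  # protective: upper limit below 1 (tramadol-style 0.63 (0.47, 0.82))
  d <- classify_rule(mk_estimate(or = c(0.63, 0.47, 0.82)), cfg)
  expect_equal(d$classification, "significant_protective")
  expect_false(d$alert_active)
  # CI straddling 1 (amiodarone-style 0.83 (0.67, 1.02)): no association
  d <- classify_rule(mk_estimate(or = c(0.83, 0.67, 1.02)), cfg)
  expect_equal(d$classification, "no_significant_association")
  # risk: lower limit above 1 keeps the alert on
  d <- classify_rule(mk_estimate(or = c(2.4, 1.3, 4.4)), cfg)
  expect_equal(d$classification, "significant_risk")
  expect_true(d$alert_active)
})

test_that("a noncomputable basis falls back to the unadjusted OR", {
  e <- mk_estimate(or = c(0.5, 0.3, 0.8))
  e$or_stepwise <- spcddi:::or_result("logistic_stepwise", point = 0,
                                      computable = FALSE, notes = "separation")
  d <- classify_rule(e, ddi_config())
  expect_equal(d$basis, "unadjusted (fallback)")
  expect_equal(d$classification, "significant_protective")
  # all tiers noncomputable: classified no-association with a warning note
  e$or_unadjusted <- spcddi:::or_result("fisher_unadjusted", computable = FALSE)
  d <- classify_rule(e, ddi_config())
  expect_equal(d$classification, "no_significant_association")
  expect_match(d$notes, "no computable")
})

test_that("every rule gets exactly one class and risk is never deactivated", {
  set.seed(99)
  ests <- lapply(1:60, function(i) {
    if (i %% 7 == 0) return(mk_estimate(sprintf("r%02d", i), n_exposed = 2L,
                                        status = "insufficient_data"))
    p <- exp(stats::rnorm(1, 0, 0.6)); w <- exp(stats::runif(1, 0.2, 1))
    mk_estimate(sprintf("r%02d", i), or = c(p, p / w, p * w))
  })
  dec <- classify_all_rules(ests, ddi_config())
  expect_equal(nrow(dec), 60L)
  cnt <- table(dec$classification)
  expect_equal(sum(cnt), 60L)
  expect_true(all(dec$classification %in%
    c("insufficient_data", "no_significant_association",
      "significant_protective", "significant_risk")))
  expect_true(all(dec[classification == "significant_risk", alert_active]))
  expect_true(all(dec[classification == "insufficient_data", alert_active]))
  expect_false(any(dec[classification == "significant_protective", alert_active]))
})

test_that("reports render the published table shape and a JSON twin", {
  ests <- list(
    mk_estimate("sig", or = c(0.5, 0.3, 0.8)),
    mk_estimate("nosig", or = c(0.9, 0.6, 1.4)),
    mk_estimate("thin", n_exposed = 2L, status = "insufficient_data"))
  # a noncomputable adjusted CI renders as the footnoted pattern
  ests[[1]]$or_adjusted <- spcddi:::or_result("logistic_adjusted", point = 0,
                                              computable = FALSE)
  dec <- classify_all_rules(ests, ddi_config())
  dir <- withr::local_tempdir()
  paths <- render_report(dec, ests, dir = dir)
  md <- readLines(paths["report_md"])
  expect_true(any(grepl("\\| sig \\|", md)))       # significant rule listed
  expect_false(any(grepl("\\| nosig \\|", md)))    # nonsignificant only in summary
  expect_true(any(grepl("0\\^d", md)))
  js <- jsonlite::read_json(paths["report_json"])
  expect_equal(js$n_rules, 3L)
  expect_length(js$rules, 3L)
  # empty decision set still renders
  p2 <- render_report(dec[0], list(), dir = withr::local_tempdir())
  expect_true(file.exists(p2["report_md"]))
})

test_that("the pipeline runs end to end, deterministically, and alpha widens CIs", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_stays = 250, seed = 17), out_dir = dir)
  book <- file.path(dir, "rulebook.csv")
  file.copy(synthetic_rulebook_path(), book)
  run1 <- run_pipeline(file.path(dir, "stays.csv"),
                       file.path(dir, "administrations.csv"),
                       file.path(dir, "labs.csv"), book,
                       out_dir = file.path(dir, "out"), quiet = TRUE)
  expect_equal(nrow(run1$decisions), 282L)
  expect_true(file.exists(run1$report_paths["report_md"]))
  run2 <- run_pipeline(file.path(dir, "stays.csv"),
                       file.path(dir, "administrations.csv"),
                       file.path(dir, "labs.csv"), book, quiet = TRUE)
  expect_identical(run1$decisions, run2$decisions)
  # a wider alpha can only shrink the set of nonsignificant rules
  run10 <- run_pipeline(file.path(dir, "stays.csv"),
                        file.path(dir, "administrations.csv"),
                        file.path(dir, "labs.csv"), book,
                        config = ddi_config(alpha = 0.10), quiet = TRUE)
  n05 <- sum(run1$decisions$classification == "no_significant_association")
  n10 <- sum(run10$decisions$classification == "no_significant_association")
  expect_lte(n10, n05)
})
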