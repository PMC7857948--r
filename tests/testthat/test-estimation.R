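test_that("the exact OR agrees with fisher.test and with the grid oracle", {
  tables <- list(c(2, 8, 4, 36), c(5, 5, 5, 5), c(3, 7, 10, 80),
                 c(1, 19, 7, 173), c(9, 1, 2, 14), c(4, 4, 1, 30))
  for (tb in tables) {
    mine <- fisher_or(tb)
    ft <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))
    expect_lt(abs(log(mine$point) - log(unname(ft$estimate))), 1e-3)
    # fisher.test inverts the same tails with a looser root tolerance,
    # so the limits agree only approximately; the precise check is
    # against the oracle tails below
    expect_lt(abs(log(mine$lower95) - log(ft$conf.int[1])), 0.03)
    expect_lt(abs(log(mine$upper95) - log(ft$conf.int[2])), 0.03)
    # independent route: staged grid search on the conditional likelihood
    expect_lt(abs(log(mine$point) - log(oracle_fisher_mle(tb[1], tb[2], tb[3], tb[4]))),
              1e-3)
    # the exact limits invert the conditional tails at alpha/2
    expect_lt(abs(oracle_tail(mine$upper95, tb[1], tb[2], tb[3], tb[4], "le") - 0.025),
              1e-6)
    expect_lt(abs(oracle_tail(mine$lower95, tb[1], tb[2], tb[3], tb[4], "ge") - 0.025),
              1e-6)
  }
})

test_that("degenerate cells give the published zero-cell reporting shape", {
  # a = 0: point 0, lower 0, finite one-sided upper (bosentan-style row)
  z <- fisher_or(c(0, 6, 50, 400))
  expect_true(z$computable)
  expect_equal(z$point, 0)
  expect_equal(z$lower95, 0)
  expect_true(is.finite(z$upper95) && z$upper95 > 0)
  # symmetric table: OR exactly 1, CI straddles it
  s <- fisher_or(c(5, 5, 5, 5))
  expect_equal(s$point, 1, tolerance = 1e-8)
  expect_true(s$lower95 < 1 && s$upper95 > 1)
  # b = 0: infinite point and upper limit, finite lower
  inf <- fisher_or(c(12, 0, 3, 40))
  expect_true(is.infinite(inf$point) && is.infinite(inf$upper95))
  expect_true(is.finite(inf$lower95))
  # no outcome variation: not computable
  expect_false(fisher_or(c(0, 10, 0, 30))$computable)
  expect_false(fisher_or(c(10, 0, 30, 0))$computable)
})

test_that("adding an exposed-with-outcome stay never lowers the estimate", {
  set.seed(11)
  for (i in 1:25) {
    tb <- random_table(30)
    p0 <- fisher_or(tb)$point
    tb2 <- tb + c(1, 0, 0, 0)
    expect_gte(fisher_or(tb2)$point, p0 - 1e-9)
  }
})

test_that("with no covariate variation the adjusted OR is the cross-product OR", {
  prof <- reference_profiles(1:100)
  y <- c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 10), rep(FALSE, 80))
  ex <- c(rep(TRUE, 10), rep(FALSE, 90))
  fit <- adjusted_or(y, ex, prof)
  expect_equal(fit$point, 3 * 80 / (7 * 10), tolerance = 1e-6)
  set.seed(22)
  for (i in 1:8) {
    tb <- random_table(40)
    y <- rep(c(TRUE, FALSE, TRUE, FALSE), tb)
    ex <- rep(c(TRUE, TRUE, FALSE, FALSE), tb)
    prof <- reference_profiles(seq_along(y))
    expect_equal(adjusted_or(y, ex, prof)$point,
                 tb[["a"]] * tb[["d"]] / (tb[["b"]] * tb[["c"]]),
                 tolerance = 1e-6)
  }
})

test_that("separation is detected and flagged, not reported as a CI", {
  # zero outcomes among the exposed: the exposure coefficient diverges
  n <- 60
  prof <- reference_profiles(1:n)
  y <- c(rep(FALSE, 30), rep(TRUE, 12), rep(FALSE, 18))
  ex <- c(rep(TRUE, 30), rep(FALSE, 30))
  prof$ntprobnp_class <- factor(
    c(rep("LT450", 30), rep("GE450", 8), rep("LT450", 22)),
    levels = c("LT450", "GE450"))
  fit <- adjusted_or(y, ex, prof)
  expect_false(fit$computable)
  expect_match(fit$notes, "separation|nonconvergence")
  expect_equal(fit$point, 0)              # exposure coefficient -> -Inf
  expect_match(format_or(fit), "\\^d")    # renders as the footnoted 0^d
  # constant outcome is not computable either
  expect_false(adjusted_or(rep(FALSE, 20), rep(c(TRUE, FALSE), 10),
                           reference_profiles(1:20))$computable)
})

test_that("stepwise selection drops noise covariates and keeps prognostic ones", {
  set.seed(33)
  n <- 3000
  ex <- stats::runif(n) < 0.3
  # pure-noise covariates: stepwise should fall back to exposure alone
  prof <- reference_profiles(1:n)
  prof$albumin_class <- factor(sample(c("GE30", "LT30"), n, TRUE),
                               levels = c("GE30", "LT30"))
  prof$tsh_class <- factor(sample(c("NORMAL_0_5_TO_5", "ABNORMAL"), n, TRUE),
                           levels = c("NORMAL_0_5_TO_5", "ABNORMAL"))
  y <- stats::runif(n) < stats::plogis(-1.5 + 0.5 * ex)
  s <- stepwise_or(y, ex, prof)
  u <- fisher_or(c(sum(y & ex), sum(!y & ex), sum(y & !ex), sum(!y & !ex)))
  # noise covariates cannot confound: stepwise ~ unadjusted
  expect_equal(log(s$point), log(u$point), tolerance = 0.05)
  # strongly prognostic covariate: retained, stepwise equals adjusted
  y2 <- stats::runif(n) < stats::plogis(-2 + 0.4 * ex +
                                          2 * (prof$albumin_class == "LT30"))
  a2 <- adjusted_or(y2, ex, prof)
  s2 <- stepwise_or(y2, ex, prof)
  expect_match(s2$notes, "albumin_class")
  expect_equal(s2$point, a2$point, tolerance = 0.02)
})

test_that("the rule cascade partitions rules by the exposed-stay minimum", {
  inc <- apply_inclusion_criteria(make_fixture_cohort())$cohort
  rules <- make_fixture_rules()
  est <- estimate_all_rules(inc, rules)
  expect_length(est, 2L)
  # discontinuation rule sits exactly at the n = 3 boundary: estimated
  disc <- est[[which(vapply(est, `[[`, "", "phase") == "discontinuation")]]
  expect_equal(disc$n_exposed, 3L)
  expect_equal(disc$status, "estimated")
  expect_true(!is.null(disc$or_unadjusted))
  # raising the minimum to 4 flags it insufficient, with no ORs
  est4 <- estimate_all_rules(inc, rules,
                             config = ddi_config(min_exposed_stays = 4L))
  disc4 <- est4[[which(vapply(est4, `[[`, "", "phase") == "discontinuation")]]
  expect_equal(disc4$status, "insufficient_data")
  expect_null(disc4$or_unadjusted)
  # full rulebook end to end on a small simulated cohort: one estimate
  # per rule, every rule classified either estimated or insufficient
  sim <- simulate_cohort(sim_config(n_stays = 120, seed = 5))
  inc2 <- apply_inclusion_criteria(sim$cohort)$cohort
  book <- curate_rulebook(load_rulebook(synthetic_rulebook_path()))$entries
  allrules <- expand_rules(book)
  est_all <- estimate_all_rules(inc2, allrules)
  expect_length(est_all, nrow(allrules))
  stat <- vapply(est_all, `[[`, "", "status")
  expect_true(all(stat %in% c("estimated", "insufficient_data")))
  nexp <- vapply(est_all, `[[`, integer(1), "n_exposed")
  expect_true(all((nexp < 3) == (stat == "insufficient_data")))
})
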