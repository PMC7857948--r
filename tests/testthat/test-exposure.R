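cfg <- ddi_config()
rules <- make_fixture_rules()
init_rule <- rules[1]
disc_rule <- rules[2]

test_that("exposure classification follows the co-administration rules", {
  st <- mk_stay("A", 12)
  adm <- rbind(mk_adm("A", 1:10, "B01AA03"), mk_adm("A", 3:6, "N02AX02"))
  expect_equal(classify_exposure(st, adm, init_rule, cfg), "exposed")
  # drug stops day 6 < VKA last day 10: discontinuation-exposed
  expect_equal(classify_exposure(st, adm, disc_rule, cfg), "exposed")
  # no overlapping day: nonexposed in both phases
  adm2 <- rbind(mk_adm("A", 1:5, "B01AA03"), mk_adm("A", 6:9, "N02AX02"))
  expect_equal(classify_exposure(st, adm2, init_rule, cfg), "nonexposed")
  expect_equal(classify_exposure(st, adm2, disc_rule, cfg), "nonexposed")
  # drug runs to the VKA's last day: not discontinuation-exposed
  adm3 <- rbind(mk_adm("A", 1:8, "B01AA03"), mk_adm("A", 5:8, "N02AX02"))
  expect_equal(classify_exposure(st, adm3, init_rule, cfg), "exposed")
  expect_equal(classify_exposure(st, adm3, disc_rule, cfg), "nonexposed")
})

test_that("window construction matches the hand-traced day arithmetic", {
  st <- mk_stay("A", 12)
  adm <- rbind(mk_adm("A", 1:10, "B01AA03"), mk_adm("A", 3:6, "N02AX02"))
  w <- build_window(st, adm, init_rule, "exposed", cfg)
  expect_equal(c(w$start_day, w$end_day), c(4L, 10L))  # 3+1, min(6+4, 12)
  w <- build_window(st, adm, disc_rule, "exposed", cfg)
  expect_equal(c(w$start_day, w$end_day), c(7L, 10L))  # 6+1, min(6+4, 10+4, 12)

  st2 <- mk_stay("B", 12)
  adm2 <- mk_adm("B", 2:5, "B01AA03")
  w <- build_window(st2, adm2, init_rule, "nonexposed", cfg)
  expect_equal(c(w$start_day, w$end_day), c(3L, 9L))  # 2+1, min(5+4, 12)

  # VKA on the discharge day only: start 8 > end 7, dropped
  st3 <- mk_stay("C", 7)
  adm3 <- mk_adm("C", 7, "B01AA03")
  w <- build_window(st3, adm3, init_rule, "nonexposed", cfg)
  expect_equal(w$exposure_status, "not_applicable")

  # only the first uninterrupted co-administration run counts
  st4 <- mk_stay("D", 20)
  adm4 <- rbind(mk_adm("D", 1:18, "B01AA03"),
                mk_adm("D", c(3, 4, 9, 10), "N02AX02"))
  w <- build_window(st4, adm4, init_rule, "exposed", cfg)
  expect_equal(c(w$start_day, w$end_day), c(4L, 8L))  # run 3-4, end 4+4
})

test_that("outcome detection is inclusive at the thresholds and window bounds", {
  win <- list(stay_id = "A", rule_id = "r", exposure_status = "exposed",
              start_day = 4L, end_day = 10L)
  expect_true(detect_outcome(win, mk_lab("A", 7, "INR", 5.0), init_rule, cfg))
  expect_false(detect_outcome(win, mk_lab("A", 3, "INR", 6.2), init_rule, cfg))
  expect_false(detect_outcome(win, mk_lab("A", c(5, 6), "INR", c(2.1, 2.9)),
                              disc_rule, cfg))
  expect_true(detect_outcome(win, mk_lab("A", 10, "INR", 1.5), disc_rule, cfg))
  expect_false(detect_outcome(win, mk_lab("A", 11, "INR", 1.2), disc_rule, cfg))
})

test_that("assembled tables count each applicable stay exactly once", {
  inc <- apply_inclusion_criteria(make_fixture_cohort())
  t1 <- assemble_table(inc$cohort, init_rule, cfg)
  expect_equal(unname(t1$table), c(1L, 3L, 1L, 2L))
  expect_equal(t1$n_exposed, 4L)
  # a + b + c + d = applicable stays
  n_appl <- sum(t1$windows$exposure_status != "not_applicable")
  expect_equal(sum(t1$table), n_appl)
  t2 <- assemble_table(inc$cohort, disc_rule, cfg)
  expect_equal(unname(t2$table), c(1L, 2L, 1L, 3L))
  expect_equal(t2$n_exposed, 3L)
})

test_that("tables match a brute-force enumeration on small random cohorts", {
  for (seed in 1:12) {
    ch <- random_cohort(n_stays = sample(5:20, 1), seed = 700 + seed)
    inc <- apply_inclusion_criteria(ch)$cohort
    for (r in 1:2) {
      got <- assemble_table(inc, rules[r], cfg)$table
      want <- brute_force_table(inc, rules[r], cfg)
      expect_equal(got, want,
                   info = sprintf("seed %d, phase %s", seed, rules$phase[r]))
    }
  }
})

test_that("tables are invariant under record order and lag-monotone", {
  ch <- random_cohort(15, seed = 314)
  inc <- apply_inclusion_criteria(ch)$cohort
  perm <- structure(list(
    stays = inc$stays[sample(nrow(inc$stays))],
    administrations = inc$administrations[sample(nrow(inc$administrations))],
    labs = inc$labs[sample(nrow(inc$labs))],
    validation = inc$validation), class = "ddi_cohort")
  for (r in 1:2) {
    expect_equal(assemble_table(perm, rules[r], cfg)$table,
                 assemble_table(inc, rules[r], cfg)$table)
  }
  # shrinking the residual-action lag never enlarges a window
  for (off in c(3L, 2L, 1L, 0L)) {
    w_small <- spcddi:::rule_windows(inc, init_rule,
                                     ddi_config(offset_lag_days = off))
    w_big <- spcddi:::rule_windows(inc, init_rule,
                                   ddi_config(offset_lag_days = off + 1L))
    m <- merge(w_small, w_big, by = "stay_id", suffixes = c("_s", "_b"))
    appl <- m[exposure_status_s != "not_applicable"]
    expect_true(all(appl$end_day_s <= appl$end_day_b))
    expect_true(all(appl$start_day_s == appl$start_day_b))
    # windows stay inside the stay span
    span <- merge(w_small[exposure_status != "not_applicable"],
                  inc$stays[, .(stay_id, admission_day, discharge_day)],
                  by = "stay_id")
    expect_true(all(span$start_day >= span$admission_day))
    expect_true(all(span$end_day <= span$discharge_day))
  }
})
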