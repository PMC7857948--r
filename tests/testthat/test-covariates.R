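test_that("categorization follows the printed class boundaries", {
  cat_of <- function(v, an) categorize(v, an)$class
  expect_equal(cat_of(65, "AGE"), "LT70")
  expect_equal(cat_of(70, "AGE"), "70_79")
  expect_equal(cat_of(79, "AGE"), "70_79")
  expect_equal(cat_of(80, "AGE"), "GE80")
  expect_equal(cat_of(29.9, "ALBUMIN"), "LT30")
  expect_equal(cat_of(30, "ALBUMIN"), "GE30")
  expect_equal(cat_of(0.069, "PREALBUMIN"), "LT0_07")
  expect_equal(cat_of(0.07, "PREALBUMIN"), "0_07_0_10")
  expect_equal(cat_of(0.105, "PREALBUMIN"), "0_07_0_10")  # printed-label gap
  expect_equal(cat_of(0.11, "PREALBUMIN"), "GE0_11")
  expect_equal(cat_of(15, "CREATININE"), "LE15")
  expect_equal(cat_of(15.5, "CREATININE"), "16_24")       # printed-label gap
  expect_equal(cat_of(24.9, "CREATININE"), "16_24")
  expect_equal(cat_of(25, "CREATININE"), "GE25")
  expect_equal(cat_of(249, "TRANSAMINASE"), "LT250")
  expect_equal(cat_of(250, "ASAT"), "GE250")
  expect_equal(cat_of(0.5, "TSH"), "NORMAL_0_5_TO_5")
  expect_equal(cat_of(5, "TSH"), "NORMAL_0_5_TO_5")
  expect_equal(cat_of(6, "TSH"), "ABNORMAL")
  expect_equal(cat_of(0.4, "TSH"), "ABNORMAL")
  expect_equal(cat_of(449, "NTPROBNP"), "LT450")
  expect_equal(cat_of(450, "NTPROBNP"), "GE450")
  expect_error(categorize(-1, "ALBUMIN"), "negative")
})

test_that("missing values impute the reference class with a flag", {
  for (an in c("AGE", "ALBUMIN", "PREALBUMIN", "CREATININE",
               "TRANSAMINASE", "TSH", "NTPROBNP")) {
    r <- categorize(NA, an)
    expect_true(r$imputed)
    fld <- switch(an, AGE = "age_class", ALBUMIN = "albumin_class",
                  PREALBUMIN = "prealbumin_class",
                  CREATININE = "creatinine_class",
                  TRANSAMINASE = "transaminase_class", TSH = "tsh_class",
                  NTPROBNP = "ntprobnp_class")
    expect_equal(r$class, spcddi:::COVARIATE_LEVELS[[fld]][1L])
  }
})

test_that("profiles use the first in-stay measurement and are total", {
  inc <- apply_inclusion_criteria(make_fixture_cohort())$cohort
  prof <- build_profiles(inc)
  expect_equal(nrow(prof), nrow(inc$stays))
  # F01 has albumin 28 on day 2 then 33 on day 8: first value rules
  expect_equal(as.character(prof[stay_id == "F01", albumin_class]), "LT30")
  expect_false(prof[stay_id == "F01", imputed_albumin])
  # F06 has creatinine 30: highest class
  expect_equal(as.character(prof[stay_id == "F06", creatinine_class]), "GE25")
  # stays without covariate labs are fully imputed to reference
  expect_equal(as.character(prof[stay_id == "F02", albumin_class]), "GE30")
  expect_true(prof[stay_id == "F02", imputed_albumin])
  # no undefined category anywhere
  for (f in names(spcddi:::COVARIATE_LEVELS)) {
    expect_false(any(is.na(prof[[f]])), info = f)
  }
})

test_that("the transaminase class uses the larger of ASAT and ALAT", {
  ch <- ddi_cohort(
    mk_stay("T1", 8),
    mk_adm("T1", 1:8, "B01AA03"),
    rbind(mk_lab("T1", 2, "INR", 2.3),
          mk_lab("T1", 2, "ASAT", 40), mk_lab("T1", 2, "ALAT", 310)))
  prof <- build_profiles(ch)
  expect_equal(as.character(prof$transaminase_class), "GE250")
})

test_that("categorization is monotone in severity within each analyte", {
  grids <- list(
    AGE = seq(0, 110, by = 1),
    ALBUMIN = seq(5, 60, by = 0.5),
    CREATININE = seq(1, 90, by = 0.5),
    TRANSAMINASE = seq(5, 900, by = 5),
    NTPROBNP = seq(10, 9000, by = 50))
  severity <- list(
    AGE = c(LT70 = 1, `70_79` = 2, GE80 = 3),
    ALBUMIN = c(GE30 = 1, LT30 = 2),
    CREATININE = c(LE15 = 1, `16_24` = 2, GE25 = 3),
    TRANSAMINASE = c(LT250 = 1, GE250 = 2),
    NTPROBNP = c(LT450 = 1, GE450 = 2))
  for (an in names(grids)) {
    sev <- severity[[an]][vapply(grids[[an]],
                                 function(v) categorize(v, an)$class,
                                 character(1))]
    mono <- if (an == "ALBUMIN") all(diff(sev) <= 0) else all(diff(sev) >= 0)
    expect_true(mono, info = an)
  }
  # prealbumin severity decreases with the value
  sev <- c(GE0_11 = 1, `0_07_0_10` = 2, LT0_07 = 3)[
    vapply(seq(0.02, 0.3, by = 0.005),
           function(v) categorize(v, "PREALBUMIN")$class, character(1))]
  expect_true(all(diff(sev) <= 0))
  # TSH is two-sided: abnormal in both tails, normal between
  cls <- vapply(c(0.1, 0.49, 0.5, 2, 5, 5.1, 30),
                function(v) categorize(v, "TSH")$class, character(1))
  expect_equal(cls, c("ABNORMAL", "ABNORMAL", "NORMAL_0_5_TO_5",
                      "NORMAL_0_5_TO_5", "NORMAL_0_5_TO_5",
                      "ABNORMAL", "ABNORMAL"))
})
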