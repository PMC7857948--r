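# Independent oracles used to cross-check the package implementation.
# They deliberately use different machinery: dhyper-based weights and
# staged grid searches instead of uniroot on log-sum-exp expressions.

# Conditional likelihood of a 2x2 table at log odds ratio t, up to a
# constant, via the central hypergeometric density.
oracle_cond_loglik <- function(t, a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  x <- max(0, k - r2):min(k, r1)
  lw <- stats::dhyper(x, r1, r2, k, log = TRUE)
  a_idx <- match(a, x)
  (lw[a_idx] + t * a) - (max(lw + t * x) + log(sum(exp(lw + t * x - max(lw + t * x)))))
}

# Grid-search maximization of the conditional likelihood; four staged
# refinements take the log-scale precision to ~1e-5.
oracle_fisher_mle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  lo <- max(0, k - r2); hi <- min(k, r1)
  if (a <= lo) return(0)
  if (a >= hi) return(Inf)
  centre <- 0; width <- 20
  for (stage in 1:4) {
    grid <- seq(centre - width, centre + width, length.out = 81)
    ll <- vapply(grid, oracle_cond_loglik, numeric(1), a = a, b = b, c = c, d = d)
    centre <- grid[which.max(ll)]
    width <- width / 25
  }
  exp(centre)
}

# Tail probabilities of the noncentral hypergeometric at odds ratio psi,
# computed from dhyper weights with direct normalization.
oracle_tail <- function(psi, a, b, c, d, side = c("le", "ge")) {
  side <- match.arg(side)
  r1 <- a + b; r2 <- c + d; k <- a + c
  x <- max(0, k - r2):min(k, r1)
  lw <- stats::dhyper(x, r1, r2, k, log = TRUE) + x * log(psi)
  w <- exp(lw - max(lw))
  p <- w / sum(w)
  if (side == "le") sum(p[x <= a]) else sum(p[x >= a])
}

# Naive reimplementation of the per-rule contingency assembly, written
# directly from the window definitions with per-stay loops over the raw
# records. Used as the brute-force cross-check for small cohorts.
brute_force_table <- function(cohort, rule, config = spcddi::ddi_config()) {
  a <- b <- cc <- d <- 0L
  codes <- rule$atc_codes[[1L]]
  for (i in seq_len(nrow(cohort$stays))) {
    st <- as.list(cohort$stays[i, ])
    adm <- cohort$administrations[cohort$administrations$stay_id == st$stay_id, ]
    lb <- cohort$labs[cohort$labs$stay_id == st$stay_id, ]
    vka_days <- sort(unique(adm$day[substr(adm$atc_code, 1, nchar(config$vka_atc_prefix)) ==
                                      config$vka_atc_prefix]))
    if (rule$match_mode == "prefix") {
      hit <- rep(FALSE, nrow(adm))
      for (cd in codes) hit <- hit | substr(adm$atc_code, 1, nchar(cd)) == cd
    } else {
      hit <- adm$atc_code %in% codes
    }
    drug_days <- sort(unique(adm$day[hit]))
    co <- intersect(vka_days, drug_days)
    exposed <- length(co) > 0
    if (rule$phase == "discontinuation" && exposed) {
      exposed <- max(drug_days) < max(vka_days)
    }
    if (exposed) {
      if (rule$phase == "initiation") {
        co <- sort(co)
        run_end <- co[1]
        for (dd in co[-1]) { if (dd == run_end + 1) run_end <- dd else break }
        start <- co[1] + config$onset_lag_days
        end <- min(run_end + config$offset_lag_days, st$discharge_day)
      } else {
        dl <- max(drug_days)
        start <- dl + config$onset_lag_days
        end <- min(dl + config$offset_lag_days,
                   max(vka_days) + config$offset_lag_days, st$discharge_day)
      }
    } else {
      start <- min(vka_days) + config$onset_lag_days
      end <- min(max(vka_days) + config$offset_lag_days, st$discharge_day)
    }
    if (start > end) next
    outcome <- FALSE
    for (j in seq_len(nrow(lb))) {
      if (lb$analyte[j] != "INR") next
      if (lb$day[j] < start || lb$day[j] > end) next
      if (rule$expected_outcome == "INR_GE_HIGH" &&
          lb$value[j] >= config$inr_high_threshold) outcome <- TRUE
      if (rule$expected_outcome == "INR_LE_LOW" &&
          lb$value[j] <= config$inr_low_threshold) outcome <- TRUE
    }
    if (exposed && outcome) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (outcome) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}
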