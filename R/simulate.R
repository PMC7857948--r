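# Synthetic inpatient cohort generator. Cohorts have the statistical
# structure the analysis assumes: one VKA episode per stay, optional
# companion-drug co-administration, INR trajectories whose excursion
# odds follow a configurable logistic model on the analysis scale, and
# covariate labs with missingness. Ground truth is serialized so any
# estimator can be scored against it.

#' Simulation configuration
#'
#' Defaults emulate the analyzed VKA subcohort of a multi-hospital
#' inpatient database: mean age 75.9 y (SD 12.0), 58.2% women, median
#' length of stay 9 days (IQR 6-15), fluindione-dominant VKA mix.
#' Outcomes are generated at the observation-window level on the
#' logistic scale, so injected log odds ratios are exact on the scale
#' the analysis estimates.
#'
#' @param n_stays number of stays.
#' @param seed integer seed fixing all randomness.
#' @param age_mean,age_sd age distribution (years).
#' @param female_fraction proportion of women.
#' @param los_median,los_iqr length-of-stay summaries (days) matched
#'   numerically by a discretized lognormal.
#' @param vka_mix named probabilities over VKA ATC codes.
#' @param drug_specs data.frame with columns label, atc_code, direction
#'   ("potentiates_vka"/"inhibits_vka"), exposure_prevalence,
#'   true_log_or_initiation, true_log_or_discontinuation. Prevalences
#'   must sum to at most 1; each stay is exposed to at most one
#'   companion drug so that every injected odds ratio is exact
#'   marginally.
#' @param baseline_outcome_rate_high,baseline_outcome_rate_low
#'   reference-profile probabilities of an INR excursion at/above the
#'   high threshold and at/below the low threshold inside the window.
#' @param covariate_effects named numeric vector of per-class log odds
#'   ratios applied to both outcomes (names are "<field>:<class>").
#' @param abnormal_rates named list of per-analyte class probabilities
#'   used when drawing covariate lab values.
#' @param lab_missingness named per-analyte probability that the analyte
#'   is never measured during the stay.
#' @param inr_measurement_rate per-day probability of a routine INR
#'   measurement (one measurement is always guaranteed).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_stays = 1000L,
                       seed = 1L,
                       age_mean = 75.9, age_sd = 12.0,
                       female_fraction = 0.582,
                       los_median = 9, los_iqr = c(6, 15),
                       vka_mix = c(B01AA12 = 3256, B01AA03 = 553,
                                   B01AA07 = 227, B01AA02 = 11) / 4047,
                       drug_specs = default_drug_specs(),
                       baseline_outcome_rate_high = 0.12,
                       baseline_outcome_rate_low = 0.20,
                       covariate_effects = default_covariate_effects(),
                       abnormal_rates = default_abnormal_rates(),
                       lab_missingness = c(ALBUMIN = 0.45, PREALBUMIN = 0.65,
                                           CREATININE = 0.15, ASAT = 0.35,
                                           TSH = 0.55, NTPROBNP = 0.6),
                       inr_measurement_rate = 0.4) {
  drug_specs <- as.data.table(drug_specs)
  stopifnot(
    n_stays >= 1,
    female_fraction >= 0 & female_fraction <= 1,
    abs(sum(vka_mix) - 1) < 1e-6,
    all(drug_specs$exposure_prevalence >= 0),
    sum(drug_specs$exposure_prevalence) <= 1,
    baseline_outcome_rate_high > 0, baseline_outcome_rate_high < 1,
    baseline_outcome_rate_low > 0, baseline_outcome_rate_low < 1,
    inr_measurement_rate >= 0, inr_measurement_rate <= 1
  )
  los_par <- fit_los_lognormal(los_median, los_iqr)
  structure(list(
    n_stays = as.integer(n_stays), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd,
    female_fraction = female_fraction,
    los_median = los_median, los_iqr = los_iqr, los_par = los_par,
    vka_mix = vka_mix, drug_specs = drug_specs,
    baseline_outcome_rate_high = baseline_outcome_rate_high,
    baseline_outcome_rate_low = baseline_outcome_rate_low,
    covariate_effects = covariate_effects,
    abnormal_rates = abnormal_rates,
    lab_missingness = lab_missingness,
    inr_measurement_rate = inr_measurement_rate
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_drug_specs <- function() {
  data.table(
    label = c("tramadol", "amiodarone", "rifampicin"),
    atc_code = c("N02AX02", "C01BD01", "J04AB02"),
    direction = c("potentiates_vka", "potentiates_vka", "inhibits_vka"),
    exposure_prevalence = c(0.12, 0.10, 0.05),
    true_log_or_initiation = c(0, 0, 0),
    true_log_or_discontinuation = c(0, 0, 0))
}

#' @rdname sim_config
#' @export
default_covariate_effects <- function() {
  c("age_class:70_79" = 0.20, "age_class:GE80" = 0.35,
    "albumin_class:LT30" = 0.30,
    "prealbumin_class:0_07_0_10" = 0.15, "prealbumin_class:LT0_07" = 0.35,
    "creatinine_class:16_24" = 0.15, "creatinine_class:GE25" = 0.30,
    "transaminase_class:GE250" = 0.25,
    "tsh_class:ABNORMAL" = 0.15,
    "ntprobnp_class:GE450" = 0.25)
}

#' @rdname sim_config
#' @export
default_abnormal_rates <- function() {
  list(ALBUMIN = c(LT30 = 0.35),
       PREALBUMIN = c(LT0_07 = 0.12, `0_07_0_10` = 0.25),
       CREATININE = c(`16_24` = 0.25, GE25 = 0.20),
       ASAT = c(GE250 = 0.08),
       TSH = c(ABNORMAL = 0.15),
       NTPROBNP = c(GE450 = 0.40))
}

# Least-squares fit of a lognormal to the printed median and IQR
# (3 summaries, 2 parameters: matched numerically, median weighted).
fit_los_lognormal <- function(med, iqr) {
  obj <- function(p) {
    q <- stats::qlnorm(c(0.25, 0.5, 0.75), p[1], exp(p[2]))
    2 * (q[2] - med)^2 + (q[1] - iqr[1])^2 + (q[3] - iqr[2])^2
  }
  o <- stats::optim(c(log(med), log(0.6)), obj)
  c(meanlog = o$par[1], sdlog = exp(o$par[2]))
}

#' Simulate a synthetic inpatient cohort with ground truth
#'
#' Every generated stay receives one VKA episode and at least one INR
#' measurement, so essentially the whole cohort passes the inclusion
#' criteria. Each stay is exposed to at most one companion drug; the
#' drug's administration run lies inside the VKA episode, and whether it
#' stops before the VKA decides discontinuation exposure. Latent
#' outcome indicators (one per excursion direction) are drawn from
#' logit P = beta0 + beta_drug * exposed + covariate effects; realized
#' outcomes place an INR value beyond the relevant threshold uniformly
#' inside the corresponding observation window (computed with the same
#' window rules as the exposure engine), while all other in-window INR
#' values lie strictly between the thresholds.
#'
#' @param config a [sim_config()].
#' @param out_dir when non-NULL, stays.csv, administrations.csv,
#'   labs.csv and truth.json are written there.
#' @param analysis_config a [ddi_config()] supplying the window lags and
#'   INR thresholds the generator mirrors.
#' @return A list: \code{cohort} (a \code{ddi_cohort}) and \code{truth}
#'   (per-drug true log odds ratios, per-stay realized indicators,
#'   realized exposure counts).
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL,
                            analysis_config = ddi_config()) {
  set.seed(config$seed)
  n <- config$n_stays
  onset <- analysis_config$onset_lag_days
  offset <- analysis_config$offset_lag_days
  lo_thr <- analysis_config$inr_low_threshold
  hi_thr <- analysis_config$inr_high_threshold

  los <- pmin(pmax(round(stats::rlnorm(n, config$los_par["meanlog"],
                                       config$los_par["sdlog"])), 3L), 60L)
  if (min(los) + offset < onset + 1L) stop("window lags incompatible with length of stay")
  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)), 18L), 105L)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  died <- stats::runif(n) < 0.04

  # one VKA episode per stay
  vka_start <- pmin(sample(1:2, n, replace = TRUE), los - 1L)
  vka_end <- pmax(vka_start, los - sample(0:2, n, replace = TRUE))
  vka_code <- sample(names(config$vka_mix), n, replace = TRUE,
                     prob = config$vka_mix)

  # mutually exclusive companion-drug assignment
  specs <- config$drug_specs
  ndrug <- nrow(specs)
  cumprev <- cumsum(specs$exposure_prevalence)
  u <- stats::runif(n)
  drug_idx <- rep(NA_integer_, n)
  if (ndrug) {
    for (j in rev(seq_len(ndrug))) drug_idx[u < cumprev[j]] <- j
  }
  has_drug <- !is.na(drug_idx)
  drug_start <- drug_end <- rep(NA_integer_, n)
  if (any(has_drug)) {
    i <- which(has_drug)
    span <- vka_end[i] - vka_start[i]
    drug_start[i] <- vka_start[i] +
      floor(stats::runif(length(i)) * (span + 1L))
    dur <- 1L + stats::rgeom(length(i), prob = 0.3)
    drug_end[i] <- pmin(drug_start[i] + dur, vka_end[i])
  }
  disc_exposed <- has_drug & !is.na(drug_end) & drug_end < vka_end

  # covariate labs: class drawn first, value drawn inside the class
  lab_rows <- list()
  class_draw <- function(analyte, ref_class, classes, ranges) {
    rates <- config$abnormal_rates[[analyte]]
    p_ref <- 1 - sum(rates)
    cls <- sample(c(ref_class, names(rates)), n, replace = TRUE,
                  prob = c(p_ref, unname(rates)))
    v <- numeric(n)
    for (cl in unique(cls)) {
      r <- ranges[[cl]]
      idx <- cls == cl
      v[idx] <- stats::runif(sum(idx), r[1], r[2])
    }
    miss <- stats::runif(n) < config$lab_missingness[[analyte]]
    list(class = ifelse(miss, ref_class, cls), value = v, missing = miss)
  }
  lab_specs <- list(
    ALBUMIN = list(ref = "GE30", ranges = list(GE30 = c(30, 45), LT30 = c(18, 29.5))),
    PREALBUMIN = list(ref = "GE0_11", ranges = list(
      GE0_11 = c(0.11, 0.3), `0_07_0_10` = c(0.07, 0.105), LT0_07 = c(0.02, 0.069))),
    CREATININE = list(ref = "LE15", ranges = list(
      LE15 = c(5, 15), `16_24` = c(16, 24.9), GE25 = c(25, 80))),
    ASAT = list(ref = "LT250", ranges = list(LT250 = c(10, 245), GE250 = c(250, 900))),
    TSH = list(ref = "NORMAL_0_5_TO_5", ranges = list(
      NORMAL_0_5_TO_5 = c(0.5, 5), ABNORMAL = c(5.2, 20))),
    NTPROBNP = list(ref = "LT450", ranges = list(LT450 = c(50, 445), GE450 = c(450, 8000)))
  )
  field_of <- c(ALBUMIN = "albumin_class", PREALBUMIN = "prealbumin_class",
                CREATININE = "creatinine_class", ASAT = "transaminase_class",
                TSH = "tsh_class", NTPROBNP = "ntprobnp_class")
  lp_cov <- numeric(n)
  observed_class <- list()
  for (an in names(lab_specs)) {
    d <- class_draw(an, lab_specs[[an]]$ref, NULL, lab_specs[[an]]$ranges)
    observed_class[[an]] <- d$class
    eff_names <- paste0(field_of[[an]], ":", d$class)
    eff <- config$covariate_effects[eff_names]
    eff[is.na(eff)] <- 0
    lp_cov <- lp_cov + eff
    keep <- which(!d$missing)
    if (length(keep)) {
      lab_rows[[an]] <- data.table(stay_id = keep, day = 1L, analyte = an,
                                   value = round(d$value[keep], 3))
    }
  }
  age_class <- ifelse(age < 70, "LT70", ifelse(age < 80, "70_79", "GE80"))
  eff <- config$covariate_effects[paste0("age_class:", age_class)]
  eff[is.na(eff)] <- 0
  lp_cov <- lp_cov + eff

  # observation windows, mirroring the exposure engine
  w_non_start <- vka_start + onset
  w_non_end <- pmin(vka_end + offset, los)
  w_init_start <- drug_start + onset
  w_init_end <- pmin(drug_end + offset, los)
  w_disc_start <- drug_end + onset
  w_disc_end <- pmin(drug_end + offset, vka_end + offset, los)

  b0_high <- stats::qlogis(config$baseline_outcome_rate_high)
  b0_low <- stats::qlogis(config$baseline_outcome_rate_low)
  lor_init <- ifelse(has_drug, specs$true_log_or_initiation[drug_idx], 0)
  lor_disc <- ifelse(has_drug, specs$true_log_or_discontinuation[drug_idx], 0)
  potent <- has_drug & specs$direction[drug_idx] == "potentiates_vka"
  inhib <- has_drug & specs$direction[drug_idx] == "inhibits_vka"

  # linear predictors for the two excursion directions
  lp_high <- b0_high + lp_cov +
    ifelse(potent, lor_init, 0) + ifelse(inhib & disc_exposed, lor_disc, 0)
  lp_low <- b0_low + lp_cov +
    ifelse(inhib, lor_init, 0) + ifelse(potent & disc_exposed, lor_disc, 0)

  # window carrying each direction's excursion
  pick_window <- function(direction_is_init, direction_is_disc) {
    s <- w_non_start; e <- w_non_end
    s[direction_is_init] <- w_init_start[direction_is_init]
    e[direction_is_init] <- w_init_end[direction_is_init]
    s[direction_is_disc] <- w_disc_start[direction_is_disc]
    e[direction_is_disc] <- w_disc_end[direction_is_disc]
    list(s = s, e = e)
  }
  wh <- pick_window(potent, inhib & disc_exposed)
  wl <- pick_window(inhib, potent & disc_exposed)

  out_high <- stats::runif(n) < stats::plogis(lp_high)
  out_low <- stats::runif(n) < stats::plogis(lp_low)
  out_high[wh$s > wh$e | wh$s > los] <- FALSE
  out_low[wl$s > wl$e | wl$s > los] <- FALSE

  day_high <- ifelse(out_high,
                     wh$s + floor(stats::runif(n) * (wh$e - wh$s + 1L)), NA)
  day_low <- ifelse(out_low,
                    wl$s + floor(stats::runif(n) * (wl$e - wl$s + 1L)), NA)
  clash <- which(out_high & out_low & day_high == day_low)
  for (i in clash) {
    alt <- setdiff(seq.int(wl$s[i], wl$e[i]), day_high[i])
    if (length(alt)) {
      day_low[i] <- alt[1 + floor(stats::runif(1) * length(alt))]
    } else {
      out_low[i] <- FALSE; day_low[i] <- NA
    }
  }

  # INR series: routine values strictly inside the thresholds, plus the
  # planted excursions (fully vectorized; day (i, d) sits at flat index
  # off[i] + d)
  guar <- pmin(vka_start + 1L, los)  # guaranteed measurement day
  routine_margin <- 0.1 * (hi_thr - lo_thr)
  off <- cumsum(c(0L, los[-n]))
  sidx <- rep(seq_len(n), los)
  dayv <- sequence(los)
  sel <- stats::runif(sum(los)) < config$inr_measurement_rate
  sel[off + guar] <- TRUE
  hi_i <- which(out_high); lo_i <- which(out_low)
  sel[off[hi_i] + day_high[hi_i]] <- FALSE
  sel[off[lo_i] + day_low[lo_i]] <- FALSE
  routine <- data.table(
    stay_id = sidx[sel], day = dayv[sel], analyte = "INR",
    value = round(stats::runif(sum(sel), lo_thr + routine_margin,
                               hi_thr - routine_margin), 2))
  excursion <- rbindlist(list(
    data.table(stay_id = hi_i, day = as.integer(day_high[hi_i]),
               analyte = "INR",
               value = round(stats::runif(length(hi_i), hi_thr, hi_thr + 3), 2)),
    data.table(stay_id = lo_i, day = as.integer(day_low[lo_i]),
               analyte = "INR",
               value = round(stats::runif(length(lo_i),
                                          max(0.4, lo_thr - 0.8), lo_thr), 2))))
  inr_rows <- list(rbindlist(list(routine, excursion)))

  sid <- sprintf("S%06d", seq_len(n))
  stays <- data.table(
    stay_id = sid, patient_id = sprintf("P%06d", seq_len(n)),
    hospital_id = "H1", admission_day = 1L, discharge_day = los,
    age_years = as.integer(age), sex = sex, died_in_hospital = died)

  adm <- list()
  vlen <- vka_end - vka_start + 1L
  adm[["vka"]] <- data.table(
    stay_id = rep(sid, vlen),
    day = sequence(vlen, from = vka_start),
    atc_code = rep(vka_code, vlen))
  if (any(has_drug)) {
    i <- which(has_drug)
    dlen <- drug_end[i] - drug_start[i] + 1L
    adm[["drug"]] <- data.table(
      stay_id = rep(sid[i], dlen),
      day = sequence(dlen, from = drug_start[i]),
      atc_code = rep(specs$atc_code[drug_idx[i]], dlen))
  }
  administrations <- rbindlist(adm)[order(stay_id, day, atc_code)]

  labs <- rbindlist(c(
    lapply(lab_rows, function(d) d[, .(stay_id = sid[stay_id], day, analyte, value)]),
    list(rbindlist(inr_rows)[, .(stay_id = sid[stay_id], day = as.integer(day),
                                 analyte, value)])
  ))[order(stay_id, day, analyte)]

  cohort <- ddi_cohort(stays, administrations, labs)
  truth <- list(
    drug_specs = specs,
    n_stays = n,
    baseline_outcome_rate_high = config$baseline_outcome_rate_high,
    baseline_outcome_rate_low = config$baseline_outcome_rate_low,
    exposure_counts = if (ndrug) data.table(
      label = specs$label,
      n_exposed_initiation = vapply(seq_len(ndrug), function(j)
        sum(drug_idx == j, na.rm = TRUE), integer(1)),
      n_exposed_discontinuation = vapply(seq_len(ndrug), function(j)
        sum(drug_idx == j & disc_exposed, na.rm = TRUE), integer(1))) else NULL,
    stay_truth = data.table(
      stay_id = sid,
      drug = ifelse(has_drug, specs$label[drug_idx], NA_character_),
      disc_exposed = disc_exposed,
      outcome_high = out_high, outcome_low = out_low)
  )
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    jsonlite::write_json(
      list(drug_specs = specs,
           exposure_counts = truth$exposure_counts,
           stay_truth = truth$stay_truth),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, truth = truth)
}

#' Tiny hand-checkable fixture cohort
#'
#' Ten deterministic stays covering every window edge case: VKA/drug
#' co-administration, discontinuation before the VKA's last day, a drug
#' stopped on the VKA's last day (not discontinuation-exposed), no
#' overlap, truncation at discharge, a VKA given on the discharge day
#' only (window not applicable), boundary INR values exactly at the
#' thresholds (5.0 and 1.5), an excursion before the window opens, and
#' two stays failing the inclusion criteria. The companion drug is
#' tramadol (N02AX02).
#'
#' @return A \code{ddi_cohort} of 10 stays.
#' @export
make_fixture_cohort <- function() {
  stays <- data.table(
    stay_id = sprintf("F%02d", 1:10),
    patient_id = sprintf("PF%02d", 1:10),
    hospital_id = "HF",
    admission_day = 1L,
    discharge_day = c(12L, 12L, 7L, 10L, 9L, 8L, 6L, 5L, 4L, 3L),
    age_years = c(81L, 67L, 74L, 90L, 55L, 79L, 70L, 62L, 84L, 45L),
    sex = c("female", "male", "female", "female", "male",
            "female", "male", "female", "male", "female"),
    died_in_hospital = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                         FALSE, FALSE, FALSE, FALSE, FALSE))
  vka <- "B01AA03"; tram <- "N02AX02"
  seqdt <- function(id, days, code) data.table(stay_id = id, day = days, atc_code = code)
  administrations <- rbindlist(list(
    seqdt("F01", 1:10, vka), seqdt("F01", 3:6, tram),
    seqdt("F02", 2:5, vka),
    seqdt("F03", 7L, vka),
    seqdt("F04", 1:8, vka), seqdt("F04", 5:8, tram),
    seqdt("F05", 1:5, vka), seqdt("F05", 6:9, tram),
    seqdt("F06", 1:8, vka), seqdt("F06", 2:4, tram),
    seqdt("F07", 1:6, vka),
    seqdt("F08", 2:4, vka), seqdt("F08", 3L, tram),
    seqdt("F09", 1:2, vka),
    seqdt("F10", 1L, "B01AB01")))
  lab <- function(id, day, analyte, value)
    data.table(stay_id = id, day = day, analyte = analyte, value = value)
  labs <- rbindlist(list(
    lab("F01", 2L, "INR", 2.8), lab("F01", 7L, "INR", 5.0),
    lab("F01", 2L, "ALBUMIN", 28), lab("F01", 8L, "ALBUMIN", 33),
    lab("F02", 4L, "INR", 2.5),
    lab("F03", 3L, "INR", 2.6),
    lab("F04", 3L, "INR", 2.4), lab("F04", 9L, "INR", 1.5),
    lab("F05", 2L, "INR", 2.2),
    lab("F06", 5L, "INR", 1.2), lab("F06", 1L, "CREATININE", 30),
    lab("F07", 4L, "INR", 5.5),
    lab("F08", 3L, "INR", 6.2), lab("F08", 4L, "INR", 2.0),
    lab("F09", 2L, "CREATININE", 12),
    lab("F10", 2L, "INR", 2.5)))
  ddi_cohort(stays, administrations, labs)
}

#' Rules for the fixture cohort's companion drug
#'
#' The initiation and discontinuation rules for tramadol (a VKA
#' potentiator), as [expand_rules()] would produce them.
#'
#' @return A two-row rules data.table.
#' @export
make_fixture_rules <- function() {
  entry <- data.table(label = "tramadol", direction = "potentiates_vka",
                      atc_codes = list("N02AX02"), group = "cns",
                      match_mode = "exact", unmappable = FALSE)
  expand_rules(entry)
}
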