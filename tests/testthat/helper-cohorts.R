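# Builders for small in-code cohorts and profiles used across tests.

# A minimal valid stays row.
mk_stay <- function(stay_id, discharge_day, age = 70L, sex = "female",
                    died = FALSE) {
  data.frame(stay_id = stay_id, patient_id = paste0("P", stay_id),
             hospital_id = "H1", admission_day = 1L,
             discharge_day = as.integer(discharge_day),
             age_years = as.integer(age), sex = sex,
             died_in_hospital = died)
}

mk_adm <- function(stay_id, days, atc) {
  data.frame(stay_id = stay_id, day = as.integer(days), atc_code = atc)
}

mk_lab <- function(stay_id, days, analyte, values) {
  data.frame(stay_id = stay_id, day = as.integer(days), analyte = analyte,
             value = values)
}

# All-reference covariate profiles for n stays (no covariate variation).
reference_profiles <- function(stay_ids) {
  prof <- data.frame(stay_id = stay_ids)
  for (f in names(spcddi:::COVARIATE_LEVELS)) {
    lv <- spcddi:::COVARIATE_LEVELS[[f]]
    prof[[f]] <- factor(lv[1L], levels = lv)
  }
  prof
}

# Random valid cohort in which every stay passes the inclusion criteria:
# a VKA run, optional companion-drug days, random INR labs.
random_cohort <- function(n_stays, seed, drug_atc = "N02AX02") {
  set.seed(seed)
  stays <- adms <- labs <- list()
  for (i in seq_len(n_stays)) {
    id <- sprintf("RS%02d", i)
    los <- sample(2:14, 1)
    stays[[i]] <- mk_stay(id, los, age = sample(40:95, 1),
                          sex = sample(c("female", "male"), 1))
    vs <- sample(seq_len(los), 1); ve <- sample(vs:los, 1)
    adms[[length(adms) + 1]] <- mk_adm(id, vs:ve, "B01AA03")
    if (stats::runif(1) < 0.7) {
      ds <- sample(seq_len(los), 1); de <- sample(ds:los, 1)
      adms[[length(adms) + 1]] <- mk_adm(id, ds:de, drug_atc)
    }
    ndays <- sample(1:4, 1)
    labs[[length(labs) + 1]] <- mk_lab(
      id, sample(seq_len(los), ndays, replace = TRUE), "INR",
      round(stats::runif(ndays, 0.8, 7), 2))
  }
  spcddi::ddi_cohort(do.call(rbind, stays), do.call(rbind, adms),
                     do.call(rbind, labs))
}

# Random strictly-positive 2x2 table with bounded cell size.
random_table <- function(max_cell = 60) {
  c(a = sample(1:max_cell, 1), b = sample(1:max_cell, 1),
    c = sample(1:max_cell, 1), d = sample(1:max_cell, 1))
}
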