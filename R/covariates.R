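# Covariate class layouts. First level of each is the reference class
# (the one imputed when the analyte was never measured during the stay).
COVARIATE_LEVELS <- list(
  age_class = c("LT70", "70_79", "GE80"),
  albumin_class = c("GE30", "LT30"),
  prealbumin_class = c("GE0_11", "0_07_0_10", "LT0_07"),
  creatinine_class = c("LE15", "16_24", "GE25"),
  transaminase_class = c("LT250", "GE250"),
  tsh_class = c("NORMAL_0_5_TO_5", "ABNORMAL"),
  ntprobnp_class = c("LT450", "GE450")
)

#' Categorize a covariate value
#'
#' Applies the class boundaries used by the adjusted models, with the
#' reference class listed first in \code{COVARIATE_LEVELS}:
#' age (years) <70 (ref) / 70-79 / >=80; albumin (g/L) >=30 (ref) / <30;
#' prealbumin (g/L) >=0.11 (ref) / 0.07-0.10 / <0.07; creatinine (mg/L)
#' <=15 (ref) / 16-24 / >=25 (values strictly between 15 and 25 fall in
#' the middle class); transaminases (IU/L) <250 (ref) / >=250 (applied
#' to the larger of ASAT and ALAT); TSH (mU/L) 0.5-5 (ref) / abnormal
#' otherwise; Nt-proBNP (pg/mL) <450 (ref) / >=450. A missing value
#' yields the reference class with the imputed flag set: unmeasured
#' parameters in routine care are assumed normal.
#'
#' @param value numeric value, or NA for missing.
#' @param analyte one of "AGE", "ALBUMIN", "PREALBUMIN", "CREATININE",
#'   "TRANSAMINASE", "TSH", "NTPROBNP".
#' @return A list with \code{class} (character) and \code{imputed}
#'   (logical).
#' @export
categorize <- function(value, analyte) {
  analyte <- toupper(analyte)
  field <- switch(analyte,
    AGE = "age_class", ALBUMIN = "albumin_class",
    PREALBUMIN = "prealbumin_class", CREATININE = "creatinine_class",
    TRANSAMINASE = "transaminase_class", ASAT = "transaminase_class",
    ALAT = "transaminase_class", TSH = "tsh_class",
    NTPROBNP = "ntprobnp_class",
    stop("unknown covariate analyte: ", analyte))
  lv <- COVARIATE_LEVELS[[field]]
  if (is.na(value)) return(list(class = lv[1L], imputed = TRUE))
  if (value < 0) stop("negative value for ", analyte, ": ", value)
  cls <- switch(field,
    age_class = if (value < 70) "LT70" else if (value < 80) "70_79" else "GE80",
    albumin_class = if (value < 30) "LT30" else "GE30",
    prealbumin_class = if (value < 0.07) "LT0_07" else
      if (value < 0.11) "0_07_0_10" else "GE0_11",
    creatinine_class = if (value <= 15) "LE15" else
      if (value < 25) "16_24" else "GE25",
    transaminase_class = if (value < 250) "LT250" else "GE250",
    tsh_class = if (value >= 0.5 && value <= 5) "NORMAL_0_5_TO_5" else "ABNORMAL",
    ntprobnp_class = if (value < 450) "LT450" else "GE450")
  list(class = cls, imputed = FALSE)
}

#' Build per-stay covariate profiles
#'
#' One profile per stay: age class from the stay record, the six
#' laboratory covariates from the stay's lab results (by default the
#' first measurement of the stay per analyte; \code{covariate_value =
#' "worst"} selects the most severe one). The transaminase class uses
#' the larger of ASAT and ALAT. Analytes never measured during the stay
#' are imputed with their reference class and flagged.
#'
#' @param cohort analyzed subcohort.
#' @param config a [ddi_config()].
#' @return data.table with stay_id, the seven class columns (factors,
#'   reference level first) and one \code{imputed_*} flag per lab
#'   covariate.
#' @export
build_profiles <- function(cohort, config = ddi_config()) {
  st <- cohort$stays
  prof <- data.table(stay_id = st$stay_id)
  prof[, age_class := vapply(st$age_years,
                             function(a) categorize(a, "AGE")$class, character(1))]

  pick <- function(analyte_set, worst_fun) {
    lb <- cohort$labs[analyte %in% analyte_set][order(stay_id, day)]
    if (nrow(lb) == 0L) {
      return(data.table(stay_id = character(), value = numeric()))
    }
    if (config$covariate_value == "first" && length(analyte_set) == 1L) {
      lb[, .(value = value[1L]), by = stay_id]
    } else if (config$covariate_value == "first") {
      # first day on which any of the pair was measured; take the max
      # of that day's measurements (transaminase severity = larger)
      lb[, .(value = max(value[day == day[1L]])), by = stay_id]
    } else {
      lb[, .(value = worst_fun(value)), by = stay_id]
    }
  }

  specs <- list(
    list(field = "albumin_class", analytes = "ALBUMIN", worst = min, arg = "ALBUMIN"),
    list(field = "prealbumin_class", analytes = "PREALBUMIN", worst = min, arg = "PREALBUMIN"),
    list(field = "creatinine_class", analytes = "CREATININE", worst = max, arg = "CREATININE"),
    list(field = "transaminase_class", analytes = c("ASAT", "ALAT"), worst = max, arg = "TRANSAMINASE"),
    list(field = "tsh_class", analytes = "TSH",
         worst = function(v) v[which.max(abs(log(pmax(v, 1e-9) / 2.75)))], arg = "TSH"),
    list(field = "ntprobnp_class", analytes = "NTPROBNP", worst = max, arg = "NTPROBNP")
  )
  for (s in specs) {
    vals <- pick(s$analytes, s$worst)
    v <- vals$value[match(prof$stay_id, vals$stay_id)]
    cl <- character(nrow(prof)); imp <- is.na(v)
    lv <- COVARIATE_LEVELS[[s$field]]
    cl[imp] <- lv[1L]
    if (any(!imp)) {
      cl[!imp] <- vapply(v[!imp], function(x) categorize(x, s$arg)$class,
                         character(1))
    }
    prof[, (s$field) := cl]
    prof[, (paste0("imputed_", sub("_class$", "", s$field))) := imp]
  }
  for (f in names(COVARIATE_LEVELS)) {
    prof[, (f) := factor(get(f), levels = COVARIATE_LEVELS[[f]])]
  }
  prof[]
}
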