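#' @import data.table
NULL

# Analytes carried by the lab table, with their canonical units.
LAB_ANALYTES <- c("INR", "ALBUMIN", "PREALBUMIN", "CREATININE",
                  "ASAT", "ALAT", "TSH", "NTPROBNP")

# ATC codes are hierarchical alternating letter/digit blocks:
# L, LDD, LDDL, LDDLL, LDDLLDD (levels 1-5).
ATC_REGEX <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

is_valid_atc <- function(x) grepl(ATC_REGEX, x)

stay_cols <- c("stay_id", "patient_id", "hospital_id", "admission_day",
               "discharge_day", "age_years", "sex", "died_in_hospital")
admin_cols <- c("stay_id", "day", "atc_code")
lab_cols <- c("stay_id", "day", "analyte", "value")

#' Construct a validated inpatient cohort
#'
#' A cohort bundles the three longitudinal EHR tables the analysis
#' consumes: one row per inpatient stay (demographics and day-indexed
#' span, day 1 = admission), one row per daily drug administration
#' (ATC-coded), and one row per laboratory result. All referential and
#' range invariants are enforced on construction.
#'
#' @param stays data.frame with columns stay_id, patient_id, hospital_id,
#'   admission_day, discharge_day, age_years, sex ("female"/"male"),
#'   died_in_hospital (logical).
#' @param administrations data.frame with columns stay_id, day, atc_code.
#' @param labs data.frame with columns stay_id, day, analyte, value.
#' @return An object of class \code{ddi_cohort}: a list of three
#'   data.tables plus the validation report.
#' @export
ddi_cohort <- function(stays, administrations, labs) {
  stays <- as.data.table(stays)
  administrations <- as.data.table(administrations)
  labs <- as.data.table(labs)
  rep <- validate_cohort_tables(stays, administrations, labs)
  if (nrow(rep$errors)) {
    stop("cohort validation failed:\n",
         paste(utils::head(format_validation_errors(rep$errors), 20),
               collapse = "\n"))
  }
  structure(list(stays = stays, administrations = administrations,
                 labs = labs, validation = rep),
            class = "ddi_cohort")
}

# Full invariant check over the three tables. Returns a report with an
# errors table (table, line, field, message) so callers can surface the
# offending row.
validate_cohort_tables <- function(stays, administrations, labs) {
  errs <- list()
  note <- function(tab, line, field, msg) {
    errs[[length(errs) + 1L]] <<- data.table(
      table = tab, line = as.integer(line), field = field, message = msg)
  }
  miss <- setdiff(stay_cols, names(stays))
  if (length(miss)) note("stays", NA, paste(miss, collapse = ","), "missing column(s)")
  miss <- setdiff(admin_cols, names(administrations))
  if (length(miss)) note("administrations", NA, paste(miss, collapse = ","), "missing column(s)")
  miss <- setdiff(lab_cols, names(labs))
  if (length(miss)) note("labs", NA, paste(miss, collapse = ","), "missing column(s)")
  if (length(errs)) {
    return(list(errors = rbindlist(errs), n_stays = nrow(stays)))
  }

  dup <- which(duplicated(stays$stay_id))
  for (i in dup) note("stays", i, "stay_id", sprintf("duplicate stay_id '%s'", stays$stay_id[i]))
  bad <- which(!(stays$discharge_day >= stays$admission_day))
  for (i in bad) note("stays", i, "discharge_day", "discharge_day < admission_day")
  bad <- which(is.na(stays$age_years) | stays$age_years < 0 | stays$age_years > 130)
  for (i in bad) note("stays", i, "age_years", "age_years outside [0, 130]")
  bad <- which(!stays$sex %in% c("female", "male"))
  for (i in bad) note("stays", i, "sex", sprintf("invalid sex '%s'", stays$sex[i]))
  bad <- which(is.na(as.logical(stays$died_in_hospital)))
  for (i in bad) note("stays", i, "died_in_hospital", "not interpretable as logical")

  span <- stays[, .(stay_id, .adm = admission_day, .dis = discharge_day)]

  if (nrow(administrations)) {
    m <- span[administrations, on = "stay_id"]
    bad <- which(is.na(m$.adm))
    for (i in bad) note("administrations", i, "stay_id",
                        sprintf("unknown stay_id '%s'", administrations$stay_id[i]))
    bad <- which(!is.na(m$.adm) & (m$day < m$.adm | m$day > m$.dis))
    for (i in bad) note("administrations", i, "day",
                        sprintf("day %d outside stay span [%d, %d]", m$day[i], m$.adm[i], m$.dis[i]))
    bad <- which(!is_valid_atc(administrations$atc_code))
    for (i in bad) note("administrations", i, "atc_code",
                        sprintf("invalid ATC code '%s'", administrations$atc_code[i]))
  }
  if (nrow(labs)) {
    m <- span[labs, on = "stay_id"]
    bad <- which(is.na(m$.adm))
    for (i in bad) note("labs", i, "stay_id", sprintf("unknown stay_id '%s'", labs$stay_id[i]))
    bad <- which(!is.na(m$.adm) & (m$day < m$.adm | m$day > m$.dis))
    for (i in bad) note("labs", i, "day",
                        sprintf("day %d outside stay span [%d, %d]", m$day[i], m$.adm[i], m$.dis[i]))
    bad <- which(!labs$analyte %in% LAB_ANALYTES)
    for (i in bad) note("labs", i, "analyte", sprintf("unknown analyte '%s'", labs$analyte[i]))
    bad <- which(!is.finite(labs$value) | labs$value <= 0)
    for (i in bad) note("labs", i, "value", "value must be a positive number")
  }

  errors <- if (length(errs)) rbindlist(errs) else
    data.table(table = character(), line = integer(),
               field = character(), message = character())
  list(errors = errors, n_stays = nrow(stays),
       n_administrations = nrow(administrations), n_labs = nrow(labs))
}

format_validation_errors <- function(errors) {
  sprintf("[%s:%s] %s: %s", errors$table,
          ifelse(is.na(errors$line), "-", errors$line),
          errors$field, errors$message)
}

#' Read a cohort from delimited text files
#'
#' Each file is delimited text with a header row. Rows violating an
#' invariant (dangling stay reference, administration or lab day outside
#' the stay span, non-positive lab value, malformed ATC code) abort with
#' a report naming the table, line and field.
#'
#' @param stays_path,administrations_path,labs_path file paths.
#' @param config a [ddi_config()]; its \code{delimiter} is used.
#' @return A validated \code{ddi_cohort}.
#' @export
read_cohort <- function(stays_path, administrations_path, labs_path,
                        config = ddi_config()) {
  for (p in c(stays_path, administrations_path, labs_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  sep <- config$delimiter
  stays <- fread(stays_path, sep = sep, colClasses = list(
    character = c("stay_id", "patient_id", "hospital_id"),
    integer = c("admission_day", "discharge_day", "age_years")))
  administrations <- fread(administrations_path, sep = sep,
                           colClasses = list(character = c("stay_id", "atc_code")))
  labs <- fread(labs_path, sep = sep,
                colClasses = list(character = c("stay_id", "analyte"),
                                  numeric = "value"))
  if (nrow(stays)) stays[, died_in_hospital := as.logical(died_in_hospital)]
  ddi_cohort(stays, administrations, labs)
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: the three tables round-trip field for
#' field.
#'
#' @param cohort a \code{ddi_cohort}.
#' @param dir output directory (created if absent).
#' @param config a [ddi_config()].
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir, config = ddi_config()) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("stays.csv", "administrations.csv", "labs.csv"))
  fwrite(cohort$stays, paths[1], sep = config$delimiter)
  fwrite(cohort$administrations, paths[2], sep = config$delimiter)
  fwrite(cohort$labs, paths[3], sep = config$delimiter)
  invisible(stats::setNames(paths, c("stays", "administrations", "labs")))
}

#' Apply the study inclusion criteria
#'
#' Retains stays with at least one INR laboratory result and at least one
#' day with a VKA administration (any ATC code starting with the
#' configured VKA prefix).
#'
#' @param cohort a \code{ddi_cohort}.
#' @param config a [ddi_config()].
#' @return A list: \code{cohort} (the subcohort, still a
#'   \code{ddi_cohort}), \code{n_total}, \code{n_retained},
#'   \code{retained_pct} (half-up, 2 decimals).
#' @export
apply_inclusion_criteria <- function(cohort, config = ddi_config()) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  has_inr <- unique(cohort$labs[analyte == "INR", stay_id])
  has_vka <- unique(cohort$administrations[
    startsWith(atc_code, config$vka_atc_prefix), stay_id])
  keep <- cohort$stays$stay_id %in% has_inr & cohort$stays$stay_id %in% has_vka
  sub_ids <- cohort$stays$stay_id[keep]
  sub <- structure(list(
    stays = cohort$stays[keep],
    administrations = cohort$administrations[stay_id %in% sub_ids],
    labs = cohort$labs[stay_id %in% sub_ids],
    validation = cohort$validation
  ), class = "ddi_cohort")
  n_total <- nrow(cohort$stays)
  n_ret <- length(sub_ids)
  list(cohort = sub, n_total = n_total, n_retained = n_ret,
       retained_pct = if (n_total > 0) pct(n_ret, n_total, 2) else NA_real_)
}

#' Descriptive summary of an analyzed subcohort
#'
#' Reports counts and percentages for categorical variables (sex, death,
#' VKA molecule) and mean/SD or median/IQR for quantitative ones (age;
#' length of stay, defined as discharge - admission + 1 days).
#' Percentages are half-up rounded.
#'
#' @param cohort a \code{ddi_cohort} (post-inclusion).
#' @param config a [ddi_config()].
#' @param pct_digits decimals for percentages (default 1).
#' @return A list of class \code{ddi_descriptives}.
#' @export
describe_cohort <- function(cohort, config = ddi_config(), pct_digits = 1) {
  stopifnot(inherits(cohort, "ddi_cohort"))
  n <- nrow(cohort$stays)
  if (n == 0L) {
    return(structure(list(n_stays = 0L, note = "no stays"),
                     class = "ddi_descriptives"))
  }
  st <- cohort$stays
  los <- st$discharge_day - st$admission_day + 1L
  sex_tab <- st[, .N, by = sex][, pct := pct(N, n, pct_digits)][]
  deaths <- sum(st$died_in_hospital)
  # VKA molecule: stays administered exactly one distinct VKA code are
  # labelled by it; several distinct codes are pooled as "multiple/other".
  vka <- cohort$administrations[startsWith(atc_code, config$vka_atc_prefix),
                                .(codes = list(unique(atc_code))), by = stay_id]
  vka[, molecule := vapply(codes, function(z)
    if (length(z) == 1L) z else "multiple/other", character(1))]
  vka_tab <- vka[, .N, by = molecule][order(-N)]
  vka_tab[, pct := pct(N, n, pct_digits)]
  structure(list(
    n_stays = n,
    age_mean = mean(st$age_years), age_sd = stats::sd(st$age_years),
    los_median = stats::median(los),
    los_iqr = unname(stats::quantile(los, c(0.25, 0.75), type = 2)),
    deaths_n = deaths, deaths_pct = pct(deaths, n, 2),
    sex = sex_tab[], vka_molecule = vka_tab[]
  ), class = "ddi_descriptives")
}

#' @export
print.ddi_descriptives <- function(x, ...) {
  if (x$n_stays == 0L) {
    cat("Analyzed subcohort: no stays\n")
    return(invisible(x))
  }
  cat(sprintf("Analyzed subcohort: %d stays\n", x$n_stays))
  cat(sprintf("  age          : mean %.1f y (SD %.1f)\n", x$age_mean, x$age_sd))
  cat(sprintf("  length of stay: median %g d (IQR %g-%g)\n",
              x$los_median, x$los_iqr[1], x$los_iqr[2]))
  cat(sprintf("  deaths       : %d (%.2f%%)\n", x$deaths_n, x$deaths_pct))
  for (i in seq_len(nrow(x$sex))) {
    cat(sprintf("  sex %-8s : %d (%.1f%%)\n", x$sex$sex[i], x$sex$N[i], x$sex$pct[i]))
  }
  cat("  VKA molecule :\n")
  for (i in seq_len(nrow(x$vka_molecule))) {
    cat(sprintf("    %-14s %d (%.1f%%)\n", x$vka_molecule$molecule[i],
                x$vka_molecule$N[i], x$vka_molecule$pct[i]))
  }
  invisible(x)
}

#' @export
print.ddi_cohort <- function(x, ...) {
  cat(sprintf("<ddi_cohort> %d stays, %d administrations, %d lab results\n",
              nrow(x$stays), nrow(x$administrations), nrow(x$labs)))
  invisible(x)
}
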