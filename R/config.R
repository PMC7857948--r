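#' Analysis configuration
#'
#' Bundles the constants of the alert-filtering analysis: the INR excursion
#' thresholds defining VKA potentiation and inhibition, the onset and
#' residual-action lags (in whole days) used to build observation windows,
#' the minimum number of exposed stays below which no odds ratio is
#' estimated, the type-1 error level, and the ATC prefix identifying
#' vitamin K antagonists.
#'
#' @param inr_high_threshold INR at or above which VKA potentiation is
#'   recorded (dimensionless, default 5).
#' @param inr_low_threshold INR at or below which VKA inhibition is
#'   recorded (default 1.5).
#' @param onset_lag_days days between a drug change and the start of the
#'   observation window (default 1, the assumed onset of action).
#' @param offset_lag_days days of residual action appended after
#'   discontinuation (default 4).
#' @param min_exposed_stays minimum number of exposed stays required to
#'   estimate odds ratios for a rule (default 3).
#' @param alpha two-sided type-1 error for all confidence limits
#'   (default 0.05).
#' @param vka_atc_prefix ATC prefix identifying VKAs (default "B01AA").
#' @param covariate_value selection rule for the laboratory value feeding
#'   each covariate: "first" (first measurement of the stay, default) or
#'   "worst".
#' @param delimiter field delimiter for cohort files (default ",").
#' @param basis which odds-ratio tier drives alert decisions:
#'   "stepwise" (default), "adjusted" or "unadjusted".
#' @param deactivate_nonsignificant should alerts for rules with no
#'   significant association be switched off (default TRUE)?
#'
#' @return An object of class \code{ddi_config} (a named list).
#' @export
ddi_config <- function(inr_high_threshold = 5,
                       inr_low_threshold = 1.5,
                       onset_lag_days = 1L,
                       offset_lag_days = 4L,
                       min_exposed_stays = 3L,
                       alpha = 0.05,
                       vka_atc_prefix = "B01AA",
                       covariate_value = c("first", "worst"),
                       delimiter = ",",
                       basis = c("stepwise", "adjusted", "unadjusted"),
                       deactivate_nonsignificant = TRUE) {
  covariate_value <- match.arg(covariate_value)
  basis <- match.arg(basis)
  stopifnot(
    is.numeric(inr_low_threshold), is.numeric(inr_high_threshold),
    inr_low_threshold < inr_high_threshold,
    onset_lag_days >= 0, offset_lag_days >= 0,
    min_exposed_stays >= 1,
    is.numeric(alpha), alpha > 0, alpha < 1,
    is.character(vka_atc_prefix), nzchar(vka_atc_prefix)
  )
  structure(list(
    inr_high_threshold = as.numeric(inr_high_threshold),
    inr_low_threshold = as.numeric(inr_low_threshold),
    onset_lag_days = as.integer(onset_lag_days),
    offset_lag_days = as.integer(offset_lag_days),
    min_exposed_stays = as.integer(min_exposed_stays),
    alpha = as.numeric(alpha),
    vka_atc_prefix = vka_atc_prefix,
    covariate_value = covariate_value,
    delimiter = delimiter,
    basis = basis,
    deactivate_nonsignificant = isTRUE(deactivate_nonsignificant)
  ), class = "ddi_config")
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [ddi_config()]; absent keys keep their
#' defaults.
#'
#' @param path file ending in .yaml/.yml (requires the yaml package) or
#'   .json.
#' @return A \code{ddi_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(ddi_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(ddi_config, vals)
}

#' @export
print.ddi_config <- function(x, ...) {
  cat("DDI analysis configuration\n")
  cat(sprintf("  outcome thresholds : INR >= %g (potentiation), INR <= %g (inhibition)\n",
              x$inr_high_threshold, x$inr_low_threshold))
  cat(sprintf("  window lags        : onset %d d, residual action %d d\n",
              x$onset_lag_days, x$offset_lag_days))
  cat(sprintf("  min exposed stays  : %d\n", x$min_exposed_stays))
  cat(sprintf("  alpha              : %g; decision basis: %s\n", x$alpha, x$basis))
  cat(sprintf("  VKA ATC prefix     : %s\n", x$vka_atc_prefix))
  invisible(x)
}

# Round half away from zero at d decimals, the convention used for all
# reported percentages and odds ratios (base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of num out of den, rounded half-up.
pct <- function(num, den, digits = 2) {
  round_half_up(100 * num / den, digits)
}
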