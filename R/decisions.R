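#' Classify one rule's evidence and decide alert activation
#'
#' Classification uses the basis odds ratio (stepwise by default,
#' configurable; a noncomputable basis falls back to the unadjusted OR):
#' \code{insufficient_data} when fewer exposed stays than the minimum;
#' \code{significant_protective} when the upper confidence limit is
#' below 1; \code{significant_risk} when the lower limit exceeds 1;
#' otherwise \code{no_significant_association}. The alert stays active
#' for \code{significant_risk} and for \code{insufficient_data}
#' (statistical filtering is ignored when the learning database holds
#' too few cases); it is deactivated for
#' \code{significant_protective}, and for
#' \code{no_significant_association} when
#' \code{deactivate_nonsignificant} is set (the default).
#'
#' @param estimate a \code{rule_estimate}.
#' @param config a [ddi_config()] (fields \code{basis},
#'   \code{deactivate_nonsignificant}).
#' @return A \code{rule_decision} list: rule_id, label, phase,
#'   n_exposed, classification, alert_active, basis, notes.
#' @export
classify_rule <- function(estimate, config = ddi_config()) {
  dec <- list(rule_id = estimate$rule_id, label = estimate$label,
              phase = estimate$phase, n_exposed = estimate$n_exposed,
              basis = config$basis, notes = "")
  if (estimate$status == "insufficient_data") {
    dec$classification <- "insufficient_data"
    dec$alert_active <- TRUE
    class(dec) <- "rule_decision"
    return(dec)
  }
  basis_or <- switch(config$basis,
                     unadjusted = estimate$or_unadjusted,
                     adjusted = estimate$or_adjusted,
                     stepwise = estimate$or_stepwise)
  if (!isTRUE(basis_or$computable)) {
    basis_or <- estimate$or_unadjusted
    dec$basis <- "unadjusted (fallback)"
  }
  if (!isTRUE(basis_or$computable)) {
    dec$classification <- "no_significant_association"
    dec$notes <- "no computable odds ratio in any tier"
    dec$alert_active <- !config$deactivate_nonsignificant
    class(dec) <- "rule_decision"
    return(dec)
  }
  dec$classification <- if (basis_or$upper95 < 1) {
    "significant_protective"
  } else if (basis_or$lower95 > 1) {
    "significant_risk"
  } else {
    "no_significant_association"
  }
  dec$alert_active <- switch(dec$classification,
    significant_risk = TRUE,
    significant_protective = FALSE,
    no_significant_association = !config$deactivate_nonsignificant)
  class(dec) <- "rule_decision"
  dec
}

#' Classify every estimated rule
#'
#' @param estimates list from [estimate_all_rules()].
#' @param config a [ddi_config()].
#' @return data.table with one row per rule.
#' @export
classify_all_rules <- function(estimates, config = ddi_config()) {
  rbindlist(lapply(estimates, function(e) {
    d <- classify_rule(e, config)
    data.table(rule_id = d$rule_id, label = d$label, phase = d$phase,
               n_exposed = d$n_exposed, classification = d$classification,
               alert_active = d$alert_active, basis = d$basis,
               notes = d$notes)
  }))
}

#' Render the per-phase result tables and the decision summary
#'
#' Produces a markdown report with one table per phase (initiation,
#' discontinuation) listing, sorted by therapeutic group and drug, the
#' rules with at least one significant odds ratio in any tier — columns
#' Drug | Outcome | n | OR (95% CLs) | Adjusted OR | Stepwise OR, with
#' noncomputable limits footnoted — plus summary counts of every
#' classification, and a machine-readable JSON twin of the full
#' decision set.
#'
#' @param decisions data.table from [classify_all_rules()].
#' @param estimates list from [estimate_all_rules()].
#' @param descriptives optional [describe_cohort()] result.
#' @param dir output directory.
#' @param config a [ddi_config()].
#' @return Invisibly, the paths written (report.md, report.json,
#'   decisions.csv).
#' @export
render_report <- function(decisions, estimates, descriptives = NULL,
                          dir = ".", config = ddi_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- estimates_table(estimates)
  est_by_id <- stats::setNames(estimates, vapply(estimates, `[[`, "", "rule_id"))

  is_significant <- function(or) {
    isTRUE(or$computable) && (or$upper95 < 1 || or$lower95 > 1)
  }
  any_sig <- vapply(estimates, function(e) {
    e$status == "estimated" && (is_significant(e$or_unadjusted) ||
      is_significant(e$or_adjusted) || is_significant(e$or_stepwise))
  }, logical(1))
  sig_ids <- vapply(estimates, `[[`, "", "rule_id")[any_sig]

  lines <- c("# Empirical DDI alert filtering report", "")
  if (!is.null(descriptives) && descriptives$n_stays > 0) {
    lines <- c(lines, sprintf(
      "Analyzed subcohort: %d stays; mean age %.1f y (SD %.1f); median length of stay %g d (IQR %g-%g); %d deaths (%.2f%%).",
      descriptives$n_stays, descriptives$age_mean, descriptives$age_sd,
      descriptives$los_median, descriptives$los_iqr[1],
      descriptives$los_iqr[2], descriptives$deaths_n, descriptives$deaths_pct),
      "")
  }
  pretty_outcome <- function(o) ifelse(o == "INR_GE_HIGH", "INR>=5", "INR<=1.5")
  for (ph in PHASES) {
    sub <- tab[phase == ph & rule_id %in% sig_ids][order(group, label)]
    lines <- c(lines, sprintf("## Drug %s rules with at least one significant OR", ph), "")
    if (nrow(sub) == 0L) {
      lines <- c(lines, "(none)", "")
      next
    }
    lines <- c(lines,
               "| Drug | Outcome | n | OR (95% CLs) | Adjusted OR | Stepwise OR |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %d | %s | %s | %s |",
                       sub$label, pretty_outcome(sub$outcome), sub$n,
                       sub$or_unadjusted, sub$or_adjusted, sub$or_stepwise),
               "",
               "^d: confidence limits not computable.", "")
  }
  cnt <- decisions[, .N, by = classification]
  lines <- c(lines, "## Decision summary", "",
             sprintf("- %s: %d", cnt$classification, cnt$N),
             sprintf("- alerts kept active: %d of %d",
                     sum(decisions$alert_active), nrow(decisions)))
  md_path <- file.path(dir, "report.md")
  writeLines(lines, md_path)

  csv_path <- file.path(dir, "decisions.csv")
  fwrite(decisions, csv_path)

  json_path <- file.path(dir, "report.json")
  json <- list(
    summary = as.list(stats::setNames(cnt$N, cnt$classification)),
    n_rules = nrow(decisions),
    n_alerts_active = sum(decisions$alert_active),
    rules = lapply(seq_len(nrow(tab)), function(i) {
      r <- as.list(tab[i])
      e <- est_by_id[[r$rule_id]]
      d <- decisions[rule_id == r$rule_id]
      r$classification <- d$classification[1]
      r$alert_active <- d$alert_active[1]
      if (e$status == "estimated") {
        r$or <- lapply(list(unadjusted = e$or_unadjusted,
                            adjusted = e$or_adjusted,
                            stepwise = e$or_stepwise), unclass)
      }
      r
    }))
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(report_md = md_path, decisions_csv = csv_path,
              report_json = json_path))
}

#' Run the whole pipeline from files to decisions
#'
#' Reads the cohort and rulebook, applies the inclusion criteria,
#' expands the rules, estimates the odds-ratio cascade, classifies every
#' rule and renders the report, logging each stage's counts.
#'
#' @param stays_path,administrations_path,labs_path cohort files.
#' @param rulebook_path rulebook file.
#' @param out_dir report directory (NULL skips rendering).
#' @param config a [ddi_config()].
#' @param quiet suppress stage logging.
#' @return A list: cohort, inclusion, rules, curation report,
#'   descriptives, estimates, decisions, report paths.
#' @export
run_pipeline <- function(stays_path, administrations_path, labs_path,
                         rulebook_path, out_dir = NULL,
                         config = ddi_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  cohort <- read_cohort(stays_path, administrations_path, labs_path, config)
  say("read: %d stays, %d administrations, %d lab results",
      nrow(cohort$stays), nrow(cohort$administrations), nrow(cohort$labs))
  incl <- apply_inclusion_criteria(cohort, config)
  say("inclusion: %d of %d stays retained (%.2f%%)",
      incl$n_retained, incl$n_total, incl$retained_pct)
  entries <- load_rulebook(rulebook_path)
  cur <- curate_rulebook(entries)
  rules <- expand_rules(cur$entries, config)
  say("rulebook: %d loaded, %d excluded (no ATC), %d merged, %d curated, %d rules",
      cur$report$n_loaded, cur$report$n_excluded_unmappable,
      cur$report$n_merged, cur$report$n_curated, nrow(rules))
  desc <- describe_cohort(incl$cohort, config)
  estimates <- estimate_all_rules(incl$cohort, rules, config = config)
  n_est <- sum(vapply(estimates, function(e) e$status == "estimated", logical(1)))
  say("estimation: %d of %d rules estimated (others insufficient data)",
      n_est, length(estimates))
  decisions <- classify_all_rules(estimates, config)
  say("decisions: %d alerts kept active, %d deactivated",
      sum(decisions$alert_active), sum(!decisions$alert_active))
  paths <- if (!is.null(out_dir)) {
    render_report(decisions, estimates, desc, out_dir, config)
  }
  list(cohort = cohort, inclusion = incl[c("n_total", "n_retained", "retained_pct")],
       curation = cur$report, rules = rules, descriptives = desc,
       estimates = estimates, decisions = decisions, report_paths = paths)
}
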