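#' Estimate the three-tier odds-ratio cascade for every rule
#'
#' For each rule: assemble the per-stay observation windows and the 2x2
#' contingency table; if fewer than \code{min_exposed_stays} stays are
#' exposed, the rule is flagged \code{insufficient_data} and no odds
#' ratio is computed; otherwise the Fisher exact unadjusted OR, the
#' covariate-adjusted OR and the stepwise-selected OR are estimated over
#' the full included-stay denominator.
#'
#' @param cohort analyzed subcohort.
#' @param rules rules from [expand_rules()].
#' @param profiles covariate profiles from [build_profiles()] (built on
#'   demand when NULL).
#' @param config a [ddi_config()].
#' @return A list of \code{rule_estimate} objects, one per rule, each
#'   with rule_id, label, phase, expected_outcome, group, n_exposed,
#'   table, status and (when estimated) or_unadjusted, or_adjusted,
#'   or_stepwise.
#' @export
estimate_all_rules <- function(cohort, rules, profiles = NULL,
                               config = ddi_config()) {
  rules <- as.data.table(rules)
  if (is.null(profiles)) profiles <- build_profiles(cohort, config)
  design <- build_design(profiles)
  lapply(seq_len(nrow(rules)), function(i) {
    estimate_rule(cohort, rules[i], profiles, config, design)
  })
}

# One rule of the cascade; design may be precomputed for the profile set.
estimate_rule <- function(cohort, rule, profiles, config = ddi_config(),
                          design = NULL) {
  tab <- assemble_table(cohort, rule, config)
  est <- list(rule_id = rule$rule_id, label = rule$label,
              phase = rule$phase, expected_outcome = rule$expected_outcome,
              group = rule$group, n_exposed = tab$n_exposed,
              table = tab$table)
  if (tab$n_exposed < config$min_exposed_stays) {
    est$status <- "insufficient_data"
    class(est) <- "rule_estimate"
    return(est)
  }
  est$status <- "estimated"
  est$or_unadjusted <- fisher_or(tab$table, config$alpha)

  w <- tab$windows[exposure_status != "not_applicable"]
  idx <- match(w$stay_id, profiles$stay_id)
  prof <- profiles[idx]
  if (is.null(design)) {
    dsg <- build_design(prof)
    xw <- dsg$x
  } else {
    dsg <- design
    xw <- design$x[idx, , drop = FALSE]
  }
  dsub <- list(x = xw, groups = dsg$groups, group_names = dsg$group_names)
  outc <- w$outcome
  expo <- w$exposure_status == "exposed"
  est$or_adjusted <- adjusted_or(outc, expo, prof, config$alpha, design = dsub)
  est$or_stepwise <- stepwise_or(outc, expo, prof, config$alpha, design = dsub)
  class(est) <- "rule_estimate"
  est
}

#' @export
print.rule_estimate <- function(x, ...) {
  cat(sprintf("%s [%s, %s] n=%d: ", x$label, x$phase,
              sub("INR_GE_HIGH", "INR>=high", sub("INR_LE_LOW", "INR<=low",
                                                  x$expected_outcome)),
              x$n_exposed))
  if (x$status == "insufficient_data") {
    cat("insufficient data (no OR computed)\n")
  } else {
    cat(sprintf("OR %s | adj %s | step %s\n",
                format_or(x$or_unadjusted), format_or(x$or_adjusted),
                format_or(x$or_stepwise)))
  }
  invisible(x)
}

#' Tabulate a list of rule estimates
#'
#' One row per rule with the table cells and formatted OR columns,
#' mirroring the published layout (Drug, Outcome, n, OR, adjusted OR,
#' stepwise OR).
#'
#' @param estimates list from [estimate_all_rules()].
#' @return A data.table.
#' @export
estimates_table <- function(estimates) {
  if (length(estimates) == 0L) {
    return(data.table(rule_id = character(), label = character(),
                      group = character(), phase = character(),
                      outcome = character(), n = integer(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), status = character(),
                      or_unadjusted = character(),
                      or_adjusted = character(),
                      or_stepwise = character()))
  }
  rbindlist(lapply(estimates, function(e) {
    data.table(
      rule_id = e$rule_id, label = e$label, group = e$group,
      phase = e$phase, outcome = e$expected_outcome,
      n = e$n_exposed,
      a = e$table[["a"]], b = e$table[["b"]],
      c = e$table[["c"]], d = e$table[["d"]],
      status = e$status,
      or_unadjusted = if (e$status == "estimated") format_or(e$or_unadjusted) else "",
      or_adjusted = if (e$status == "estimated") format_or(e$or_adjusted) else "",
      or_stepwise = if (e$status == "estimated") format_or(e$or_stepwise) else "")
  }))
}
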