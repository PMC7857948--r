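# Days on which an administration matches a rule's drug. match_mode
# "exact" requires the administered code to equal one of the entry codes;
# "prefix" lets an entry code stand for an ATC class (the administered
# code starts with it).
match_drug_days <- function(days, codes, entry_atc, match_mode) {
  hit <- if (match_mode == "prefix") {
    Reduce(`|`, lapply(entry_atc, function(p) startsWith(codes, p)))
  } else {
    codes %in% entry_atc
  }
  sort(unique(days[hit]))
}

# Length of the initial run of consecutive days in a sorted day vector.
first_run_end <- function(days) {
  if (length(days) == 1L) return(days[1L])
  brk <- which(diff(days) != 1L)
  if (length(brk)) days[brk[1L]] else days[length(days)]
}

#' Classify a stay's exposure status for one rule
#'
#' A stay is exposed to an initiation rule if the interacting drug and a
#' VKA were administered on at least one common day. For a
#' discontinuation rule the drug must additionally have stopped while
#' the VKA continued: its last matched administration day precedes the
#' VKA's last administration day.
#'
#' @param stay one-row data.frame (or list) with the stay's fields.
#' @param administrations administrations of that stay.
#' @param rule one rule row from [expand_rules()].
#' @param config a [ddi_config()].
#' @return "exposed" or "nonexposed".
#' @export
classify_exposure <- function(stay, administrations, rule, config = ddi_config()) {
  adm <- as.data.table(administrations)
  vka_days <- sort(unique(adm$day[startsWith(adm$atc_code, config$vka_atc_prefix)]))
  drug_days <- match_drug_days(adm$day, adm$atc_code,
                               rule$atc_codes[[1L]], rule$match_mode)
  co_days <- intersect(vka_days, drug_days)
  if (length(co_days) == 0L) return("nonexposed")
  if (rule$phase == "discontinuation" &&
      !(max(drug_days) < max(vka_days))) return("nonexposed")
  "exposed"
}

#' Build the observation window for a (stay, rule) pair
#'
#' Windows reflect a 1-day onset of action and a 4-day residual action
#' (configurable). An exposed initiation window opens the day after the
#' first co-administration day and closes \code{offset_lag_days} after
#' the first uninterrupted co-administration run ends (truncated at
#' discharge). An exposed discontinuation window opens the day after the
#' drug's last administration and closes \code{offset_lag_days} later
#' (truncated by the VKA's own residual window and discharge). A
#' nonexposed window spans the day after the first VKA administration to
#' \code{offset_lag_days} after the last one (truncated at discharge).
#' A window whose start exceeds its end is not applicable: the stay is
#' dropped from that rule's contingency table.
#'
#' @inheritParams classify_exposure
#' @param exposure_status result of [classify_exposure()].
#' @return A list with stay_id, rule_id, exposure_status ("exposed",
#'   "nonexposed" or "not_applicable") and, when applicable, start_day
#'   and end_day.
#' @export
build_window <- function(stay, administrations, rule, exposure_status,
                         config = ddi_config()) {
  adm <- as.data.table(administrations)
  vka_days <- sort(unique(adm$day[startsWith(adm$atc_code, config$vka_atc_prefix)]))
  dis <- stay$discharge_day
  onset <- config$onset_lag_days
  offset <- config$offset_lag_days
  if (exposure_status == "exposed") {
    drug_days <- match_drug_days(adm$day, adm$atc_code,
                                 rule$atc_codes[[1L]], rule$match_mode)
    co_days <- sort(intersect(vka_days, drug_days))
    if (rule$phase == "initiation") {
      start <- min(co_days) + onset
      end <- min(first_run_end(co_days) + offset, dis)
    } else {
      dl <- max(drug_days)
      start <- dl + onset
      end <- min(dl + offset, max(vka_days) + offset, dis)
    }
  } else {
    start <- min(vka_days) + onset
    end <- min(max(vka_days) + offset, dis)
  }
  if (start > end) {
    return(list(stay_id = stay$stay_id, rule_id = rule$rule_id,
                exposure_status = "not_applicable",
                start_day = NA_integer_, end_day = NA_integer_))
  }
  list(stay_id = stay$stay_id, rule_id = rule$rule_id,
       exposure_status = exposure_status,
       start_day = as.integer(start), end_day = as.integer(end))
}

#' Detect the rule's INR outcome inside an observation window
#'
#' True if at least one INR result within the window (bounds inclusive)
#' is at or beyond the rule's threshold: at or above
#' \code{inr_high_threshold} for an expected potentiation
#' (\code{INR_GE_HIGH}), at or below \code{inr_low_threshold} for an
#' expected inhibition (\code{INR_LE_LOW}).
#'
#' @param window result of [build_window()] with a day interval.
#' @param labs lab results of the stay.
#' @param rule the rule row.
#' @param config a [ddi_config()].
#' @return Logical.
#' @export
detect_outcome <- function(window, labs, rule, config = ddi_config()) {
  if (window$exposure_status == "not_applicable") {
    stop("cannot detect an outcome in a not_applicable window")
  }
  labs <- as.data.table(labs)
  v <- labs[analyte == "INR" & day >= window$start_day & day <= window$end_day,
            value]
  if (rule$expected_outcome == "INR_GE_HIGH") {
    any(v >= config$inr_high_threshold)
  } else {
    any(v <= config$inr_low_threshold)
  }
}

# Vectorized core: per-stay exposure status, window and outcome for one
# rule over a whole subcohort. Returns one row per stay.
rule_windows <- function(cohort, rule, config = ddi_config()) {
  adm <- cohort$administrations
  onset <- config$onset_lag_days
  offset <- config$offset_lag_days
  entry_atc <- rule$atc_codes[[1L]]
  is_vka <- startsWith(adm$atc_code, config$vka_atc_prefix)
  is_drug <- if (rule$match_mode == "prefix") {
    Reduce(`|`, lapply(entry_atc, function(p) startsWith(adm$atc_code, p)))
  } else {
    adm$atc_code %in% entry_atc
  }
  vka <- adm[is_vka, .(first_vka = min(day), last_vka = max(day)), by = stay_id]
  if (any(is_drug)) {
    drug <- adm[is_drug, .(drug_last = max(day)), by = stay_id]
    co <- merge(
      unique(adm[is_vka, .(stay_id, day)]),
      unique(adm[is_drug, .(stay_id, day)]),
      by = c("stay_id", "day"))[, .(co_days = list(sort(day))), by = stay_id]
  } else {
    drug <- data.table(stay_id = character(), drug_last = integer())
    co <- data.table(stay_id = character(), co_days = list())
  }

  w <- merge(cohort$stays[, .(stay_id, discharge_day)], vka, by = "stay_id")
  w <- merge(w, drug[, .(stay_id, drug_last)], by = "stay_id", all.x = TRUE)
  w <- merge(w, co, by = "stay_id", all.x = TRUE)
  has_co <- !vapply(w$co_days, is.null, logical(1))
  exposed <- if (rule$phase == "initiation") has_co else {
    has_co & !is.na(w$drug_last) & w$drug_last < w$last_vka
  }
  start <- integer(nrow(w)); end <- integer(nrow(w))
  ne <- !exposed
  start[ne] <- w$first_vka[ne] + onset
  end[ne] <- pmin(w$last_vka[ne] + offset, w$discharge_day[ne])
  if (any(exposed)) {
    idx <- which(exposed)
    if (rule$phase == "initiation") {
      co_first <- vapply(w$co_days[idx], `[`, integer(1), 1L)
      run_end <- vapply(w$co_days[idx], first_run_end, integer(1))
      start[idx] <- co_first + onset
      end[idx] <- pmin(run_end + offset, w$discharge_day[idx])
    } else {
      dl <- w$drug_last[idx]
      start[idx] <- dl + onset
      end[idx] <- pmin(dl + offset, w$last_vka[idx] + offset, w$discharge_day[idx])
    }
  }
  out <- data.table(stay_id = w$stay_id, rule_id = rule$rule_id,
                    exposure_status = ifelse(exposed, "exposed", "nonexposed"),
                    start_day = start, end_day = end)
  out[start_day > end_day,
      `:=`(exposure_status = "not_applicable",
           start_day = NA_integer_, end_day = NA_integer_)]

  # outcome: any in-window INR at/beyond the rule threshold
  inr <- cohort$labs[analyte == "INR"]
  hit <- if (rule$expected_outcome == "INR_GE_HIGH") {
    inr[value >= config$inr_high_threshold]
  } else {
    inr[value <= config$inr_low_threshold]
  }
  appl <- out[exposure_status != "not_applicable"]
  if (nrow(appl) && nrow(hit)) {
    m <- hit[appl, on = .(stay_id, day >= start_day, day <= end_day),
             nomatch = NULL]
    out[, outcome := stay_id %in% unique(m$stay_id) &
          exposure_status != "not_applicable"]
  } else {
    out[, outcome := FALSE]
  }
  out[exposure_status == "not_applicable", outcome := NA]
  out[]
}

#' Assemble the per-rule 2x2 contingency table
#'
#' Counts each included stay with an applicable window exactly once:
#' a = exposed with outcome, b = exposed without, c = nonexposed with,
#' d = nonexposed without. Stays whose window is not applicable are
#' excluded from all cells.
#'
#' @param cohort analyzed subcohort (a \code{ddi_cohort} after
#'   [apply_inclusion_criteria()]).
#' @param rule one rule row.
#' @param config a [ddi_config()].
#' @return A list: \code{table} (named integer a, b, c, d),
#'   \code{n_exposed} (= a + b), \code{windows} (per-stay detail).
#' @export
assemble_table <- function(cohort, rule, config = ddi_config()) {
  w <- rule_windows(cohort, rule, config)
  a <- w[exposure_status == "exposed" & outcome == TRUE, .N]
  b <- w[exposure_status == "exposed" & outcome == FALSE, .N]
  cc <- w[exposure_status == "nonexposed" & outcome == TRUE, .N]
  d <- w[exposure_status == "nonexposed" & outcome == FALSE, .N]
  list(table = c(a = a, b = b, c = cc, d = d),
       n_exposed = a + b, windows = w)
}
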