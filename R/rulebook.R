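DIRECTIONS <- c("potentiates_vka", "inhibits_vka", "both")
GROUPS <- c("analgesic_immunologic", "anti_infective", "cardiovascular",
            "cns", "other")
OUTCOMES <- c("INR_GE_HIGH", "INR_LE_LOW")
PHASES <- c("initiation", "discontinuation")

#' Load a DDI rulebook
#'
#' Reads a drug-entry table: one row per (drug, interaction direction)
#' pair, with its ATC codes (semicolon-separated; empty if the drug could
#' not be mapped to an ATC term), therapeutic group and ATC match mode.
#' Rows duplicated on (label, direction) are collapsed with a warning.
#'
#' @param path CSV (columns label, direction, atc_codes, group,
#'   match_mode) or JSON array of objects with the same fields.
#' @return A data.table of drug entries with list-column
#'   \code{atc_codes} and logical \code{unmappable}.
#' @export
load_rulebook <- function(path) {
  if (!file.exists(path)) stop("rulebook file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    dt <- as.data.table(raw)
    if (is.list(dt$atc_codes)) {
      dt[, atc_codes := vapply(atc_codes, paste, character(1), collapse = ";")]
    }
  } else {
    dt <- fread(path, colClasses = "character")
  }
  need <- c("label", "direction", "atc_codes", "group")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("rulebook is missing column(s): ", paste(miss, collapse = ", "))
  if (!"match_mode" %in% names(dt)) dt[, match_mode := "exact"]
  dt[match_mode == "" | is.na(match_mode), match_mode := "exact"]
  if (nrow(dt) == 0L) {
    return(data.table(label = character(), direction = character(),
                      atc_codes = list(), group = character(),
                      match_mode = character(), unmappable = logical()))
  }
  bad <- setdiff(unique(dt$direction), DIRECTIONS)
  if (length(bad)) stop("unknown direction token(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(dt$group), GROUPS)
  if (length(bad)) stop("unknown therapeutic group(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(dt$match_mode), c("exact", "prefix"))
  if (length(bad)) stop("unknown match_mode value(s): ", paste(bad, collapse = ", "))
  dt[, atc_codes := lapply(strsplit(atc_codes, ";", fixed = TRUE),
                           function(z) sort(z[nzchar(z)]))]
  badatc <- unlist(dt$atc_codes)[!is_valid_atc(unlist(dt$atc_codes))]
  if (length(badatc)) stop("invalid ATC code(s) in rulebook: ",
                           paste(unique(badatc), collapse = ", "))
  dup <- duplicated(dt[, .(label, direction)])
  if (any(dup)) {
    warning(sum(dup), " duplicate (label, direction) entr",
            if (sum(dup) == 1) "y" else "ies", " dropped")
    dt <- dt[!dup]
  }
  dt[, unmappable := lengths(atc_codes) == 0L]
  dt[]
}

#' Curate a loaded rulebook
#'
#' Performs the bookkeeping applied to the literature-derived drug list:
#' entries with no ATC term are excluded, and entries sharing an
#' identical ATC code set and direction are merged into one (labels
#' concatenated with " | ").
#'
#' @param entries output of [load_rulebook()].
#' @return A list: \code{entries} (curated data.table) and \code{report}
#'   (n_loaded, n_excluded_unmappable, n_merged, n_curated).
#' @export
curate_rulebook <- function(entries) {
  entries <- as.data.table(entries)
  n0 <- nrow(entries)
  if (!"unmappable" %in% names(entries)) {
    entries[, unmappable := lengths(atc_codes) == 0L]
  }
  mappable <- entries[unmappable == FALSE]
  n_excl <- n0 - nrow(mappable)
  if (nrow(mappable)) {
    mappable[, .atc_key := vapply(atc_codes, paste, character(1), collapse = ";")]
    merged <- mappable[, .(
      label = paste(sort(label), collapse = " | "),
      atc_codes = list(sort(unique(unlist(atc_codes)))),
      group = group[1L],
      match_mode = if (any(match_mode == "prefix")) "prefix" else "exact",
      n_source = .N
    ), by = .(.atc_key, direction)]
    n_merged_away <- sum(merged$n_source - 1L)
    curated <- merged[, .(label, direction, atc_codes, group, match_mode)]
    curated[, unmappable := FALSE]
    setorder(curated, group, label, direction)
  } else {
    curated <- mappable
    n_merged_away <- 0L
  }
  list(entries = curated[],
       report = list(n_loaded = n0,
                     n_excluded_unmappable = n_excl,
                     n_merged = n_merged_away,
                     n_curated = nrow(curated)))
}

#' Expand curated drug entries into DDI alert rules
#'
#' Each (drug, direction) entry yields an initiation rule and a
#' discontinuation rule with the opposite expected INR outcome: a
#' potentiating drug is expected to push the INR at or above the high
#' threshold upon initiation and at or below the low threshold upon
#' discontinuation; an inhibiting drug the reverse. An entry with
#' direction \code{both} yields all four rules.
#'
#' @param curated curated entries from [curate_rulebook()].
#' @param config a [ddi_config()] (unused constants are carried for
#'   interface stability).
#' @return A data.table of rules: rule_id, label, phase,
#'   expected_outcome, direction, group, atc_codes (list), match_mode.
#' @export
expand_rules <- function(curated, config = ddi_config()) {
  curated <- as.data.table(curated)
  if (nrow(curated) == 0L) {
    return(data.table(rule_id = character(), label = character(),
                      phase = character(), expected_outcome = character(),
                      direction = character(), group = character(),
                      atc_codes = list(), match_mode = character()))
  }
  if (any(lengths(curated$atc_codes) == 0L)) {
    stop("entries with empty atc_codes must be removed by curate_rulebook() first")
  }
  rows <- list()
  for (i in seq_len(nrow(curated))) {
    e <- curated[i]
    dirs <- if (e$direction == "both") c("potentiates_vka", "inhibits_vka") else e$direction
    for (d in dirs) {
      init_outcome <- if (d == "potentiates_vka") "INR_GE_HIGH" else "INR_LE_LOW"
      disc_outcome <- setdiff(OUTCOMES, init_outcome)
      for (ph in PHASES) {
        rows[[length(rows) + 1L]] <- data.table(
          label = e$label, phase = ph,
          expected_outcome = if (ph == "initiation") init_outcome else disc_outcome,
          direction = d, group = e$group,
          atc_codes = list(e$atc_codes[[1L]]), match_mode = e$match_mode)
      }
    }
  }
  rules <- rbindlist(rows)
  rules[, rule_id := sprintf("R%03d_%s_%s", .I, gsub("[^a-z0-9]+", "_", tolower(label)),
                             substr(phase, 1, 4))]
  setcolorder(rules, c("rule_id", "label", "phase", "expected_outcome",
                       "direction", "group", "atc_codes", "match_mode"))
  rules[]
}

#' Path to the synthetic rulebook fixture shipped with the package
#'
#' A 149-row drug-entry table emulating a literature-derived VKA
#' interaction list: 7 entries without ATC terms, one pair of entries
#' sharing an ATC code set (merged at curation), and 141 curated
#' (drug, direction) entries — 107 potentiating and 34 inhibiting, with
#' 4 drugs present in both categories. Drug names printed in published
#' VKA interaction reviews are used where available; the remainder are
#' placeholder rows labelled "synthetic".
#'
#' @return File path of the CSV.
#' @export
synthetic_rulebook_path <- function() {
  system.file("extdata", "rulebook_synthetic.csv", package = "spcddi",
              mustWork = TRUE)
}
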