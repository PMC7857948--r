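# Logistic-regression tier: covariate-adjusted and stepwise-selected
# odds ratios for one rule. Fitting goes through stats::glm.fit on an
# explicit design matrix (the per-rule loop refits the same covariate
# block hundreds of times; the formula interface would dominate the
# runtime). The absolute log-odds bound flagging separation.
SEPARATION_BOUND <- 15

covariate_fields <- function() names(COVARIATE_LEVELS)

# Dummy-coded covariate design (treatment contrasts, reference level
# first) plus the assignment of columns to covariates.
build_design <- function(profiles) {
  f <- stats::as.formula(paste("~", paste(covariate_fields(), collapse = " + ")))
  mm <- stats::model.matrix(f, data = profiles)
  assign <- attr(mm, "assign")
  list(x = mm[, assign != 0, drop = FALSE],
       groups = split(seq_len(sum(assign != 0)), assign[assign != 0]),
       group_names = covariate_fields())
}

# IRLS fit returning coefficients, standard errors, deviance and rank.
fit_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)))
  p <- ncol(X)
  coefs <- fit$coefficients
  se <- rep(NA_real_, p)
  r <- fit$rank
  if (r > 0) {
    Rm <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
    Rm[lower.tri(Rm)] <- 0
    cov <- tryCatch(chol2inv(Rm), error = function(e) NULL)
    if (!is.null(cov)) {
      piv <- fit$qr$pivot[seq_len(r)]
      se[piv] <- sqrt(pmax(diag(cov), 0))
    }
  }
  list(coef = coefs, se = se, deviance = fit$deviance, rank = r,
       converged = isTRUE(fit$converged), aic = fit$deviance + 2 * r)
}

# Shared extraction of the exposure OR from a fitted model: Wald
# interval on the coefficient; separation or a singular information
# matrix flags the result as not computable, keeping the point estimate
# (a coefficient diverging to -Inf prints as the degenerate "0").
exposure_or_from_fit <- function(fit, method, alpha, extra_notes = "") {
  beta <- unname(fit$coef[2L])  # column 2 is the exposure indicator
  se <- unname(fit$se[2L])
  notes <- extra_notes
  if (is.na(beta)) {
    return(or_result(method, computable = FALSE,
                     notes = paste0(notes, "exposure term aliased")))
  }
  point <- exp(beta)
  # a diverging coefficient anywhere in the model, a non-finite or
  # explosive exposure standard error, or nonconvergence all mark a
  # degenerate (separated) fit
  separated <- any(abs(fit$coef) > SEPARATION_BOUND, na.rm = TRUE) ||
    !is.finite(se) || is.na(se) || se > SEPARATION_BOUND || !fit$converged
  if (separated) {
    pt <- if (beta < -SEPARATION_BOUND) 0 else if (beta > SEPARATION_BOUND) Inf else point
    return(or_result(method, point = pt, computable = FALSE,
                     notes = paste0(notes, "separation or nonconvergence: ",
                                    "confidence limits not computable")))
  }
  z <- stats::qnorm(1 - alpha / 2)
  or_result(method, point = point, lower95 = exp(beta - z * se),
            upper95 = exp(beta + z * se), computable = TRUE, notes = notes)
}

#' Covariate-adjusted odds ratio for one rule
#'
#' Multivariable logistic regression of the in-window INR outcome on the
#' exposure indicator plus the seven categorized covariates (age,
#' albumin, prealbumin, creatinine, transaminases, TSH, Nt-proBNP),
#' reference levels as defined in \code{COVARIATE_LEVELS}. The adjusted
#' OR is the exponentiated exposure coefficient with a Wald interval.
#' Separation (|log OR| beyond the configured bound or a non-finite
#' standard error) and nonconvergence are flagged not computable.
#'
#' @param outcome logical vector, one element per stay with an
#'   applicable window.
#' @param exposed logical vector aligned with \code{outcome}.
#' @param profiles covariate profiles aligned with \code{outcome}
#'   (rows of [build_profiles()] for the same stays).
#' @param alpha two-sided type-1 error.
#' @param design optional precomputed [build_design()] result for
#'   \code{profiles} (an optimization for per-rule loops).
#' @return An \code{or_result}.
#' @export
adjusted_or <- function(outcome, exposed, profiles, alpha = 0.05,
                        design = NULL) {
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2L) {
    return(or_result("logistic_adjusted", computable = FALSE,
                     notes = "constant outcome"))
  }
  if (is.null(design)) design <- build_design(profiles)
  X <- cbind(`(Intercept)` = 1, exposure = as.numeric(exposed), design$x)
  fit <- fit_logistic(X, y)
  exposure_or_from_fit(fit, "logistic_adjusted", alpha)
}

#' Stepwise-selected odds ratio for one rule
#'
#' Bidirectional stepwise covariate selection by AIC, starting from the
#' full adjusted model, with the exposure term locked in the model. At
#' each step every single-covariate removal and re-entry is scored; the
#' move with the lowest AIC is taken until no move improves. Ties are
#' broken deterministically (removals first, covariates in declaration
#' order). The stepwise OR is the exposure OR of the final model.
#'
#' @inheritParams adjusted_or
#' @return An \code{or_result}; retained covariates are listed in
#'   \code{notes}.
#' @export
stepwise_or <- function(outcome, exposed, profiles, alpha = 0.05,
                        design = NULL) {
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2L) {
    return(or_result("logistic_stepwise", computable = FALSE,
                     notes = "constant outcome"))
  }
  if (is.null(design)) design <- build_design(profiles)
  base <- cbind(`(Intercept)` = 1, exposure = as.numeric(exposed))
  ngroup <- length(design$groups)
  included <- rep(TRUE, ngroup)

  fit_subset <- function(incl) {
    cols <- unlist(design$groups[incl], use.names = FALSE)
    X <- if (length(cols)) cbind(base, design$x[, cols, drop = FALSE]) else base
    fit_logistic(X, y)
  }
  current <- fit_subset(included)
  repeat {
    best_aic <- current$aic; best_incl <- NULL; best_fit <- NULL
    # all single moves scored; ties go to the earliest enumerated
    # (removals first, covariates in declaration order)
    moves <- c(which(included), which(!included))
    move_is_drop <- c(rep(TRUE, sum(included)), rep(FALSE, sum(!included)))
    for (m in seq_along(moves)) {
      cand <- included; cand[moves[m]] <- !move_is_drop[m]
      f <- fit_subset(cand)
      if (f$aic < best_aic - 1e-8) {
        best_aic <- f$aic; best_incl <- cand; best_fit <- f
      }
    }
    if (is.null(best_incl)) break
    included <- best_incl; current <- best_fit
  }
  kept <- design$group_names[included]
  exposure_or_from_fit(
    current, "logistic_stepwise", alpha,
    extra_notes = if (length(kept))
      paste0("retained: ", paste(kept, collapse = ","), "; ") else
      "retained: none; ")
}
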