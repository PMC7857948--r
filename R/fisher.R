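# Conditional (noncentral hypergeometric) machinery for the exact
# unadjusted odds ratio of a 2x2 table
#
#              outcome   no outcome
#   exposed       a          b       | r1 = a + b
#   nonexposed    c          d       | r2 = c + d
#                k = a + c
#
# Conditional on all margins, the exposed-with-outcome count X follows
# Fisher's noncentral hypergeometric distribution with odds ratio psi:
#   P(X = x | psi) ∝ choose(r1, x) choose(r2, k - x) psi^x,
# for x in [max(0, k - r2), min(k, r1)].

# Support and log binomial weights of the conditional distribution.
cond_support <- function(r1, r2, k) {
  lo <- max(0L, k - r2); hi <- min(k, r1)
  x <- lo:hi
  list(x = x, lw = lchoose(r1, x) + lchoose(r2, k - x), lo = lo, hi = hi)
}

# Normalized conditional pmf at log-odds-ratio t (log psi), computed with
# a log-sum-exp guard.
cond_pmf <- function(sup, t) {
  lp <- sup$lw + t * sup$x
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

# E[X | psi = exp(t)], strictly increasing in t.
cond_mean <- function(sup, t) {
  p <- cond_pmf(sup, t)
  sum(p * sup$x)
}

# P(X <= a | psi = exp(t)) (decreasing in t) and P(X >= a | psi = exp(t))
# (increasing in t).
cond_tail_le <- function(sup, t, a) sum(cond_pmf(sup, t)[sup$x <= a])
cond_tail_ge <- function(sup, t, a) sum(cond_pmf(sup, t)[sup$x >= a])

# Bracket bound for root finding on the log-odds scale: outside
# [-BOUND, BOUND] the conditional distribution is numerically degenerate
# at its support edge for any table this analysis can produce.
LOGPSI_BOUND <- 60

#' Exact (Fisher) unadjusted odds ratio for a 2x2 table
#'
#' Point estimate: the conditional maximum-likelihood odds ratio of the
#' noncentral hypergeometric model (the estimator reported by exact-test
#' implementations), found by solving E[X | psi] = a. 95% limits: exact
#' tail inversion at alpha/2 per side — the upper limit makes
#' P(X <= a) = alpha/2, the lower makes P(X >= a) = alpha/2. A zero
#' exposed-with-outcome cell yields a point estimate of 0 with lower
#' limit 0 and a finite upper limit; the symmetric degeneracies yield an
#' infinite point or upper limit, flagged in \code{notes}. Tables with
#' no outcome variation (a + c = 0 or b + d = 0) are not computable.
#'
#' @param table named or positional integer vector (a, b, c, d).
#' @param alpha two-sided type-1 error (default 0.05).
#' @return An \code{or_result} list: method, point, lower95, upper95,
#'   computable, notes.
#' @export
fisher_or <- function(table, alpha = 0.05) {
  a <- as.numeric(table[[1]]); b <- as.numeric(table[[2]])
  cc <- as.numeric(table[[3]]); d <- as.numeric(table[[4]])
  stopifnot(all(c(a, b, cc, d) >= 0))
  r1 <- a + b; r2 <- cc + d; k <- a + cc
  if (k == 0 || (b + d) == 0) {
    return(or_result("fisher_unadjusted", computable = FALSE,
                     notes = "no outcome variation"))
  }
  if (r1 == 0 || r2 == 0) {
    return(or_result("fisher_unadjusted", computable = FALSE,
                     notes = "empty exposure arm"))
  }
  sup <- cond_support(r1, r2, k)
  notes <- character()

  point <- if (a <= sup$lo) 0 else if (a >= sup$hi) Inf else {
    exp(stats::uniroot(function(t) cond_mean(sup, t) - a,
                       c(-LOGPSI_BOUND, LOGPSI_BOUND), tol = 1e-10)$root)
  }
  if (!is.finite(point) || point == 0) {
    notes <- c(notes, "degenerate cell: point estimate at boundary")
  }
  half <- alpha / 2
  lower <- if (a <= sup$lo) 0 else {
    exp(stats::uniroot(function(t) cond_tail_ge(sup, t, a) - half,
                       c(-LOGPSI_BOUND, LOGPSI_BOUND), tol = 1e-12)$root)
  }
  upper <- if (a >= sup$hi) Inf else {
    exp(stats::uniroot(function(t) cond_tail_le(sup, t, a) - half,
                       c(-LOGPSI_BOUND, LOGPSI_BOUND), tol = 1e-12)$root)
  }
  if (!is.finite(upper)) notes <- c(notes, "upper confidence limit infinite")
  or_result("fisher_unadjusted", point = point, lower95 = lower,
            upper95 = upper, computable = TRUE,
            notes = paste(notes, collapse = "; "))
}

# Constructor for the common odds-ratio result shape shared by the
# unadjusted, adjusted and stepwise tiers.
or_result <- function(method, point = NA_real_, lower95 = NA_real_,
                      upper95 = NA_real_, computable = TRUE, notes = "") {
  structure(list(method = method, point = point, lower95 = lower95,
                 upper95 = upper95, computable = computable, notes = notes),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  if (!x$computable) {
    cat(sprintf("%s: not computable (%s)\n", x$method, x$notes))
  } else {
    cat(sprintf("%s: OR %.3g (%.3g, %.3g)%s\n", x$method, x$point,
                x$lower95, x$upper95,
                if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  }
  invisible(x)
}

#' Format an odds-ratio result the way the result tables print it
#'
#' Half-up rounded to 2 decimals; noncomputable limits render as the
#' footnoted "0^d" pattern used when a degenerate fit leaves only the
#' point estimate.
#'
#' @param x an \code{or_result}.
#' @return A character scalar.
#' @export
format_or <- function(x) {
  if (is.null(x) || (!isTRUE(x$computable) && is.na(x$point))) return("NC")
  if (!isTRUE(x$computable)) return(sprintf("%s^d", format(round_half_up(x$point, 2))))
  fmt <- function(v) {
    if (!is.finite(v)) return("Inf")
    format(round_half_up(v, 2))
  }
  sprintf("%s (%s, %s)", fmt(x$point), fmt(x$lower95), fmt(x$upper95))
}
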