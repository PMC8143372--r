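#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction (df = 1), the default
#' for comparing response rates between rrSCNA groups; rows are groups,
#' columns outcomes.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return List with `statistic`, `p_value`, `df`, `expected`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(17, 4, 5, 5), 2, byrow = TRUE))$p_value # ~0.076
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0)) {
    abort("`table` must be a non-negative 2x2 matrix", "invalid_table_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin in 2x2 table", "zero_margin_error")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), expected = ht$expected)
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return List with `p_value` and the conditional odds-ratio estimate.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0)) {
    abort("`table` must be a non-negative 2x2 matrix", "invalid_table_error")
  }
  ht <- fisher.test(table)
  list(p_value = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Mann-Whitney U test
#'
#' Exact enumeration when both groups have at most 8 untied observations,
#' otherwise the normal approximation with tie correction (and continuity
#' correction). Two identical value sets return p = 1 by convention.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Largest per-group size for the exact test.
#' @return List with `U` and two-sided `p_value`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", "empty_sample_error")
  }
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  }
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p_value = ht$p.value)
}

#' Censoring policy for rank statistics on cohort tables
#'
#' Tumor fractions reported as `"<3.0%"` carry no recoverable value; for
#' rank-based statistics every censored entry enters at a single common
#' value just below the 3% gate (default 2.9%), producing ties that are
#' handled by average ranks. The policy value only needs to stay below the
#' smallest uncensored value for ranks to be unaffected by its exact
#' choice.
#'
#' @param value Common substitute (same scale as the data).
#' @return Object of class `censor_policy`.
#' @export
censor_policy <- function(value = 2.9) {
  structure(list(value = value), class = "censor_policy")
}

#' Spearman rank correlation with censored-value policy
#'
#' Ranks use average ties; p-value by the t approximation. Inputs may be
#' numeric, or character vectors in the cohort-table dialect where `"<x"`
#' entries are replaced by the censoring policy value.
#'
#' @param x,y Equal-length vectors (n >= 4).
#' @param policy A [censor_policy()] applied to censored character entries.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y, policy = censor_policy()) {
  resolve <- function(v) {
    if (is.character(v)) {
      censored <- grepl("^<", v)
      out <- suppressWarnings(as.numeric(sub("%", "", sub("^<", "", v))))
      out[censored] <- policy$value
      out
    } else {
      as.numeric(v)
    }
  }
  x <- resolve(x)
  y <- resolve(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", "length_mismatch_error")
  }
  if (length(x) < 4) abort("need n >= 4", "too_few_values_error")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Kaplan-Meier median survival
#'
#' Product-limit estimate; the median is the earliest time at which the
#' survival curve drops to 0.5 or below, undefined when the curve never
#' reaches 0.5 (e.g. all observations censored).
#'
#' @param time Survival times (> 0).
#' @param event Event indicators (1/TRUE = event).
#' @return List with `median`, `defined`, and the `survfit` object.
#' @export
km_median <- function(time, event) {
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  if (sum(event) == 0) {
    return(list(median = NA_real_, defined = FALSE, fit = fit))
  }
  # earliest time at which the curve reaches 0.5 (survfit's summary would
  # average across a plateau sitting exactly at 0.5)
  reached <- fit$surv <= 0.5 + 1e-12
  med <- if (any(reached)) min(fit$time[reached]) else NA_real_
  list(median = med, defined = !is.na(med), fit = fit)
}

#' Log-rank test between two groups
#'
#' Standard observed-minus-expected statistic over the shared risk sets,
#' referred to chi-square with 1 df. With no events in either group the
#' test is vacuous and p = 1.
#'
#' @param time Survival times.
#' @param event Event indicators.
#' @param group Two-level group labels.
#' @return List with `statistic`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.integer(event)
  if (length(unique(group)) != 2L) {
    abort("`group` must have exactly two levels", "invalid_group_error")
  }
  if (sum(event) == 0) return(list(statistic = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq),
       p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# Wald chi-square test of a (possibly multi-coefficient) term
term_wald <- function(fit, term_label) {
  asn <- fit$assign
  idx <- asn[[term_label]]
  b <- coef(fit)[idx]
  V <- vcov(fit)[idx, idx, drop = FALSE]
  w <- drop(t(b) %*% solve(V) %*% b)
  list(chisq = w, df = length(idx),
       p = pchisq(w, df = length(idx), lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Maximizes the partial likelihood with the Efron approximation for ties;
#' reports per-coefficient hazard ratios with Wald 95% confidence
#' intervals and p-values, plus a term-level Wald test for multi-level
#' factors. Non-convergence or a monotone likelihood (runaway
#' coefficients) is flagged, never silently returned.
#'
#' @param data Data frame of one record per subject.
#' @param time,event Column names of the survival time and event indicator.
#' @param covariates Character vector of covariate column names.
#' @return Object of class `cox_result`: list with `coefficients` (term,
#'   coef, hr, ci_low, ci_high, p), `term_tests`, `loglik`, `converged`,
#'   `flagged`, `model`.
#' @export
cox_fit <- function(data, time, event, covariates) {
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) abort(sprintf("covariate `%s` not found", cv),
                          "invalid_covariate_error")
    if (length(unique(v)) < 2L) {
      abort(sprintf("covariate `%s` is constant", cv),
            "constant_covariate_error")
    }
  }
  if (length(covariates) == 0) {
    abort("at least one covariate is required", "invalid_covariate_error")
  }
  fml <- stats::as.formula(paste(
    sprintf("survival::Surv(%s, %s)", time, event), "~",
    paste(covariates, collapse = " + ")
  ))
  ctl <- survival::coxph.control(eps = 1e-12, iter.max = 100,
                                 toler.chol = 1e-13)
  fit <- survival::coxph(fml, data = data, ties = "efron", control = ctl)
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  coefs <- data.frame(
    term = names(b), coef = unname(b), hr = exp(unname(b)),
    ci_low = exp(unname(b) - z * se), ci_high = exp(unname(b) + z * se),
    p = 2 * stats::pnorm(-abs(unname(b) / se)),
    stringsAsFactors = FALSE
  )
  term_tests <- do.call(rbind, lapply(covariates, function(tm) {
    tw <- term_wald(fit, tm)
    data.frame(term = tm, chisq = tw$chisq, df = tw$df, p = tw$p,
               stringsAsFactors = FALSE)
  }))
  flagged <- anyNA(b) || any(abs(b) > 15) || fit$iter >= 100
  structure(
    list(coefficients = coefs, term_tests = term_tests,
         retained = covariates, loglik = fit$loglik[2L],
         converged = !flagged, flagged = flagged, model = fit),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %d covariate(s)%s, logLik %.2f\n",
              length(x$retained),
              if (x$flagged) " [FLAGGED: check convergence]" else "",
              x$loglik))
  df <- x$coefficients
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %s: HR %.2f (95%% CI %.2f-%.2f); p = %.3g\n",
                df$term[i], df$hr[i], df$ci_low[i], df$ci_high[i], df$p[i]))
  }
  invisible(x)
}

#' Stepwise backward elimination for Cox models
#'
#' Starting from the full model, repeatedly removes the covariate with the
#' largest term-level Wald p-value exceeding `p_remove` and refits, until
#' every remaining covariate has p <= `p_remove`. An empty retained set is
#' a legitimate outcome and is reported as such.
#'
#' @inheritParams cox_fit
#' @param p_remove Removal threshold on the Wald p-value (default 0.10).
#' @return A `cox_result` for the final model, with `retained` holding the
#'   surviving covariates (possibly empty, in which case `coefficients` is
#'   empty) and `eliminated` the removal order.
#' @export
stepwise_backward <- function(data, time, event, covariates,
                              p_remove = 0.10) {
  remaining <- covariates
  eliminated <- character(0)
  fit <- NULL
  while (length(remaining) > 0) {
    fit <- cox_fit(data, time, event, remaining)
    p <- fit$term_tests$p
    worst <- which.max(p)
    if (p[worst] <= p_remove) break
    eliminated <- c(eliminated, remaining[worst])
    remaining <- remaining[-worst]
    fit <- NULL
  }
  if (is.null(fit)) {
    fit <- structure(
      list(coefficients = data.frame(), term_tests = data.frame(),
           retained = character(0), loglik = NA_real_, converged = TRUE,
           flagged = FALSE, model = NULL),
      class = "cox_result"
    )
  }
  fit$retained <- remaining
  fit$eliminated <- eliminated
  fit$p_remove <- p_remove
  fit
}
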