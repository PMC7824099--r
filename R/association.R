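## Case-control association statistics for nongenetic factors:
## 2x2 odds ratios with Wald intervals, logistic regression, and
## backward stepwise elimination on Wald p-values.

#' Odds ratio from a 2x2 contingency table
#'
#' Cross-product odds ratio with Wald confidence interval and p-value.
#' Cell convention: `a` = exposed cases, `b` = reference cases,
#' `c` = exposed controls, `d` = reference controls, so
#' `OR = (a d) / (b c)`.
#'
#' @param a,b,c,d Non-negative counts (see convention above).
#' @param ci_level Confidence level (default 0.95).
#' @return A list with `or`, `ci_lo`, `ci_hi`, `p`, `estimable`. With a
#'   zero cell the OR is unestimable: `estimable = FALSE` and the
#'   statistics are `NA`.
#' @examples
#' odds_ratio_2x2(26, 75, 184, 1042)  # OR 1.96 (1.22-3.15)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, ci_level = 0.95) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("cell counts must be non-negative integers")
  check_probability(ci_level, "ci_level")
  if (any(counts == 0))
    return(list(or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                p = NA_real_, estimable = FALSE))
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(or = or,
       ci_lo = exp(log(or) - z * se),
       ci_hi = exp(log(or) + z * se),
       p = 2 * stats::pnorm(-abs(log(or) / se)),
       estimable = TRUE)
}

#' Logistic regression fit with Wald statistics
#'
#' Binomial GLM (logit link) fit by iteratively reweighted least
#' squares, complete-case: rows with any missing value are dropped and
#' the used count reported. Convergence tolerance 1e-8, at most 100
#' iterations.
#'
#' @param design Data frame or matrix of covariates (no intercept
#'   column; one is added).
#' @param outcome Binary 0/1 vector.
#' @return A list of class `"logistic_fit"`: `coefficients` (log-odds),
#'   `standard_errors`, `wald_p_values`, `or` (exponentiated slopes),
#'   `converged`, `separation` (TRUE when fitted probabilities hit 0/1,
#'   a perfect-separation symptom), `n_used`, `fit` (the underlying
#'   `glm`).
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design)
  if (length(outcome) != nrow(design))
    stop_invalid("`outcome` length must match `design` rows")
  keep <- stats::complete.cases(design) & !is.na(outcome)
  design <- design[keep, , drop = FALSE]
  outcome <- outcome[keep]
  if (!all(outcome %in% 0:1))
    stop_invalid("`outcome` must be binary 0/1")
  if (length(unique(outcome)) < 2L)
    stop_invalid("outcome is constant (no events or no non-events)")
  non_const <- vapply(design, function(x) length(unique(x)) > 1L, TRUE)
  if (!all(non_const))
    stop_invalid("constant covariate column(s): %s",
                 paste(names(design)[!non_const], collapse = ", "))
  if (nrow(design) <= ncol(design) + 1L)
    stop_invalid("more terms than observations")

  dat <- cbind(.y = outcome, design)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (any(is.na(stats::coef(fit))))
    stop_invalid("singular design matrix")
  sm <- summary(fit)$coefficients
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  if (!fit$converged || separation)
    warning("logistic fit did not converge cleanly (possible separation); ",
            "coefficients reported as-is")
  structure(list(coefficients = sm[, "Estimate"],
                 standard_errors = sm[, "Std. Error"],
                 wald_p_values = sm[, "Pr(>|z|)"],
                 or = exp(sm[-1, "Estimate"]),
                 converged = fit$converged && !separation,
                 separation = separation,
                 n_used = length(outcome),
                 fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (n =", x$n_used, if (!x$converged)
    "; NOT converged", ")\n")
  print(data.frame(coef = x$coefficients, se = x$standard_errors,
                   p = x$wald_p_values))
  invisible(x)
}

#' Backward stepwise elimination on Wald p-values
#'
#' Starting from the full model, repeatedly removes the non-intercept
#' term with the largest Wald p-value at or above `alpha` and refits;
#' stops when every remaining term has p < `alpha` (possibly leaving an
#' intercept-only model). Ties are broken by the earlier column.
#'
#' @param design Data frame of candidate covariates.
#' @param outcome Binary 0/1 vector.
#' @param alpha Retention threshold on the Wald p-value (default 0.05).
#' @return A list with `retained` (column names kept, possibly empty),
#'   `dropped` (in removal order) and `fit` (the final
#'   [fit_logistic()] result, `NULL` when no term survived).
#' @export
backward_eliminate <- function(design, outcome, alpha = 0.05) {
  design <- as.data.frame(design)
  check_probability(alpha, "alpha")
  terms <- names(design)
  dropped <- character(0)
  fit <- NULL
  while (length(terms) > 0L) {
    fit <- fit_logistic(design[, terms, drop = FALSE], outcome)
    p <- fit$wald_p_values[-1]            # non-intercept terms, input order
    worst <- which(p >= alpha)
    if (length(worst) == 0L)
      return(list(retained = terms, dropped = dropped, fit = fit))
    ## remove the largest p; ties -> earliest column
    rm_idx <- worst[which.max(p[worst])]
    dropped <- c(dropped, terms[rm_idx])
    terms <- terms[-rm_idx]
    fit <- NULL
  }
  list(retained = character(0), dropped = dropped, fit = NULL)
}

#' Univariate odds-ratio table for a set of factors
#'
#' Convenience wrapper reproducing a case-control characteristics
#' table: for each column of `design`, fits a univariate logistic
#' regression of `outcome` on that column and reports the per-unit OR
#' with Wald CI and p-value.
#'
#' @param design Data frame of covariates.
#' @param outcome Binary 0/1 vector.
#' @param ci_level Confidence level.
#' @return Data frame with `term`, `or`, `ci_lo`, `ci_hi`, `p`, `n`.
#' @export
univariate_or_table <- function(design, outcome, ci_level = 0.95) {
  design <- as.data.frame(design)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  rows <- lapply(names(design), function(nm) {
    f <- fit_logistic(design[, nm, drop = FALSE], outcome)
    b <- f$coefficients[2]
    se <- f$standard_errors[2]
    data.frame(term = nm, or = exp(b), ci_lo = exp(b - z * se),
               ci_hi = exp(b + z * se), p = f$wald_p_values[2],
               n = f$n_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
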