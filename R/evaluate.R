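## Predictive-performance metrics: rank AUC with DeLong CI, per-point
## odds ratios, continuous NRI, stratified k-fold cross-validation,
## per-cohort evaluation.

#' Rank-based AUC with DeLong confidence interval
#'
#' The Mann-Whitney AUC (probability that a random case outscores a
#' random control, ties counted one half) with the DeLong asymptotic
#' confidence interval.
#'
#' @param scores Numeric scores (or a `score_set`).
#' @param status Binary 0/1 disease status; both classes required.
#' @param ci_level Confidence level (default 0.95).
#' @return A list with `auc`, `ci_lo`, `ci_hi`, `n_cases`,
#'   `n_controls`.
#' @export
auc_rank <- function(scores, status, ci_level = 0.95) {
  scores <- score_values(scores)
  keep <- !is.na(scores) & !is.na(status)
  scores <- scores[keep]; status <- status[keep]
  if (!all(status %in% 0:1)) stop_invalid("`status` must be binary 0/1")
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("both cases and controls are required for the AUC")
  roc <- pROC::roc(response = status, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  ci <- tryCatch(
    as.numeric(pROC::ci.auc(roc, conf.level = ci_level, method = "delong")),
    error = function(e) c(NA_real_, auc, NA_real_))
  list(auc = auc, ci_lo = ci[1], ci_hi = ci[3],
       n_cases = n1, n_controls = n0)
}

#' Odds ratio per 1-point score increase
#'
#' Univariate logistic regression of disease status on a (0-10
#' normalized) score; the exponentiated slope is the odds ratio for
#' each 1-point increase.
#'
#' @param scores Numeric scores, normally a `score_set` on the 0-10
#'   scale.
#' @param status Binary 0/1 disease status.
#' @param ci_level Confidence level.
#' @return A list with `or`, `ci_lo`, `ci_hi`, `p`, `n`.
#' @export
per_point_or <- function(scores, status, ci_level = 0.95) {
  scores <- score_values(scores)
  f <- fit_logistic(data.frame(score = scores), status)
  b <- f$coefficients[2]; se <- f$standard_errors[2]
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(or = unname(exp(b)), ci_lo = unname(exp(b - z * se)),
       ci_hi = unname(exp(b + z * se)), p = unname(f$wald_p_values[2]),
       n = f$n_used)
}

#' Continuous net reclassification improvement
#'
#' Compares paired per-sample risks from two models:
#' `NRI_e = P(new > old | case) - P(new < old | case)` and
#' `NRI_ne = P(new < old | control) - P(new > old | control)`, ties
#' contributing to neither; the overall NRI is their sum (range
#' [-2, 2]).
#'
#' @param risk_old,risk_new Paired risks under the reference and the
#'   enhanced model.
#' @param status Binary 0/1 disease status.
#' @return A list with `nri_event`, `nri_nonevent`, `nri_overall`,
#'   `n_cases`, `n_controls`.
#' @export
continuous_nri <- function(risk_old, risk_new, status) {
  if (length(risk_old) != length(risk_new) ||
      length(risk_old) != length(status))
    stop_invalid("`risk_old`, `risk_new` and `status` must be aligned")
  keep <- !is.na(risk_old) & !is.na(risk_new) & !is.na(status)
  risk_old <- risk_old[keep]; risk_new <- risk_new[keep]
  status <- status[keep]
  if (!all(status %in% 0:1)) stop_invalid("`status` must be binary 0/1")
  up <- risk_new > risk_old
  down <- risk_new < risk_old
  ev <- status == 1
  if (!any(ev) || all(ev)) stop_invalid("need both cases and controls")
  nri_e <- mean(up[ev]) - mean(down[ev])
  nri_ne <- mean(down[!ev]) - mean(up[!ev])
  list(nri_event = nri_e, nri_nonevent = nri_ne,
       nri_overall = nri_e + nri_ne,
       n_cases = sum(ev), n_controls = sum(!ev))
}

#' Stratified k-fold cross-validation of a score
#'
#' Partitions samples into k folds preserving the case/control ratio
#' (fold class counts differ by at most one). For each fold the
#' normalization parameters are fitted on the training folds only, the
#' held-out fold is normalized with them (out-of-range values clipped),
#' and the fold AUC and per-point OR are computed on the held-out
#' samples.
#'
#' @param raw_scores Raw (unnormalized) scores, fixed functions of the
#'   inputs (SNP weights are external, so no per-fold refitting of
#'   effects is involved).
#' @param status Binary 0/1 disease status.
#' @param k Number of folds (default 10); must not exceed either class
#'   count.
#' @param seed Integer seed fixing the fold assignment.
#' @param score_type Passed to [minmax_normalize()].
#' @return A list with `folds` (per-fold data frame: fold, n, n_cases,
#'   auc, per_point_or), `mean_auc`, `sd_auc`, `assignment` (fold id
#'   per sample).
#' @export
kfold_cv <- function(raw_scores, status, k = 10L, seed = 1L,
                     score_type = "liability") {
  raw_scores <- score_values(raw_scores)
  k <- check_count(k, "k", min = 2L)
  keep <- !is.na(raw_scores) & !is.na(status)
  if (!all(status[keep] %in% 0:1)) stop_invalid("`status` must be binary 0/1")
  idx_case <- which(keep & status == 1)
  idx_ctrl <- which(keep & status == 0)
  if (min(length(idx_case), length(idx_ctrl)) < k)
    stop_invalid("class too small for %d stratified folds", k)
  set.seed(seed)
  fold <- rep(NA_integer_, length(raw_scores))
  fold[idx_case] <- sample(rep_len(seq_len(k), length(idx_case)))
  fold[idx_ctrl] <- sample(rep_len(seq_len(k), length(idx_ctrl)))

  rows <- lapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- which(!is.na(fold) & fold != f)
    ss <- suppressWarnings(
      minmax_normalize(raw_scores[test], reference = raw_scores[train],
                       score_type = score_type))
    a <- auc_rank(ss$normalized, status[test])
    pp <- tryCatch(per_point_or(ss$normalized, status[test]),
                   error = function(e) list(or = NA_real_))
    data.frame(fold = f, n = length(test), n_cases = sum(status[test] == 1),
               auc = a$auc, per_point_or = pp$or)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds, mean_auc = mean(folds$auc),
       sd_auc = stats::sd(folds$auc), assignment = fold)
}

#' Per-cohort evaluation
#'
#' Computes the rank AUC and per-point OR within each cohort label;
#' cohorts lacking either class are skipped with a recorded reason.
#'
#' @param scores Numeric scores (or a `score_set`).
#' @param status Binary 0/1 disease status.
#' @param cohort Cohort label per sample.
#' @return A list with `table` (cohort, n, n_cases, auc, ci_lo, ci_hi,
#'   per_point_or) and `skipped` (named character vector of reasons).
#' @export
per_cohort_eval <- function(scores, status, cohort) {
  scores <- score_values(scores)
  skipped <- character(0)
  rows <- list()
  for (lab in unique(cohort)) {
    i <- which(cohort == lab & !is.na(scores) & !is.na(status))
    if (length(unique(status[i])) < 2L) {
      skipped[lab] <- "only one class present"
      next
    }
    a <- auc_rank(scores[i], status[i])
    pp <- tryCatch(per_point_or(scores[i], status[i]),
                   error = function(e) list(or = NA_real_))
    rows[[lab]] <- data.frame(cohort = lab, n = length(i),
                              n_cases = sum(status[i] == 1),
                              auc = a$auc, ci_lo = a$ci_lo,
                              ci_hi = a$ci_hi, per_point_or = pp$or)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tab)) rownames(tab) <- NULL
  list(table = tab, skipped = skipped)
}
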