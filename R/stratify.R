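## Discrete (cutoff) and quartile risk stratification.

#' Dichotomize scores at a cutoff and tabulate classification
#'
#' Samples with `score >= cutoff` are called high risk. Reports the
#' confusion counts against disease status plus sensitivity,
#' specificity and the percentage correctly classified; the high/low
#' odds ratio is attached via [odds_ratio_2x2()] and flagged
#' unestimable when a cell is empty.
#'
#' @param scores Numeric scores (or a `score_set`, whose normalized
#'   values are used).
#' @param status Binary 0/1 disease status.
#' @param cutoff High-risk threshold (inclusive).
#' @return A list with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `percent_correct`, `low_control_fraction`,
#'   `or` (list from [odds_ratio_2x2()]).
#' @export
dichotomize <- function(scores, status, cutoff) {
  scores <- score_values(scores)
  if (length(scores) != length(status))
    stop_invalid("`scores` and `status` must be aligned")
  keep <- !is.na(scores) & !is.na(status)
  scores <- scores[keep]; status <- status[keep]
  if (!all(status %in% 0:1)) stop_invalid("`status` must be binary 0/1")
  if (sum(status) == 0L || sum(status) == length(status))
    stop_invalid("need both cases and controls")
  high <- scores >= cutoff
  tp <- sum(high & status == 1); fn <- sum(!high & status == 1)
  fp <- sum(high & status == 0); tn <- sum(!high & status == 0)
  or <- odds_ratio_2x2(tp, fn, fp, tn)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       percent_correct = (tp + tn) / length(status),
       low_control_fraction = tn / (tn + fp),
       or = or)
}

#' Quartile risk groups with Q4-vs-Q1 odds ratio
#'
#' Assigns each sample to a quartile of the pooled score distribution
#' (boundaries at the 25/50/75th linear-interpolation percentiles;
#' scores equal to a boundary fall in the lower group), tabulates cases
#' and controls per group, and computes the highest-vs-lowest quartile
#' odds ratio.
#'
#' @param scores Numeric scores (or a `score_set`).
#' @param status Binary 0/1 disease status.
#' @return A list with `group` (factor Q1-Q4 per sample), `counts`
#'   (data frame: group, cases, controls, case_fraction), `or_q4_q1`
#'   (list from [odds_ratio_2x2()]) and `boundaries`.
#' @export
quartile_assign <- function(scores, status) {
  scores <- score_values(scores)
  keep <- !is.na(scores) & !is.na(status)
  scores <- scores[keep]; status <- status[keep]
  if (length(unique(scores)) < 4L)
    stop_invalid("need at least 4 distinct score values for quartiles")
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  grp <- factor(paste0("Q", categorize(scores, qs) + 1L),
                levels = paste0("Q", 1:4))
  counts <- data.frame(group = levels(grp),
                       cases = as.integer(tapply(status, grp, sum,
                                                 default = 0L)),
                       controls = as.integer(tapply(1 - status, grp, sum,
                                                    default = 0L)))
  counts$case_fraction <- with(counts, cases / pmax(cases + controls, 1L))
  or <- odds_ratio_2x2(counts$cases[4], counts$cases[1],
                       counts$controls[4], counts$controls[1])
  list(group = grp, counts = counts, or_q4_q1 = or, boundaries = qs)
}

score_values <- function(scores) {
  if (inherits(scores, "score_set")) scores$normalized else as.numeric(scores)
}
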