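## Polygenic risk scores and the common 0-10 min-max scale.

#' Polygenic risk score
#'
#' Dosage-weighted sum of per-SNP natural-log odds ratios:
#' `PRS = sum_i log(OR_i) * x_i`, with `x_i` the risk-allele count at
#' locus i. Samples missing any dosage in the panel get `NA`
#' (complete-case), with the count in attribute `n_excluded`.
#'
#' @param dosages Matrix (samples x loci) of risk-allele counts 0/1/2,
#'   columns named by rsid.
#' @param weights SNP weight table with columns `rsid` and `or`.
#' @return Numeric vector of raw scores.
#' @export
compute_prs <- function(dosages, weights) {
  weights <- validate_snp_weights(weights, need_raf = FALSE)
  dosages <- as.matrix(dosages)
  miss <- setdiff(weights$rsid, colnames(dosages))
  if (length(miss))
    stop_invalid("dosage matrix lacks loci: %s",
                 paste(utils::head(miss, 5), collapse = ", "))
  d <- dosages[, weights$rsid, drop = FALSE]
  if (any(!is.na(d) & !(d %in% 0:2)))
    stop_invalid("dosages must be 0, 1 or 2")
  s <- as.numeric(d %*% log(weights$or))
  attr(s, "n_excluded") <- sum(is.na(s))
  s
}

#' Nongenetic risk score
#'
#' Covariate analogue of the polygenic risk score: the sum over
#' schemes of the natural-log odds ratio of the sample's assigned
#' category, `sum_j log(OR_{j, c_j})`.
#'
#' @param categories Data frame of 0-based category codes, columns
#'   named by scheme.
#' @param schemes List of [covariate_scheme()] objects.
#' @return Numeric vector of raw scores (`NA` for incomplete samples).
#' @export
nongenetic_score <- function(categories, schemes) {
  if (inherits(schemes, "covariate_scheme")) schemes <- list(schemes)
  s <- numeric(nrow(categories))
  for (sc in schemes) {
    if (!sc$name %in% names(categories))
      stop_invalid("category table lacks scheme '%s'", sc$name)
    cc <- categories[[sc$name]]
    ok <- is.na(cc) | cc %in% (seq_along(sc$ors) - 1L)
    if (!all(ok)) stop_invalid("invalid category for scheme '%s'", sc$name)
    s <- s + log(sc$ors)[cc + 1L]
  }
  attr(s, "n_excluded") <- sum(is.na(s))
  s
}

#' Min-max normalization to the common 0-10 scale
#'
#' Affine map `(x - x_min) / x_range * 10` with `x_min` and `x_range`
#' taken from a reference value set (default: the values themselves),
#' so the reference spans exactly [0, 10]. Values outside the reference
#' range (e.g. held-out fold samples) are clipped to [0, 10]; the clip
#' count is recorded.
#'
#' @param values Numeric vector of raw scores.
#' @param reference Optional reference values fixing the normalization;
#'   also accepts a previous `score_set` to reuse its parameters.
#' @param score_type Label: `"liability"`, `"prs"`, `"nongenetic"` or
#'   `"multifactorial"`.
#' @param sample_ids Optional sample identifiers.
#' @return A data frame of class `"score_set"` with columns `sample`,
#'   `raw`, `normalized`; attributes `x_min`, `x_range`, `score_type`
#'   and `n_clipped`.
#' @export
minmax_normalize <- function(values, reference = NULL,
                             score_type = c("liability", "prs",
                                            "nongenetic", "multifactorial"),
                             sample_ids = NULL) {
  score_type <- match.arg(score_type)
  if (inherits(reference, "score_set")) {
    x_min <- attr(reference, "x_min")
    x_range <- attr(reference, "x_range")
  } else {
    ref <- reference %||% values
    ref <- ref[!is.na(ref)]
    if (length(ref) == 0L) stop_invalid("reference has no finite values")
    x_min <- min(ref)
    x_range <- max(ref) - x_min
  }
  if (x_range <= 0)
    stop_invalid("reference range is zero; scores cannot be normalized")
  norm <- (values - x_min) / x_range * 10
  n_clip <- sum(norm < 0 | norm > 10, na.rm = TRUE)
  if (n_clip > 0)
    warning(n_clip, " value(s) outside the reference range clipped to [0, 10]")
  norm <- pmin(pmax(norm, 0), 10)
  out <- data.frame(sample = sample_ids %||% seq_along(values),
                    raw = as.numeric(values), normalized = norm)
  structure(out, class = c("score_set", "data.frame"),
            x_min = x_min, x_range = x_range,
            score_type = score_type, n_clipped = n_clip)
}

#' @export
print.score_set <- function(x, ...) {
  cat("Score set (", attr(x, "score_type"), "): ", nrow(x), " samples, ",
      "x_min = ", signif(attr(x, "x_min"), 4),
      ", x_range = ", signif(attr(x, "x_range"), 4), "\n", sep = "")
  print.data.frame(utils::head(x))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
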