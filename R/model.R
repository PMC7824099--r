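#' Fit a liability-threshold risk model
#'
#' Builds a probit (liability-threshold) disease-risk model from a SNP
#' weight table and/or categorical covariate schemes. Each per-allele
#' odds ratio is converted to per-genotype penetrances and centered
#' liability mean shifts via [locus_effects()]; covariate schemes go
#' through [covariate_effects()]. An individual's measured liability is
#' the sum of their per-locus and per-category shifts; posterior risk is
#' the normal tail beyond the prevalence threshold given that liability.
#'
#' Three model flavours fall out of the inputs: genetic (`weights`
#' only), nongenetic (`schemes` only) and multifactorial (both); the
#' liabilities of the multifactorial model are exactly the sum of the
#' component liabilities by construction.
#'
#' @param weights SNP weight table: a data frame with columns `rsid`,
#'   `raf` (population risk-allele frequency) and `or` (per-allele odds
#'   ratio); columns `chrom`, `pos`, `risk_allele`, `nonrisk_allele` are
#'   carried through if present. See [read_snp_weights()].
#' @param schemes List of [covariate_scheme()] objects (or `NULL`).
#' @param prevalence Disease prevalence `K` in (0, 1).
#' @param heritability Liability-scale heritability `h2` in `[0, 1]`,
#'   used only by the family-history update and the cohort simulator.
#' @param family_history `"conditional"` (default): positive family
#'   history adds the conditional polygenic mean shift of
#'   [family_history_update()]; `"off"`: family history ignored.
#' @param effect_scale How per-allele/per-category effects are read:
#'   `"rr"` (relative risks, default) or `"or"` (odds ratios); see
#'   [locus_effects()].
#' @return An object of class `"liability_model"` with components
#'   `prevalence`, `heritability`, `threshold`, `loci` (per-locus shift
#'   table), `schemes`, `scheme_effects`, `variance_explained` (total
#'   `V`), `genetic_variance`, `covariate_variance` and `fh_shift`.
#' @examples
#' w <- data.frame(rsid = c("rs1", "rs2"), raf = c(0.3, 0.1),
#'                 or = c(1.3, 1.5))
#' m <- liability_model(w, prevalence = 0.17, heritability = 0.5)
#' m
#' @export
liability_model <- function(weights = NULL, schemes = NULL,
                            prevalence = 0.17, heritability = 0.5,
                            family_history = c("conditional", "off"),
                            effect_scale = c("rr", "or")) {
  check_probability(prevalence, "prevalence")
  check_fraction(heritability, "heritability")
  family_history <- match.arg(family_history)
  effect_scale <- match.arg(effect_scale)
  if (is.null(weights) && is.null(schemes))
    stop_invalid("supply `weights`, `schemes`, or both")

  loci <- NULL
  v_g <- 0
  if (!is.null(weights)) {
    weights <- validate_snp_weights(weights)
    eff <- lapply(seq_len(nrow(weights)), function(i)
      locus_effects(weights$raf[i], weights$or[i], prevalence,
                    effect_scale = effect_scale))
    loci <- weights
    loci$mu0 <- vapply(eff, function(e) e$mu[1], 0)
    loci$mu1 <- vapply(eff, function(e) e$mu[2], 0)
    loci$mu2 <- vapply(eff, function(e) e$mu[3], 0)
    loci$variance <- vapply(eff, function(e) e$variance, 0)
    v_g <- sum(loci$variance)
  }

  scheme_effects <- NULL
  v_c <- 0
  if (!is.null(schemes)) {
    if (inherits(schemes, "covariate_scheme")) schemes <- list(schemes)
    names(schemes) <- vapply(schemes, function(s) s$name, "")
    scheme_effects <- lapply(schemes, covariate_effects,
                             prevalence = prevalence,
                             effect_scale = effect_scale)
    v_c <- sum(vapply(scheme_effects, function(e) e$variance, 0))
  }

  V <- v_g + v_c
  if (V >= 1)
    stop_invalid(paste0("model misspecified: measured factors explain ",
                        "%.3f of unit liability variance"), V)

  T_ <- stats::qnorm(1 - prevalence)
  resid_h2 <- max(heritability - v_g, 0)
  structure(list(
    prevalence = prevalence,
    heritability = heritability,
    threshold = T_,
    loci = loci,
    schemes = schemes,
    scheme_effects = scheme_effects,
    variance_explained = V,
    genetic_variance = v_g,
    covariate_variance = v_c,
    family_history = family_history,
    effect_scale = effect_scale,
    fh_correlation = 0.5 * heritability,
    fh_shift = if (family_history == "conditional")
      0.5 * resid_h2 * stats::dnorm(T_) / prevalence else 0
  ), class = "liability_model")
}

#' @export
print.liability_model <- function(x, ...) {
  kind <- if (!is.null(x$loci) && !is.null(x$schemes)) "multifactorial"
          else if (!is.null(x$loci)) "genetic" else "nongenetic"
  cat("Liability-threshold risk model (", kind, ")\n", sep = "")
  cat(sprintf("  prevalence K = %.3f  (threshold T = %.4f)\n",
              x$prevalence, x$threshold))
  cat(sprintf("  heritability h2 = %.2f\n", x$heritability))
  if (!is.null(x$loci))
    cat(sprintf("  %d loci, genetic variance explained = %.4f\n",
                nrow(x$loci), x$genetic_variance))
  if (!is.null(x$schemes))
    cat(sprintf("  %d covariate schemes, covariate variance = %.4f\n",
                length(x$schemes), x$covariate_variance))
  cat(sprintf("  total variance explained V = %.4f\n", x$variance_explained))
  if (x$fh_shift > 0)
    cat(sprintf("  family-history liability shift = %.4f\n", x$fh_shift))
  invisible(x)
}

#' @export
summary.liability_model <- function(object, ...) {
  out <- list(model = object,
              locus_table = object$loci,
              scheme_table = if (!is.null(object$scheme_effects))
                data.frame(
                  scheme = names(object$scheme_effects),
                  n_categories = vapply(object$scheme_effects,
                                        function(e) length(e$mu), 0L),
                  variance = vapply(object$scheme_effects,
                                    function(e) e$variance, 0)))
  class(out) <- "summary.liability_model"
  out
}

#' @export
print.summary.liability_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$locus_table)) {
    cat("\nPer-locus liability shifts (head):\n")
    print(utils::head(x$locus_table[, c("rsid", "raf", "or",
                                        "mu0", "mu1", "mu2", "variance")]))
  }
  if (!is.null(x$scheme_table)) {
    cat("\nCovariate schemes:\n")
    print(x$scheme_table, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.liability_model <- function(object, ...) {
  out <- numeric(0)
  if (!is.null(object$loci)) {
    g <- as.vector(t(as.matrix(object$loci[, c("mu0", "mu1", "mu2")])))
    names(g) <- paste0(rep(object$loci$rsid, each = 3), ":g",
                       rep(0:2, nrow(object$loci)))
    out <- c(out, g)
  }
  if (!is.null(object$scheme_effects)) {
    for (nm in names(object$scheme_effects)) {
      e <- object$scheme_effects[[nm]]
      v <- e$mu
      names(v) <- paste0(nm, ":c", seq_along(v) - 1L)
      out <- c(out, v)
    }
  }
  out
}

#' Measured liability of samples under a fitted model
#'
#' Sums per-locus genotype shifts and per-scheme category shifts;
#' samples missing any required genotype or category are excluded
#' (complete-case) and returned as `NA`, with the exclusion count in
#' attribute `n_excluded`.
#'
#' @param model A [liability_model()].
#' @param dosages Numeric matrix (samples x loci) of risk-allele counts
#'   0/1/2, columns named by rsid; `NULL` for a nongenetic model.
#' @param categories Data frame (samples x schemes) of category codes
#'   (0-based), columns named by scheme; `NULL` for a genetic model.
#' @param fh Optional family-history flag vector (0/1/NA); applied via
#'   [family_history_update()] when the model's family-history mode is
#'   `"conditional"`.
#' @return Numeric vector of measured liabilities (NA = excluded).
#' @export
measured_liability <- function(model, dosages = NULL, categories = NULL,
                               fh = NULL) {
  stopifnot(inherits(model, "liability_model"))
  n <- if (!is.null(dosages)) nrow(dosages)
       else if (!is.null(categories)) nrow(categories)
       else stop_invalid("no sample data supplied")
  L <- numeric(n)

  if (!is.null(model$loci)) {
    if (is.null(dosages))
      stop_invalid("model has loci but no `dosages` supplied")
    dosages <- as.matrix(dosages)
    miss <- setdiff(model$loci$rsid, colnames(dosages))
    if (length(miss))
      stop_invalid("dosage matrix lacks loci: %s",
                   paste(utils::head(miss, 5), collapse = ", "))
    mu <- as.matrix(model$loci[, c("mu0", "mu1", "mu2")])
    for (i in seq_len(nrow(model$loci))) {
      d <- dosages[, model$loci$rsid[i]]
      bad <- !is.na(d) & !(d %in% 0:2)
      if (any(bad)) stop_invalid("dosages must be 0, 1 or 2")
      L <- L + mu[i, ][d + 1L]          # NA dosage propagates
    }
  }

  if (!is.null(model$scheme_effects)) {
    if (is.null(categories))
      stop_invalid("model has covariate schemes but no `categories` supplied")
    for (nm in names(model$scheme_effects)) {
      if (!nm %in% colnames(categories))
        stop_invalid("category table lacks scheme '%s'", nm)
      cc <- categories[[nm]]
      e <- model$scheme_effects[[nm]]
      ok <- is.na(cc) | (cc %in% (seq_along(e$mu) - 1L))
      if (!all(ok)) stop_invalid("invalid category code for scheme '%s'", nm)
      L <- L + e$mu[cc + 1L]
    }
  }

  if (!is.null(fh) && model$family_history == "conditional" &&
      model$fh_shift > 0) {
    fh0 <- ifelse(is.na(fh), 0, fh)
    L <- L + model$fh_shift * fh0
  }

  n_excl <- sum(is.na(L))
  if (n_excl > 0)
    message(n_excl, " sample(s) excluded for missing inputs (complete-case)")
  attr(L, "n_excluded") <- n_excl
  L
}

#' Predict from a liability-threshold model
#'
#' @param object A [liability_model()].
#' @param newdata A [simulate_cohort()] cohort, or a list with elements
#'   `dosages` (matrix, columns named by rsid), `categories` (data
#'   frame, columns named by scheme) and optionally `fh`, `sex`,
#'   `start_age`.
#' @param type `"liability"` (measured liability, the default),
#'   `"risk"` (posterior disease probability) or `"lifetime"`
#'   (incidence-based lifetime risk; requires `life_table`).
#' @param life_table Life table for `type = "lifetime"`.
#' @param use_fh Apply the family-history update when flags are present
#'   (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predictions (NA for incomplete samples).
#' @export
predict.liability_model <- function(object, newdata,
                                    type = c("liability", "risk", "lifetime"),
                                    life_table = NULL, use_fh = TRUE, ...) {
  type <- match.arg(type)
  nd <- as_model_data(newdata)
  L <- measured_liability(object, dosages = nd$dosages,
                          categories = nd$categories,
                          fh = if (use_fh) nd$fh)
  if (type == "liability") return(L)
  risk <- posterior_risk(L, object$variance_explained, object$prevalence)
  if (type == "risk") return(risk)
  if (is.null(life_table))
    stop_invalid("`life_table` required for lifetime risk")
  sex <- nd$sex %||% rep("female", length(L))
  start_age <- nd$start_age %||% rep(NA_real_, length(L))
  vapply(seq_along(risk), function(i) {
    if (is.na(risk[i])) return(NA_real_)
    as.numeric(lifetime_risk(risk[i] / object$prevalence, life_table,
                             sex = sex[i],
                             start_age = if (is.na(start_age[i])) NULL
                                         else start_age[i]))
  }, 0)
}

as_model_data <- function(newdata) {
  if (inherits(newdata, "dcvd_cohort"))
    return(list(dosages = newdata$dosages,
                categories = newdata$samples[, newdata$scheme_names,
                                             drop = FALSE],
                fh = newdata$samples$fh,
                sex = newdata$samples$sex,
                start_age = newdata$samples$age))
  if (is.list(newdata))
    return(list(dosages = newdata$dosages, categories = newdata$categories,
                fh = newdata$fh, sex = newdata$sex,
                start_age = newdata$start_age))
  stop_invalid("`newdata` must be a cohort or a list of model inputs")
}

#' @export
plot.liability_model <- function(x, from = -2, to = 3, ...) {
  L <- seq(from, to, length.out = 200)
  r <- posterior_risk(L, x$variance_explained, x$prevalence)
  graphics::plot(L, r, type = "l", xlab = "measured liability",
                 ylab = "posterior disease risk",
                 main = "Liability-threshold risk curve", ...)
  graphics::abline(v = x$threshold, lty = 2)
  graphics::abline(h = x$prevalence, lty = 3)
  invisible(x)
}
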