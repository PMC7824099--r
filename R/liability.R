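## Core liability-threshold (probit) machinery.
##
## Disease liability is latent N(0,1); disease occurs when liability
## exceeds T = qnorm(1 - K) for prevalence K. Each measured risk factor
## (SNP genotype or covariate category) shifts the liability mean; the
## shifts are derived from per-category odds ratios by (i) converting
## odds ratios to penetrances under the prevalence constraint and
## (ii) solving for mean shifts consistent with the probit link.

#' Liability threshold from disease prevalence
#'
#' The liability-threshold model places disease on the upper tail of a
#' standard-normal latent liability: an individual is affected when
#' liability exceeds `T = qnorm(1 - K)`, so that a fraction `K` of the
#' population is affected.
#'
#' @param prevalence Disease prevalence `K` in (0, 1).
#' @return The threshold in liability (standard-deviation) units.
#' @examples
#' threshold_from_prevalence(0.5)   # 0
#' threshold_from_prevalence(0.17)  # ~0.954
#' @export
threshold_from_prevalence <- function(prevalence) {
  check_probability(prevalence, "prevalence")
  stats::qnorm(1 - prevalence)
}

## Shared machinery for loci and covariate schemes: given category
## frequencies and category effect sizes (reference category 1), solve
## for penetrances and centered liability mean shifts.
##
## Penetrances: under the default relative-risk scale (the So-et-al.
## convention the liability framework builds on) f_g = f_0 * RR_g with
## sum(P_g f_g) = K, giving f_0 = K / sum(P_g RR_g) in closed form.
## Under the odds scale, odds(f_g) = odds(f_0) * OR_g and the
## prevalence constraint is solved on the logit scale by uniroot.
## Mean shifts mu_g satisfy 1 - pnorm((T - mu_g)/sqrt(1 - v)) = f_g
## where v = sum(P_g mu_g^2) is the variance the factor explains;
## mu_g inverts in closed form via qnorm, and v is found by fixed-point
## iteration (damped if oscillating).
category_effects <- function(freqs, ors, prevalence,
                             effect_scale = c("rr", "or"),
                             tol = 1e-10, max_iter = 100L) {
  effect_scale <- match.arg(effect_scale)
  check_probability(prevalence, "prevalence")
  if (length(freqs) != length(ors))
    stop_invalid("category frequencies and odds ratios differ in length")
  if (any(freqs <= 0))
    stop_invalid("every category must have frequency > 0")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop_invalid("category frequencies must sum to 1 (got %g)", sum(freqs))
  check_positive(ors, "odds ratios")
  if (abs(ors[1] - 1) > 1e-12)
    stop_invalid("reference category must have odds ratio 1")

  K <- prevalence
  T_ <- stats::qnorm(1 - K)

  if (all(abs(ors - 1) < 1e-14)) {
    mu <- rep(0, length(freqs))
    return(list(mu = mu, penetrance = rep(K, length(freqs)),
                variance = 0, freqs = freqs))
  }

  if (effect_scale == "rr") {
    f <- K * ors / sum(freqs * ors)
  } else {
    ## baseline penetrance on the logit scale: monotone in x
    log_or <- log(ors)
    g <- function(x) sum(freqs * stats::plogis(x + log_or)) - K
    root <- stats::uniroot(g, lower = -40, upper = 40, tol = 1e-12)
    f <- stats::plogis(root$root + log_or)
  }
  if (any(f >= 1 - 1e-12))
    stop_invalid("implied penetrance reaches 1; effect too large for prevalence %g", K)

  ## fixed point on the explained variance v
  v <- 0
  mu <- rep(0, length(freqs))
  prev_step <- NULL
  for (it in seq_len(max_iter)) {
    if (v >= 1)
      stop_invalid("factor would explain >= 100%% of liability variance")
    mu_raw <- T_ - sqrt(1 - v) * stats::qnorm(1 - f)
    mu_new <- mu_raw - sum(freqs * mu_raw)          # center: E[mu] = 0
    v_new <- sum(freqs * mu_new^2)
    step <- v_new - v
    if (!is.null(prev_step) && prev_step * step < 0)
      v_new <- v + 0.5 * step                        # damp oscillation
    delta <- max(abs(v_new - v), max(abs(mu_new - mu)))
    mu <- mu_new
    v <- v_new
    prev_step <- step
    if (delta < tol)
      return(list(mu = mu, penetrance = f, variance = v, freqs = freqs))
  }
  stop("liability shift iteration failed to converge after ", max_iter,
       " iterations")
}

#' Liability-scale effects of one SNP
#'
#' Converts a per-allele effect size and risk-allele frequency into
#' per-genotype penetrances and centered liability mean shifts under a
#' multiplicative genotype model: genotypic effects (1, r, r^2)
#' against the homozygous non-risk genotype, genotype frequencies from
#' Hardy-Weinberg equilibrium. By default the per-allele effect is
#' treated as a relative risk on the penetrance scale (the additive
#' relative-risk convention of the liability framework), so
#' `P(D|g) / P(D|0) = r^g` exactly; `effect_scale = "or"` instead
#' treats it as an odds ratio, `odds(D|g) = odds(D|0) * r^g`. For the
#' modest effects typical of SNP panels the two are nearly identical.
#'
#' @param raf Population risk-allele frequency in (0, 1).
#' @param or Per-allele effect size (> 0); relative risk by default.
#' @param prevalence Disease prevalence `K` in (0, 1).
#' @param effect_scale `"rr"` (default) or `"or"`, see Details.
#' @return A list with `mu` (centered liability shifts for genotypes
#'   0/1/2 copies of the risk allele), `penetrance` (per-genotype
#'   disease probabilities summing to `K` under HWE weights),
#'   `variance` (liability variance explained by the locus) and
#'   `freqs` (HWE genotype frequencies).
#' @examples
#' locus_effects(raf = 0.27, or = 1.5, prevalence = 0.17)
#' @export
locus_effects <- function(raf, or, prevalence, effect_scale = c("rr", "or")) {
  check_probability(raf, "raf")
  check_positive(or, "or")
  p <- raf
  freqs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  category_effects(freqs, c(1, or, or^2), prevalence,
                   effect_scale = effect_scale)
}

#' Liability-scale effects of a categorical covariate
#'
#' Identical machinery to [locus_effects()] with arbitrary category
#' frequencies and odds ratios in place of Hardy-Weinberg genotypes.
#'
#' @param scheme A [covariate_scheme()].
#' @param prevalence Disease prevalence in (0, 1).
#' @param effect_scale `"rr"` (default) or `"or"`, as in
#'   [locus_effects()].
#' @return As [locus_effects()], with one entry per category.
#' @export
covariate_effects <- function(scheme, prevalence,
                              effect_scale = c("rr", "or")) {
  scheme <- as_covariate_scheme(scheme)
  category_effects(scheme$frequencies, scheme$ors, prevalence,
                   effect_scale = effect_scale)
}

#' Covariate scheme: categories, frequencies and odds ratios
#'
#' A nongenetic risk factor coded into ordered categories (binary 0/1
#' or ordinal 0/1/2), with population category frequencies and
#' per-category odds ratios (reference category OR = 1). Optionally
#' carries a generator for raw covariate values and cut points used to
#' categorize them, which the synthetic cohort generator uses.
#'
#' @param name Covariate name.
#' @param frequencies Category frequencies, summing to 1.
#' @param ors Per-category odds ratios; first (reference) must be 1.
#' @param generator Optional `function(n)` drawing raw values.
#' @param cutpoints Optional increasing cut points mapping raw values to
#'   categories (`value <= cutpoint` falls in the lower category).
#' @return An object of class `"covariate_scheme"`.
#' @export
covariate_scheme <- function(name, frequencies, ors,
                             generator = NULL, cutpoints = NULL) {
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-8)
    stop_invalid("`frequencies` must be non-negative and sum to 1")
  check_positive(ors, "ors")
  if (abs(ors[1] - 1) > 1e-12)
    stop_invalid("reference category of `%s` must have OR = 1", name)
  if (length(frequencies) != length(ors))
    stop_invalid("`frequencies` and `ors` must have equal length")
  if (!is.null(cutpoints) && length(cutpoints) != length(ors) - 1L)
    stop_invalid("`cutpoints` must have one fewer entry than categories")
  structure(list(name = name, frequencies = frequencies, ors = ors,
                 generator = generator, cutpoints = cutpoints),
            class = "covariate_scheme")
}

as_covariate_scheme <- function(x) {
  if (inherits(x, "covariate_scheme")) return(x)
  stop_invalid("expected a `covariate_scheme` object")
}

#' @export
print.covariate_scheme <- function(x, ...) {
  cat("Covariate scheme:", x$name, "\n")
  print(data.frame(category = seq_along(x$ors) - 1L,
                   frequency = x$frequencies, or = x$ors))
  invisible(x)
}

#' Posterior disease risk given measured liability
#'
#' The probit posterior: with measured liability `L` explaining a
#' fraction `V` of unit liability variance, the unmeasured residual is
#' normal with variance `1 - V`, so
#' `risk = 1 - pnorm((T - L) / sqrt(1 - V))`.
#'
#' @param liability Measured liability (vector allowed).
#' @param variance_explained Fraction `V` of liability variance captured
#'   by the measured factors, in `[0, 1)`.
#' @param prevalence Disease prevalence in (0, 1).
#' @return Posterior probability of disease, strictly increasing in
#'   `liability`.
#' @examples
#' posterior_risk(0, 0, 0.17)  # population baseline = prevalence
#' @export
posterior_risk <- function(liability, variance_explained, prevalence) {
  check_probability(prevalence, "prevalence")
  if (!is.numeric(variance_explained) || variance_explained < 0 ||
      variance_explained >= 1)
    stop_invalid("`variance_explained` must lie in [0, 1)")
  T_ <- stats::qnorm(1 - prevalence)
  1 - stats::pnorm((T_ - liability) / sqrt(1 - variance_explained))
}

#' Family-history liability update
#'
#' Conditional mean shift of the unmeasured polygenic liability given
#' one affected first-degree relative. With relative-pair liability
#' correlation `rho = 0.5 * h2` and measured genetic variance `V_g`
#' already in the score, the residual shared component contributes
#' `delta = 0.5 * (h2 - V_g) * dnorm(T) / K` when family history is
#' positive; liability is unchanged when family history is negative or
#' unknown.
#'
#' @param liability Measured liability (vector allowed).
#' @param prevalence Disease prevalence `K`.
#' @param heritability Liability-scale heritability `h2` in `[0, 1]`.
#' @param genetic_variance Liability variance already explained by the
#'   measured SNPs (`V_g`), subtracted from the shared component.
#' @param fh Family-history flag per sample: 1 (positive), 0 (negative)
#'   or `NA` (unknown, treated as 0).
#' @return Adjusted liability.
#' @export
family_history_update <- function(liability, prevalence, heritability,
                                  genetic_variance = 0, fh = 0L) {
  check_probability(prevalence, "prevalence")
  check_fraction(heritability, "heritability")
  check_fraction(genetic_variance, "genetic_variance")
  T_ <- stats::qnorm(1 - prevalence)
  resid_h2 <- max(heritability - genetic_variance, 0)
  delta <- 0.5 * resid_h2 * stats::dnorm(T_) / prevalence
  fh <- ifelse(is.na(fh), 0, fh)
  liability + delta * fh
}

#' Incidence-based lifetime risk
#'
#' Cumulates an individual's disease risk over a life table of age- and
#' sex-specific incidence and disease-free mortality rates, treating
#' death free of disease as a competing event. The individual's hazard
#' in each band is `risk_ratio` times the band incidence; within each
#' band hazards are constant, giving the competing-risk increment
#' `S * h/(h+m) * (1 - exp(-(h+m) * width))` where `S` is disease-free
#' survival at band entry.
#'
#' @param risk_ratio Individual posterior risk divided by prevalence
#'   (>= 0); 1 gives the population-average lifetime risk.
#' @param life_table A [life_table] data frame (see [make_life_tables()]).
#' @param sex `"male"` or `"female"`.
#' @param start_age Age at which cumulation starts; bands ending before
#'   it are skipped and a band containing it is truncated.
#' @return Cumulative probability of disease by the end of the table,
#'   capped at 1.
#' @export
lifetime_risk <- function(risk_ratio, life_table, sex = c("female", "male"),
                          start_age = NULL) {
  check_positive(risk_ratio, "risk_ratio", strict = FALSE)
  sex <- match.arg(sex)
  lt <- validate_life_table(life_table)
  lt <- lt[lt$sex == sex, , drop = FALSE]
  if (nrow(lt) == 0L) stop_invalid("life table has no rows for sex '%s'", sex)
  lt <- lt[order(lt$age_lo), , drop = FALSE]
  if (is.null(start_age)) start_age <- lt$age_lo[1]
  if (start_age >= max(lt$age_hi))
    stop_invalid("`start_age` (%g) is beyond the life table", start_age)

  surv <- 1
  risk <- 0
  capped <- FALSE
  for (i in seq_len(nrow(lt))) {
    if (lt$age_hi[i] <= start_age) next
    lo <- max(lt$age_lo[i], start_age)
    width <- lt$age_hi[i] - lo
    h <- risk_ratio * lt$incidence_per_1000py[i] / 1000
    if (h > 1) {
      warning("band hazard ", signif(h, 3), " exceeds 1/person-year; capped")
      h <- 1
      capped <- TRUE
    }
    m <- lt$mortality_per_10000py[i] / 10000
    tot <- h + m
    if (tot > 0)
      risk <- risk + surv * (h / tot) * (1 - exp(-tot * width))
    surv <- surv * exp(-tot * width)
  }
  out <- min(risk, 1)
  attr(out, "capped") <- capped
  out
}
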