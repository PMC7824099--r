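## Synthetic cohort generation under the exact statistical model the
## analysis assumes: Hardy-Weinberg genotypes, additive liability,
## threshold disease, correlated-relative family history.

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws an n x m matrix of risk-allele counts, column j i.i.d. with
#' genotype probabilities ((1-p)^2, 2p(1-p), p^2) for risk-allele
#' frequency p.
#'
#' @param rafs Vector of risk-allele frequencies, each in (0, 1).
#' @param n Number of samples.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return Integer matrix of dosages in \{0, 1, 2\}, columns named by
#'   `names(rafs)` when present.
#' @export
simulate_genotypes <- function(rafs, n, seed = NULL) {
  if (any(rafs <= 0 | rafs >= 1))
    stop_invalid("all risk-allele frequencies must lie in (0, 1)")
  n <- check_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  m <- length(rafs)
  ## dosage ~ Binomial(2, p) is exactly the HWE genotype distribution
  g <- matrix(stats::rbinom(n * m, 2L, rep(rafs, each = n)), nrow = n)
  colnames(g) <- names(rafs)
  g
}

#' Simulation specification for a synthetic cohort
#'
#' Collects the study conditions for [simulate_cohort()]: the SNP
#' panel, covariate schemes, prevalence, heritability, family-history
#' relative correlation, number of cohorts and the master seed.
#' Defaults are the conditions of the case-control study the package
#' models: prevalence 0.17 (CVD among Korean adults with type 2
#' diabetes), heritability 0.5, four population cohorts.
#'
#' @param n_samples Number of individuals.
#' @param weights SNP weight table (see [liability_model()]); `NULL`
#'   for a purely nongenetic cohort.
#' @param schemes List of [covariate_scheme()]; defaults to
#'   [default_covariate_schemes()] when `NULL` and `weights` is `NULL`.
#' @param prevalence Disease prevalence `K`.
#' @param heritability Liability heritability `h2`.
#' @param fh_relative_correlation Liability correlation with one
#'   first-degree relative; default `0.5 * heritability`.
#' @param n_cohorts Number of cohort labels, assigned uniformly.
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_samples, weights = NULL, schemes = NULL,
                            prevalence = 0.17, heritability = 0.5,
                            fh_relative_correlation = 0.5 * heritability,
                            n_cohorts = 4L, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  check_probability(prevalence, "prevalence")
  check_fraction(heritability, "heritability")
  check_fraction(fh_relative_correlation, "fh_relative_correlation")
  n_cohorts <- check_count(n_cohorts, "n_cohorts")
  if (is.null(weights) && is.null(schemes))
    schemes <- default_covariate_schemes()
  structure(list(n_samples = n_samples, weights = weights,
                 schemes = schemes, prevalence = prevalence,
                 heritability = heritability,
                 fh_relative_correlation = fh_relative_correlation,
                 n_cohorts = n_cohorts, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a cohort under the liability-threshold model
#'
#' Each sample's liability is the sum of its per-locus genotype shifts,
#' per-category covariate shifts and a normal residual with variance
#' `1 - V`, so liability is N(0, 1) marginally and thresholding at
#' `qnorm(1 - K)` reproduces prevalence `K`. Family history is drawn
#' from one first-degree relative whose liability correlates with the
#' index individual at `fh_relative_correlation`; the relative is
#' affected (flag = 1) when their liability exceeds the same threshold.
#'
#' @param spec A [simulation_spec()].
#' @return An object of class `"dcvd_cohort"`: a list with `samples`
#'   (data frame: `sample_id`, `cohort`, `status`, `fh`, `liability`,
#'   raw covariate values and 0-based category codes), `dosages`
#'   (samples x loci matrix, `NULL` if no SNP panel), `scheme_names`,
#'   `model` (the underlying [liability_model()]) and `seed`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  model <- liability_model(weights = spec$weights, schemes = spec$schemes,
                           prevalence = spec$prevalence,
                           heritability = spec$heritability,
                           family_history = "off")
  n <- spec$n_samples
  L <- numeric(n)

  dosages <- NULL
  if (!is.null(model$loci)) {
    rafs <- model$loci$raf
    names(rafs) <- model$loci$rsid
    dosages <- simulate_genotypes(rafs, n, seed = derive_seed(spec$seed, 1L))
    mu <- as.matrix(model$loci[, c("mu0", "mu1", "mu2")])
    for (i in seq_len(nrow(model$loci)))
      L <- L + mu[i, ][dosages[, i] + 1L]
  }

  samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)))
  scheme_names <- character(0)
  if (!is.null(model$schemes)) {
    set.seed(derive_seed(spec$seed, 2L))
    for (s in model$schemes) {
      e <- model$scheme_effects[[s$name]]
      if (!is.null(s$generator)) {
        raw <- s$generator(n)
        cat_codes <- if (is.null(s$cutpoints)) as.integer(raw)
                     else categorize(raw, s$cutpoints)
        samples[[paste0(s$name, "_raw")]] <- raw
      } else {
        cat_codes <- sample(seq_along(s$frequencies) - 1L, n,
                            replace = TRUE, prob = s$frequencies)
      }
      samples[[s$name]] <- cat_codes
      L <- L + e$mu[cat_codes + 1L]
      scheme_names <- c(scheme_names, s$name)
    }
  }

  V <- model$variance_explained
  set.seed(derive_seed(spec$seed, 3L))
  liability <- L + stats::rnorm(n, 0, sqrt(1 - V))
  status <- as.integer(liability > model$threshold)

  rho <- spec$fh_relative_correlation
  rel <- rho * liability + sqrt(1 - rho^2) * stats::rnorm(n)
  fh <- as.integer(rel > model$threshold)

  samples$cohort <- sample(paste0("cohort", seq_len(spec$n_cohorts)),
                           n, replace = TRUE)
  samples$status <- status
  samples$fh <- fh
  samples$liability <- liability

  structure(list(samples = samples, dosages = dosages,
                 scheme_names = scheme_names, model = model,
                 seed = spec$seed),
            class = "dcvd_cohort")
}

categorize <- function(x, cutpoints) {
  ## value equal to a cut point falls in the lower category
  as.integer(rowSums(outer(x, cutpoints, ">")))
}

#' @export
print.dcvd_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$samples), "samples\n")
  cat("  cases:", sum(x$samples$status), sprintf("(%.1f%%)",
      100 * mean(x$samples$status)), "\n")
  if (!is.null(x$dosages)) cat("  loci:", ncol(x$dosages), "\n")
  if (length(x$scheme_names))
    cat("  covariates:", paste(x$scheme_names, collapse = ", "), "\n")
  cat("  cohorts:", length(unique(x$samples$cohort)), " seed:", x$seed, "\n")
  invisible(x)
}

#' @rdname simulate_cohort
#' @param object A fitted [liability_model()].
#' @param nsim Number of samples to draw.
#' @param seed Master seed.
#' @param n_cohorts,fh_relative_correlation Passed to
#'   [simulation_spec()].
#' @param ... Unused.
#' @export
simulate.liability_model <- function(object, nsim = 1000, seed = 1L,
                                     n_cohorts = 4L,
                                     fh_relative_correlation =
                                       0.5 * object$heritability, ...) {
  spec <- simulation_spec(
    n_samples = nsim,
    weights = object$loci,
    schemes = object$schemes,
    prevalence = object$prevalence,
    heritability = object$heritability,
    fh_relative_correlation = fh_relative_correlation,
    n_cohorts = n_cohorts, seed = seed)
  simulate_cohort(spec)
}

## ---- default covariate schemes -------------------------------------

## Truncated-normal helpers (age generator).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}
qtruncnorm <- function(p, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + p * (p_hi - p_lo), mean, sd)
}

## Mean of a density on (lo, hi], for converting per-unit odds ratios
## into per-tertile category odds ratios.
segment_mean <- function(dens, lo, hi, mass) {
  stats::integrate(function(x) x * dens(x), lo, hi,
                   rel.tol = 1e-9)$value / mass
}

tertile_scheme <- function(name, dens, quant, rand, per_unit_or) {
  cuts <- quant(c(1 / 3, 2 / 3))
  lo <- quant(1e-9); hi <- quant(1 - 1e-9)
  bounds <- c(lo, cuts, hi)
  means <- vapply(1:3, function(i)
    segment_mean(dens, bounds[i], bounds[i + 1], 1 / 3), 0)
  ors <- per_unit_or^(means - means[1])
  covariate_scheme(name, frequencies = rep(1 / 3, 3), ors = ors,
                   generator = rand, cutpoints = cuts)
}

#' Default nongenetic covariate schemes
#'
#' The four nongenetic risk factors retained in the multivariate model
#' of the case-control analysis the package emulates — age, sex, body
#' mass index and serum creatinine — coded as the liability model
#' expects: continuous covariates cut at population tertiles (ordinal
#' 0/1/2), sex binary. Per-category odds ratios are derived from the
#' published per-unit odds ratios (age 1.07 per year, BMI 1.06 per
#' kg/m^2, creatinine 2.62 per mg/dL, male sex 1.07) evaluated at the
#' tertile means of the generating distributions: age truncated normal
#' (mean 57, sd 9, range 40-69); BMI lognormal (mean 25.2, sd 3.5);
#' creatinine lognormal (mean 0.91, sd 0.45); sex Bernoulli(0.52).
#'
#' @return Named list of four [covariate_scheme()] objects.
#' @export
default_covariate_schemes <- function() {
  age <- tertile_scheme(
    "age",
    dens = function(x) stats::dnorm(x, 57, 9) /
      (stats::pnorm(69, 57, 9) - stats::pnorm(40, 57, 9)),
    quant = function(p) qtruncnorm(p, 57, 9, 40, 69),
    rand = function(n) rtruncnorm(n, 57, 9, 40, 69),
    per_unit_or = 1.07)

  lnorm_pars <- function(m, s) {
    sdlog <- sqrt(log(1 + (s / m)^2))
    c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  bp <- lnorm_pars(25.2, 3.5)
  bmi <- tertile_scheme(
    "bmi",
    dens = function(x) stats::dlnorm(x, bp[1], bp[2]),
    quant = function(p) stats::qlnorm(p, bp[1], bp[2]),
    rand = function(n) stats::rlnorm(n, bp[1], bp[2]),
    per_unit_or = 1.06)
  cp <- lnorm_pars(0.91, 0.45)
  creatinine <- tertile_scheme(
    "creatinine",
    dens = function(x) stats::dlnorm(x, cp[1], cp[2]),
    quant = function(p) stats::qlnorm(p, cp[1], cp[2]),
    rand = function(n) stats::rlnorm(n, cp[1], cp[2]),
    per_unit_or = 2.62)

  sex <- covariate_scheme(
    "sex", frequencies = c(0.48, 0.52), ors = c(1, 1.07),
    generator = function(n) stats::rbinom(n, 1L, 0.52))

  list(age = age, sex = sex, bmi = bmi, creatinine = creatinine)
}

#' Build an age- and sex-specific life table
#'
#' Constructs a life table of disease incidence (per 1000 person-years)
#' and disease-free mortality (per 10,000 person-years) over contiguous
#' age bands, constant across bands at the supplied sex-specific rates.
#' Defaults are the published summary rates for the Korean T2D
#' population aged 40-69: incidence 15.67 (women) and 13.47 (men) per
#' 1000 person-years; disease-free mortality 19.5 (men) and 7.3 (women)
#' per 10,000 people.
#'
#' @param base_ir_female,base_ir_male Incidence per 1000 person-years.
#' @param mort_male,mort_female Disease-free mortality per 10,000
#'   person-years.
#' @param age_bands Increasing break points; bands are
#'   `[age_bands[i], age_bands[i+1])`.
#' @return A data frame of class `"life_table"` with columns `age_lo`,
#'   `age_hi`, `sex`, `incidence_per_1000py`, `mortality_per_10000py`.
#' @export
make_life_tables <- function(base_ir_female = 15.67, base_ir_male = 13.47,
                             mort_male = 19.5, mort_female = 7.3,
                             age_bands = seq(40, 70, by = 5)) {
  check_positive(c(base_ir_female, base_ir_male, mort_male, mort_female),
                 "rates", strict = FALSE)
  if (length(age_bands) < 2L || any(diff(age_bands) <= 0))
    stop_invalid("`age_bands` must be increasing with >= 2 break points")
  k <- length(age_bands) - 1L
  lt <- data.frame(
    age_lo = rep(age_bands[-length(age_bands)], times = 2),
    age_hi = rep(age_bands[-1], times = 2),
    sex = rep(c("female", "male"), each = k),
    incidence_per_1000py = rep(c(base_ir_female, base_ir_male), each = k),
    mortality_per_10000py = rep(c(mort_female, mort_male), each = k))
  class(lt) <- c("life_table", "data.frame")
  lt
}

validate_life_table <- function(lt) {
  need <- c("age_lo", "age_hi", "sex", "incidence_per_1000py",
            "mortality_per_10000py")
  if (!all(need %in% names(lt)))
    stop_invalid("life table lacks columns: %s",
                 paste(setdiff(need, names(lt)), collapse = ", "))
  if (any(lt$incidence_per_1000py < 0) || any(lt$mortality_per_10000py < 0))
    stop_invalid("life-table rates must be non-negative")
  for (s in unique(lt$sex)) {
    b <- lt[lt$sex == s, ]
    b <- b[order(b$age_lo), ]
    if (any(b$age_hi <= b$age_lo))
      stop_invalid("life-table bands must have age_hi > age_lo")
    if (nrow(b) > 1 && any(abs(b$age_lo[-1] - b$age_hi[-nrow(b)]) > 1e-9))
      stop_invalid("life-table bands must be contiguous for sex '%s'", s)
  }
  lt
}
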