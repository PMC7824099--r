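## Shared fixtures built in code.

## A small synthetic weight table with a spread of frequencies/effects.
toy_weights <- function(n = 8, seed = 11) {
  set.seed(seed)
  data.frame(rsid = paste0("rs", seq_len(n)),
             raf = round(runif(n, 0.05, 0.6), 2),
             or = round(exp(runif(n, log(1.05), log(1.6))), 2))
}

## Weight table with alleles, for VCF round-trips.
toy_weights_alleles <- function(n = 5, seed = 7) {
  w <- toy_weights(n, seed)
  set.seed(seed + 1)
  pairs <- t(replicate(n, sample(c("A", "C", "G", "T"), 2)))
  w$risk_allele <- pairs[, 1]
  w$nonrisk_allele <- pairs[, 2]
  w$chrom <- seq_len(n)
  w$pos <- seq_len(n) * 100L
  w
}

## Logistic-model case-control data with known per-unit odds ratios,
## for the association-module power checks.
sim_logistic_cohort <- function(n, betas, intercept, seed) {
  set.seed(seed)
  x <- data.frame(
    age = pmin(pmax(rnorm(n, 57, 9), 40), 69),
    bmi = rlnorm(n, log(25.2) - 0.01, 0.14),
    creatinine = rlnorm(n, log(0.91) - 0.11, 0.47),
    null1 = rnorm(n),
    null2 = rbinom(n, 1, 0.4))
  eta <- intercept + as.matrix(x[, names(betas)]) %*% betas
  y <- rbinom(n, 1, plogis(eta))
  list(design = x, outcome = as.integer(y))
}

## Brute-force Mann-Whitney AUC: all case-control pairs, ties count 1/2.
brute_force_auc <- function(scores, status) {
  ca <- scores[status == 1]
  co <- scores[status == 0]
  cmp <- outer(ca, co, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
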