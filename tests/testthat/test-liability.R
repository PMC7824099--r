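test_that("threshold is the upper-tail normal quantile of prevalence", {
  expect_equal(threshold_from_prevalence(0.5), 0)
  expect_equal(threshold_from_prevalence(0.17), 0.9542, tolerance = 1e-4)
  expect_equal(threshold_from_prevalence(pnorm(-3)), 3, tolerance = 1e-10)
  expect_error(threshold_from_prevalence(0), class = "dcvd_validation_error")
  expect_error(threshold_from_prevalence(1.2), class = "dcvd_validation_error")
})

test_that("null locus has zero shifts and variance", {
  e <- locus_effects(raf = 0.3, or = 1, prevalence = 0.17)
  expect_equal(e$mu, c(0, 0, 0))
  expect_equal(e$variance, 0)
  expect_equal(e$penetrance, rep(0.17, 3))
})

test_that("locus shifts are centered and recover prevalence", {
  for (raf in c(0.05, 0.27, 0.6)) {
    for (or in c(1.1, 1.5, 2.5)) {
      e <- locus_effects(raf, or, 0.17)
      expect_equal(sum(e$freqs * e$mu), 0, tolerance = 1e-12)
      expect_equal(sum(e$freqs * e$penetrance), 0.17, tolerance = 1e-8)
      # relative-risk convention: penetrance ratios are exactly (1, r, r^2)
      expect_equal(e$penetrance / e$penetrance[1], c(1, or, or^2),
                   tolerance = 1e-10)
    }
  }
})

test_that("simulated penetrance ratios match the genotypic relative risks", {
  # Monte-Carlo oracle: draw liabilities with the locus shifts and a
  # residual of variance 1 - v, threshold at qnorm(1 - K), and compare
  # empirical P(D | g = 2) / P(D | g = 0) with the input RR^2 = 2.25
  K <- 0.17
  e <- locus_effects(raf = 0.27, or = 1.5, prevalence = K)
  set.seed(101)
  n <- 1e6
  g <- rbinom(n, 2, 0.27)
  L <- e$mu[g + 1] + rnorm(n, 0, sqrt(1 - e$variance))
  d <- L > threshold_from_prevalence(K)
  emp <- tapply(d, g, mean)
  expect_equal(unname(emp[3] / emp[1]), 2.25, tolerance = 0.02)
  expect_equal(mean(d), K, tolerance = 3 * sqrt(K * (1 - K) / n) / K)
})

test_that("independent loci contribute additive variance", {
  e <- locus_effects(0.3, 1.4, 0.17)
  w <- data.frame(rsid = c("a", "b"), raf = 0.3, or = 1.4)
  m <- liability_model(w, prevalence = 0.17)
  expect_equal(m$genetic_variance, 2 * e$variance, tolerance = 1e-12)
})

test_that("covariate effects mirror locus machinery", {
  s0 <- covariate_scheme("x", c(0.5, 0.5), c(1, 1))
  e0 <- covariate_effects(s0, 0.17)
  expect_equal(e0$mu, c(0, 0))

  s <- covariate_scheme("x", c(0.25, 0.5, 0.25), c(1, 2, 4))
  e <- covariate_effects(s, 0.17)
  expect_true(all(diff(e$penetrance) > 0))
  expect_equal(sum(e$freqs * e$mu), 0, tolerance = 1e-12)
  # MC oracle on the top/bottom category risk ratio
  set.seed(7)
  n <- 5e5
  cc <- sample(0:2, n, replace = TRUE, prob = s$frequencies)
  L <- e$mu[cc + 1] + rnorm(n, 0, sqrt(1 - e$variance))
  d <- L > threshold_from_prevalence(0.17)
  emp <- tapply(d, cc, mean)
  expect_equal(unname(emp[3] / emp[1]), 4, tolerance = 0.03)

  expect_error(covariate_scheme("x", c(0, 0.5, 0.5), c(1, 2, 4)) |>
                 covariate_effects(0.17),
               class = "dcvd_validation_error")
})

test_that("over-strong effects for the prevalence are rejected", {
  # RR so large that the top-category penetrance would exceed 1
  s <- covariate_scheme("x", c(0.98, 0.02), c(1, 50))
  expect_error(covariate_effects(s, 0.4), class = "dcvd_validation_error")
})

test_that("posterior risk is the probit tail and is calibrated", {
  expect_equal(posterior_risk(0, 0, 0.17), 0.17)
  T_ <- threshold_from_prevalence(0.17)
  expect_equal(posterior_risk(T_, 0.3, 0.17), 0.5)
  L <- seq(-2, 2, 0.1)
  expect_true(all(diff(posterior_risk(L, 0.2, 0.17)) > 0))
  expect_error(posterior_risk(0, 1, 0.17), class = "dcvd_validation_error")

  # law of total probability: E[posterior risk] = prevalence
  e <- locus_effects(0.3, 1.6, 0.17)
  set.seed(5)
  g <- rbinom(2e5, 2, 0.3)
  L <- e$mu[g + 1]
  # exact mean-zero centering of the shifts leaves a second-order bias
  # in the integrated risk, well inside the Monte-Carlo band
  expect_lt(abs(mean(posterior_risk(L, e$variance, 0.17)) - 0.17), 2e-3)
})

test_that("posterior risk matches per-bin disease rates in simulation", {
  e <- locus_effects(0.3, 2, 0.17)
  set.seed(31)
  n <- 4e5
  g <- rbinom(n, 2, 0.3)
  L <- e$mu[g + 1]
  d <- (L + rnorm(n, 0, sqrt(1 - e$variance))) >
    threshold_from_prevalence(0.17)
  for (gg in 0:2) {
    i <- g == gg
    rate <- mean(d[i])
    se <- sqrt(rate * (1 - rate) / sum(i))
    expect_lt(abs(posterior_risk(e$mu[gg + 1], e$variance, 0.17) - rate),
              3 * se)
  }
})

test_that("family-history update adds the conditional polygenic shift", {
  expect_equal(family_history_update(0.3, 0.17, 0.5, fh = 0), 0.3)
  expect_equal(family_history_update(0.3, 0.17, 0, fh = 1), 0.3)
  expect_equal(family_history_update(0.3, 0.17, 0.5, fh = NA), 0.3)

  # bivariate-normal oracle: mean liability given an affected
  # first-degree relative, pair correlation 0.5 * h2 = 0.25
  K <- 0.17; h2 <- 0.5
  set.seed(21)
  n <- 1e6
  rel <- rnorm(n)
  self <- 0.25 * rel + sqrt(1 - 0.25^2) * rnorm(n)
  T_ <- threshold_from_prevalence(K)
  oracle <- mean(self[rel > T_])
  delta <- family_history_update(0, K, h2, genetic_variance = 0, fh = 1)
  expect_equal(delta, oracle, tolerance = 0.05)
})

test_that("lifetime risk cumulates incidence against competing mortality", {
  lt0 <- make_life_tables(0, 0, 0, 0)
  expect_equal(as.numeric(lifetime_risk(1, lt0, "female")), 0)

  # constant hazard, zero mortality: closed form 1 - exp(-lambda * T)
  lam <- 12 / 1000   # per person-year
  lt <- make_life_tables(12, 12, 0, 0, age_bands = seq(40, 70, 5))
  r <- lifetime_risk(1, lt, "male")
  expect_equal(as.numeric(r), 1 - exp(-lam * 30), tolerance = 1e-10)

  # higher disease-free mortality lowers lifetime risk
  risks <- vapply(c(0, 50, 200, 800), function(m)
    as.numeric(lifetime_risk(1.5, make_life_tables(12, 12, m, m), "male")),
    0)
  expect_true(all(diff(risks) < 0))

  # hazard above 1/person-year is capped with a warning
  expect_warning(lifetime_risk(200, make_life_tables(12, 12, 5, 5), "male"),
                 "capped")
})

test_that("start_age truncates the life table", {
  lt <- make_life_tables(10, 10, 0, 0, age_bands = seq(40, 70, 5))
  r_all <- as.numeric(lifetime_risk(1, lt, "female"))
  r_55 <- as.numeric(lifetime_risk(1, lt, "female", start_age = 55))
  expect_equal(r_55, 1 - exp(-10 / 1000 * 15), tolerance = 1e-10)
  expect_lt(r_55, r_all)
  expect_error(lifetime_risk(1, lt, "female", start_age = 80),
               class = "dcvd_validation_error")
})
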