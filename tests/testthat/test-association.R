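test_that("published univariate odds ratios are reproduced from counts", {
  t1 <- table1_counts()
  rep_rows <- t1[t1$reproducible, ]
  for (i in seq_len(nrow(rep_rows))) {
    r <- rep_rows[i, ]
    o <- odds_ratio_2x2(r$a, r$b, r$c, r$d)
    expect_equal(round(o$or, 2), r$published_or,
                 info = paste("term:", r$term))
  }
  # ex-drinker confidence interval to the printed precision
  ex <- t1[t1$term == "ex_drinker", ]
  o <- odds_ratio_2x2(ex$a, ex$b, ex$c, ex$d)
  expect_equal(round(o$ci_lo, 2), 1.22)
  expect_equal(round(o$ci_hi, 2), 3.15)
  expect_lt(o$p, 0.01)
})

test_that("odds ratio handles degenerate and symmetric tables", {
  o <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(o$or, 1)
  expect_equal(o$ci_lo * o$ci_hi, 1, tolerance = 1e-12)  # symmetric about 1

  z <- odds_ratio_2x2(0, 5, 10, 20)
  expect_false(z$estimable)
  expect_true(is.na(z$or))

  # swapping exposed and reference inverts the OR and reciprocates the CI
  o1 <- odds_ratio_2x2(26, 75, 184, 1042)
  o2 <- odds_ratio_2x2(75, 26, 1042, 184)
  expect_equal(o2$or, 1 / o1$or, tolerance = 1e-12)
  expect_equal(o2$ci_lo, 1 / o1$ci_hi, tolerance = 1e-12)
  expect_equal(o2$ci_hi, 1 / o1$ci_lo, tolerance = 1e-12)
})

test_that("logistic fit on a saturated 2x2 equals the cross-product OR", {
  tab <- table1_counts()[table1_counts()$term == "ex_drinker", ]
  x <- c(rep(1, tab$a), rep(0, tab$b), rep(1, tab$c), rep(0, tab$d))
  y <- c(rep(1, tab$a + tab$b), rep(0, tab$c + tab$d))
  f <- fit_logistic(data.frame(exposed = x), y)
  o <- odds_ratio_2x2(tab$a, tab$b, tab$c, tab$d)
  expect_equal(unname(exp(f$coefficients[2])), o$or, tolerance = 1e-6)
  expect_true(f$converged)
  expect_equal(f$n_used, length(y))
})

test_that("logistic fit rejects degenerate inputs and drops incomplete rows", {
  expect_error(fit_logistic(data.frame(x = rnorm(20)), rep(0, 20)),
               class = "dcvd_validation_error")
  expect_error(fit_logistic(data.frame(x = rep(1, 20)),
                            rep(c(0, 1), 10)),
               class = "dcvd_validation_error")
  set.seed(2)
  x <- rnorm(100); x[1:5] <- NA
  y <- rbinom(100, 1, 0.4)
  f <- fit_logistic(data.frame(x = x), y)
  expect_equal(f$n_used, 95)
})

test_that("null covariate shows no association", {
  set.seed(33)
  x <- rnorm(1e4)
  y <- rbinom(1e4, 1, 0.2)
  f <- fit_logistic(data.frame(x = x), y)
  expect_gt(f$wald_p_values[2], 0.001)
})

test_that("perfect separation is flagged, not silently reported", {
  x <- c(rnorm(50, -3), rnorm(50, 3))
  y <- rep(0:1, each = 50)
  expect_warning(f <- fit_logistic(data.frame(x = x), y), "separation")
  expect_false(f$converged)
})

test_that("backward elimination keeps significant terms and drops the rest", {
  # fixed point: all terms significant
  set.seed(4)
  n <- 2000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1.5 + 0.8 * x1 + 0.9 * x2))
  b <- backward_eliminate(data.frame(x1 = x1, x2 = x2), y)
  expect_setequal(b$retained, c("x1", "x2"))

  # single null term: intercept-only model
  set.seed(6)
  x <- rnorm(1000)
  y <- rbinom(1000, 1, 0.3)
  b0 <- backward_eliminate(data.frame(x = x), y)
  expect_length(b0$retained, 0)
  expect_null(b0$fit)
})

test_that("backward elimination recovers the true model across replicates", {
  # truth: the published per-unit effects (age 1.07/yr, BMI 1.06,
  # creatinine 2.62/mg/dL) plus two pure-noise covariates, at the
  # case-control study's sample size
  betas <- c(age = log(1.07), bmi = log(1.06), creatinine = log(2.62))
  true_kept <- nulls_dropped <- logical(100)
  for (r in 1:100) {
    d <- sim_logistic_cohort(2378, betas, intercept = -7.5, seed = 1000 + r)
    b <- backward_eliminate(d$design, d$outcome, alpha = 0.05)
    true_kept[r] <- all(names(betas) %in% b$retained)
    nulls_dropped[r] <- !any(c("null1", "null2") %in% b$retained)
  }
  expect_gte(mean(true_kept), 0.90)
  expect_gte(mean(nulls_dropped), 0.85)
})

test_that("elimination path is stable under column permutation", {
  set.seed(8)
  n <- 3000
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + 1 * d$a))
  b1 <- backward_eliminate(d, y)
  b2 <- backward_eliminate(d[, c("c", "a", "b")], y)
  expect_setequal(b1$retained, b2$retained)
})

test_that("univariate OR table matches per-column logistic fits", {
  set.seed(12)
  n <- 1500
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-1 + 0.5 * d$x1))
  tab <- univariate_or_table(d, y)
  expect_equal(tab$term, c("x1", "x2"))
  f <- fit_logistic(d["x1"], y)
  expect_equal(tab$or[1], unname(exp(f$coefficients[2])))
  expect_true(all(tab$ci_lo < tab$or & tab$or < tab$ci_hi))
})
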