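test_that("rank AUC equals brute-force pair counting, ties included", {
  set.seed(51)
  for (r in 1:5) {
    n <- sample(20:200, 1)
    scores <- sample(1:8, n, replace = TRUE)   # heavy ties
    status <- rbinom(n, 1, 0.3)
    if (length(unique(status)) < 2) status[1:2] <- 0:1
    expect_equal(auc_rank(scores, status)$auc,
                 brute_force_auc(scores, status))
  }
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auc_rank(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(auc_rank(1:5, rep(1, 5)), class = "dcvd_validation_error")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(53)
  scores <- rnorm(150)
  status <- rbinom(150, 1, plogis(scores))
  a <- auc_rank(scores, status)$auc
  expect_equal(auc_rank(exp(scores), status)$auc, a)
  expect_equal(auc_rank(3 * scores - 7, status)$auc, a)
})

test_that("observed AUC matches the model-implied binormal value", {
  # enumerable single-locus model: case/control genotype mixtures give
  # the model-implied AUC exactly; the empirical rank AUC must agree
  K <- 0.17
  e <- locus_effects(0.35, 2.2, K)
  q_case <- e$freqs * e$penetrance / sum(e$freqs * e$penetrance)
  q_ctrl <- e$freqs * (1 - e$penetrance) / sum(e$freqs * (1 - e$penetrance))
  implied <- sum(outer(seq_along(q_case), seq_along(q_ctrl), ">") *
                   outer(q_case, q_ctrl)) +
    0.5 * sum(q_case * q_ctrl)

  spec <- simulation_spec(5e4, weights = data.frame(rsid = "x", raf = 0.35,
                                                    or = 2.2),
                          prevalence = K, seed = 57)
  ch <- simulate_cohort(spec)
  a <- auc_rank(ch$dosages[, "x"], ch$samples$status)
  se <- (a$ci_hi - a$ci_lo) / (2 * 1.96)
  expect_lt(abs(a$auc - implied), 3 * se)
})

test_that("per-point OR recovers a known logistic slope", {
  set.seed(59)
  n <- 1e4
  score <- runif(n, 0, 10)
  beta <- 0.35
  status <- rbinom(n, 1, plogis(-3 + beta * score))
  pp <- per_point_or(score, status)
  f <- fit_logistic(data.frame(score = score), status)
  se <- f$standard_errors[2]
  expect_lt(abs(log(pp$or) - beta), 2 * se)

  # halving the scale doubles the log-OR per point
  pp2 <- per_point_or(score / 2, status)
  expect_equal(log(pp2$or), 2 * log(pp$or), tolerance = 1e-6)

  # null score: CI covers 1
  status0 <- rbinom(n, 1, 0.2)
  pp0 <- per_point_or(score, status0)
  expect_gt(pp0$or, pp0$ci_lo)
  expect_true(pp0$ci_lo < 1.1 & pp0$ci_hi > 0.9)
})

test_that("continuous NRI counts reclassification movements", {
  r <- runif(15)
  expect_equal(continuous_nri(r, r, rep(0:1, length.out = 15))$nri_overall, 0)

  # maximal improvement: every case up, every control down
  old <- rep(0.5, 10); status <- rep(c(1, 0), 5)
  new <- ifelse(status == 1, 0.9, 0.1)
  expect_equal(continuous_nri(old, new, status)$nri_overall, 2)

  # enumerated 15-sample example: 5 cases (3 up, 2 down),
  # 10 controls (6 down, 4 up)
  status <- c(rep(1, 5), rep(0, 10))
  old <- rep(0.5, 15)
  new <- c(rep(0.6, 3), rep(0.4, 2), rep(0.4, 6), rep(0.6, 4))
  out <- continuous_nri(old, new, status)
  expect_equal(out$nri_event, 0.2)
  expect_equal(out$nri_nonevent, 0.2)
  expect_equal(out$nri_overall, 0.4)
  expect_true(abs(out$nri_event) <= 1 && abs(out$nri_nonevent) <= 1)

  expect_error(continuous_nri(1:3, 1:4, c(0, 1, 0)),
               class = "dcvd_validation_error")
})

test_that("stratified folds partition samples and preserve class balance", {
  set.seed(61)
  scores <- rnorm(100)
  status <- rep(c(1, 0), c(30, 70))
  cv <- kfold_cv(scores, status, k = 10, seed = 5)
  expect_equal(sort(as.vector(table(cv$assignment))), rep(10L, 10))
  expect_true(all(cv$folds$n_cases == 3))

  cv2 <- kfold_cv(scores, status, k = 10, seed = 5)
  expect_identical(cv$assignment, cv2$assignment)

  expect_error(kfold_cv(scores, rep(c(1, 0), c(5, 95)), k = 10, seed = 1),
               class = "dcvd_validation_error")
})

test_that("cross-validated AUC is consistent with the full-sample AUC", {
  spec <- simulation_spec(2e4, weights = toy_weights(n = 12, seed = 63),
                          seed = 63)
  ch <- simulate_cohort(spec)
  L <- measured_liability(ch$model, dosages = ch$dosages)
  full <- auc_rank(L, ch$samples$status)$auc
  cv <- kfold_cv(L, ch$samples$status, k = 10, seed = 65)
  expect_lt(abs(cv$mean_auc - full), 3 * cv$sd_auc)
})

test_that("per-cohort evaluation skips degenerate strata", {
  set.seed(67)
  n <- 2000
  scores <- rnorm(n)
  status <- rbinom(n, 1, plogis(scores - 1.5))
  cohort <- sample(paste0("cohort", 1:4), n, replace = TRUE)
  pc <- per_cohort_eval(scores, status, cohort)
  expect_equal(nrow(pc$table), 4)
  # same score distribution in every cohort: AUCs agree within noise
  expect_lt(diff(range(pc$table$auc)), 0.15)

  status[cohort == "cohort1"] <- 0
  pc2 <- per_cohort_eval(scores, status, cohort)
  expect_equal(nrow(pc2$table), 3)
  expect_match(pc2$skipped[["cohort1"]], "one class")
})
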