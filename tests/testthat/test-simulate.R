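test_that("genotype simulation is HWE-calibrated and deterministic", {
  expect_error(simulate_genotypes(c(0.5, 1.2), 10, 1),
               class = "dcvd_validation_error")

  g1 <- simulate_genotypes(c(a = 0.3, b = 0.7), 50, seed = 42)
  g2 <- simulate_genotypes(c(a = 0.3, b = 0.7), 50, seed = 42)
  expect_identical(g1, g2)
  expect_true(all(g1 %in% 0:2))

  n <- 1e5
  g <- simulate_genotypes(c(0.5, 0.05), n, seed = 9)
  expect_lt(abs(mean(g[, 1]) / 2 - 0.5), 3 * sqrt(0.25 / (2 * n)))
  # homozygote fraction ~ p^2 under HWE
  expect_lt(abs(mean(g[, 2] == 2) - 0.05^2),
            3 * sqrt(0.0025 * (1 - 0.0025) / n))
})

test_that("simulated prevalence converges to K", {
  w <- data.frame(rsid = paste0("n", 1:5), raf = 0.3, or = 1)
  spec <- simulation_spec(2e5, weights = w, prevalence = 0.17,
                          heritability = 0, seed = 3)
  ch <- simulate_cohort(spec)
  se <- sqrt(0.17 * 0.83 / 2e5)
  expect_lt(abs(mean(ch$samples$status) - 0.17), 3 * se)
})

test_that("cohorts are byte-identical under a fixed seed", {
  spec <- simulation_spec(500, weights = toy_weights(),
                          schemes = default_covariate_schemes(), seed = 77)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$dosages, c2$dosages)
})

test_that("null model leaves status independent of genotypes", {
  w <- data.frame(rsid = paste0("n", 1:40), raf = 0.4, or = 1)
  spec <- simulation_spec(2e4, weights = w, prevalence = 0.17,
                          heritability = 0, seed = 13)
  ch <- simulate_cohort(spec)
  p <- vapply(seq_len(ncol(ch$dosages)), function(j)
    suppressWarnings(
      chisq.test(table(ch$dosages[, j], ch$samples$status))$p.value), 0)
  # at alpha = 0.01, >= 95% of null loci should be non-significant
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("risk loci are enriched in cases", {
  spec <- simulation_spec(2e5, weights = dcvd_snp_panel(),
                          prevalence = 0.17, heritability = 0.5, seed = 19)
  ch <- simulate_cohort(spec)
  case <- ch$samples$status == 1
  raf_case <- colMeans(ch$dosages[case, ]) / 2
  raf_ctrl <- colMeans(ch$dosages[!case, ]) / 2
  pos <- sum(raf_case > raf_ctrl)
  # sign test over the 47 loci (all have OR > 1)
  expect_lt(binom.test(pos, 47, alternative = "greater")$p.value, 1e-6)
})

test_that("family history is enriched in cases when h2 > 0", {
  spec <- simulation_spec(4e4, weights = toy_weights(),
                          prevalence = 0.17, heritability = 0.5, seed = 23)
  ch <- simulate_cohort(spec)
  fh_case <- mean(ch$samples$fh[ch$samples$status == 1])
  fh_ctrl <- mean(ch$samples$fh[ch$samples$status == 0])
  expect_gt(fh_case, fh_ctrl)
})

test_that("measured liability has mean ~0 and variance ~V in the cohort", {
  spec <- simulation_spec(5e4, weights = toy_weights(),
                          schemes = default_covariate_schemes(), seed = 29)
  ch <- simulate_cohort(spec)
  L <- measured_liability(ch$model, dosages = ch$dosages,
                          categories = ch$samples[, ch$scheme_names])
  V <- ch$model$variance_explained
  expect_lt(abs(mean(L)), 3 * sqrt(V / 5e4))
  expect_equal(var(L), V, tolerance = 0.05)
})

test_that("life-table fixtures carry the supplied rates and round-trip", {
  lt <- make_life_tables()
  expect_equal(unique(lt$incidence_per_1000py[lt$sex == "female"]), 15.67)
  expect_equal(unique(lt$incidence_per_1000py[lt$sex == "male"]), 13.47)
  expect_equal(unique(lt$mortality_per_10000py[lt$sex == "male"]), 19.5)
  expect_equal(unique(lt$mortality_per_10000py[lt$sex == "female"]), 7.3)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path)
  expect_equal(as.data.frame(lt2), as.data.frame(lt))

  expect_error(make_life_tables(-1, 1, 1, 1),
               class = "dcvd_validation_error")
})

test_that("cohort age range and covariate coding follow the study design", {
  spec <- simulation_spec(2000, schemes = default_covariate_schemes(),
                          seed = 41)
  ch <- simulate_cohort(spec)
  expect_true(all(ch$samples$age_raw >= 40 & ch$samples$age_raw <= 69))
  expect_true(all(ch$samples$age %in% 0:2))
  expect_true(all(ch$samples$sex %in% 0:1))
  expect_setequal(unique(ch$samples$cohort),
                  paste0("cohort", 1:4))
})
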