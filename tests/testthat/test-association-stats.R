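# Two-sample tests, correlations, multivariate fits, subgroup battery,
# repeatability CV, and noise robustness.

make_cohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  sex <- rep(c("M", "F"), length.out = n)
  age <- runif(n, 20, 75)
  bmi <- runif(n, 20, 40)
  manifest <- data.frame(subject_id = sprintf("s%03d", 1:n), sex = sex,
                         age = age, bmi = bmi)
  cohort_measurements(manifest,
                      sft = 6 + rnorm(n), bma = 34 + 5 * rnorm(n),
                      mfi_mean = 140 + 10 * rnorm(n),
                      mfi_mode = 110 + 8 * rnorm(n))
}

test_that("pooled two-sample t-test matches the closed form and its symmetries", {
  x <- c(1, 2, 3)
  same <- two_sample_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  y <- x + 10 + c(-0.1, 0, 0.1)
  res <- two_sample_test(x, y)
  # closed-form pooled t with 4 degrees of freedom
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$t, t_manual)
  expect_equal(res$df, 4)
  expect_lt(res$p, 0.01)

  flipped <- two_sample_test(y, x)
  expect_equal(flipped$t, -res$t)
  expect_equal(flipped$p, res$p)

  expect_error(two_sample_test(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("correlation test handles exact linear relations and rejects constants", {
  x <- 1:10
  expect_equal(correlation_test(x, 2 * x + 1)$r, 1)
  expect_equal(correlation_test(x, -x)$r, -1)
  expect_error(correlation_test(x, rep(2, 10)), "constant")
})

test_that("correlation test type-I error is calibrated at alpha = 0.05", {
  set.seed(31)
  rejections <- mean(replicate(2000, {
    correlation_test(rnorm(20), rnorm(20))$p < 0.05
  }))
  expect_gte(rejections, 0.035)
  expect_lte(rejections, 0.065)
})

test_that("multivariate fit recovers exact and planted relationships", {
  set.seed(32)
  age <- runif(100, 20, 70)
  bmi <- runif(100, 20, 40)
  y <- 2 + 0.3 * age - 0.5 * bmi
  # lm warns that the noiseless fit is "essentially perfect"; that is the point
  fit <- suppressWarnings(multivariate_fit(y, age, bmi))
  expect_lt(max(abs(fit$coef - c(2, 0.3, -0.5))), 1e-8)
  expect_lt(fit$p, 1e-12)

  age2 <- runif(200, 20, 70)
  bmi2 <- runif(200, 20, 40)
  y2 <- 5 - 0.05 * age2 + rnorm(200, 0, 0.5)
  fit2 <- multivariate_fit(y2, age2, bmi2)
  expect_lt(abs(fit2$coef[["age"]] + 0.05), 3 * fit2$se[["age"]])

  expect_error(multivariate_fit(y[1:10], age[1:10], 2 * age[1:10]), "rank")
})

test_that("F-test type-I error is calibrated at alpha = 0.05", {
  set.seed(33)
  age <- runif(100, 20, 70)
  bmi <- runif(100, 20, 40)
  rejections <- mean(replicate(2000, {
    multivariate_fit(rnorm(100), age, bmi)$p < 0.05
  }))
  expect_gte(rejections, 0.035)
  expect_lte(rejections, 0.065)
})

test_that("the subgroup battery enumerates the full crossing", {
  cohort <- make_cohort(80)
  rep <- subgroup_battery(cohort)
  # 9 strata x (4 outcomes x (2 univariate + 1 multivariate) + 4 cross rows)
  expect_equal(nrow(rep), 9 * 16)
  expect_named(rep, c("outcome", "predictor", "stratum", "n", "stat", "p", "note"))
  expect_true(all(rep$p >= 0 & rep$p <= 1, na.rm = TRUE))
  # stratum sizes add up
  n_all <- rep$n[rep$stratum == "all"][1]
  expect_equal(rep$n[rep$stratum == "male"][1] + rep$n[rep$stratum == "female"][1], n_all)
  expect_equal(rep$n[rep$stratum == "obese"][1] + rep$n[rep$stratum == "nonobese"][1], n_all)
})

test_that("tiny strata yield NA rows with a reason instead of errors", {
  cohort <- make_cohort(12)
  cohort$bmi[cohort$sex == "F"] <- 25 # no obese females
  cohort$obese <- cohort$bmi >= 30
  rep <- subgroup_battery(cohort)
  fo <- rep[rep$stratum == "female_obese", ]
  expect_true(all(is.na(fo$p)))
  expect_true(all(fo$note != ""))
})

test_that("a planted female-only SFT~BMI slope shows up in the female stratum", {
  cfg <- cohort_config(
    slopes = list(sft_age = c(M = 0, F = 0), sft_bmi = c(M = 0, F = 0.4),
                  bma_age = c(M = 0, F = 0), bma_bmi = c(M = 0, F = 0),
                  mfi_age = c(M = 0, F = 0), mfi_bmi = c(M = 0, F = 0)),
    seed = 41L)
  m <- generate_truths(cfg)
  cohort <- cohort_measurements(m, sft = m$true_sft, bma = m$true_bma,
                                mfi_mean = 140 + m$true_fat_fraction * 100,
                                mfi_mode = 110 + m$true_fat_fraction * 80)
  rep <- subgroup_battery(cohort)
  pick <- function(stratum) rep[rep$outcome == "sft" & rep$predictor == "bmi" &
                                  rep$stratum == stratum, ]
  expect_lt(pick("female")$p, 0.001)
  expect_lt(abs(pick("male")$stat), abs(pick("female")$stat))
})

test_that("planted sex-specific MFI slopes propagate to the truth fat fractions", {
  cfg <- cohort_config(
    n_male = 150L, n_female = 150L,
    slopes = list(sft_age = c(M = 0, F = 0), sft_bmi = c(M = 0, F = 0),
                  bma_age = c(M = 0, F = 0), bma_bmi = c(M = 0, F = 0),
                  mfi_age = c(M = 0, F = 0.004), mfi_bmi = c(M = 0, F = 0)),
    seed = 42L)
  m <- generate_truths(cfg)
  fem <- m[m$sex == "F", ]
  mal <- m[m$sex == "M", ]
  expect_lt(correlation_test(fem$age, fem$true_fat_fraction)$p, 0.01)
  r_m <- correlation_test(mal$age, mal$true_fat_fraction)$r
  r_f <- correlation_test(fem$age, fem$true_fat_fraction)$r
  expect_lt(abs(r_m), abs(r_f))
})

test_that("repeatability CV matches hand computations and is scale-free", {
  expect_equal(reproducibility_cv(c(10, 10, 10)), 0)
  expect_equal(reproducibility_cv(c(9, 10, 11)), 10) # sample sd 1.0, mean 10
  expect_equal(reproducibility_cv(5 * c(9, 10, 11)),
               reproducibility_cv(c(9, 10, 11)))
  expect_error(reproducibility_cv(c(-1, 1)), "zero mean")
  expect_error(reproducibility_cv(7), "length")
})

test_that("noise robustness: cv = 0 reproduces the noiseless battery exactly", {
  cohort <- make_cohort(40)
  out <- noise_robustness(cohort, cv = c(sft = 0, bma = 0, mfi_mean = 0,
                                         mfi_mode = 0), n_exec = 3, seed = 2L)
  expect_equal(out$p_noise_avg, out$p)
  expect_true(!any(out$sig_changed, na.rm = TRUE))
})

test_that("noise robustness is seeded and leaves strong associations significant", {
  cfg <- cohort_config(seed = 43L)
  m <- generate_truths(cfg)
  cohort <- cohort_measurements(m, sft = m$true_sft, bma = m$true_bma,
                                mfi_mean = 140 + m$true_fat_fraction * 100,
                                mfi_mode = 110 + m$true_fat_fraction * 80)
  out1 <- noise_robustness(cohort, n_exec = 10, seed = 9L)
  out2 <- noise_robustness(cohort, n_exec = 10, seed = 9L)
  expect_equal(out1$p_noise_avg, out2$p_noise_avg)
  # the planted female SFT~BMI association survives 3%-level noise
  row <- out1[out1$outcome == "sft" & out1$predictor == "bmi" &
                out1$stratum == "female", ]
  expect_lt(row$p, 0.05)
  expect_false(row$sig_changed)
})
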