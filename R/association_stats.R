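# Statistical battery: two-sample comparisons, univariate and multivariate
# correlation, sex/obesity subgrouping, repeatability CV, and the
# segmentation-noise robustness procedure.

OBESE_BMI_CUTOFF <- 30.0

#' Assemble per-subject cohort measurements
#'
#' @param manifest data.frame with `subject_id`, `sex`, `age`, `bmi`.
#' @param sft,bma,mfi_mean,mfi_mode numeric vectors aligned with the manifest.
#' @return A `data.frame` (class `cohort_measurements`) with the analyzed
#'   columns plus the derived `obese` flag (BMI >= 30).
#' @export
cohort_measurements <- function(manifest, sft, bma, mfi_mean, mfi_mode) {
  df <- data.frame(subject_id = manifest$subject_id, sex = manifest$sex,
                   age = manifest$age, bmi = manifest$bmi,
                   sft = sft, bma = bma,
                   mfi_mean = mfi_mean, mfi_mode = mfi_mode)
  stopifnot(!anyNA(df))
  df$obese <- df$bmi >= OBESE_BMI_CUTOFF
  class(df) <- c("cohort_measurements", "data.frame")
  df
}

#' Pooled-variance two-sample t-test
#'
#' @param x1,x2 numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p`, `mean1`, `mean2`, `sd1`, `sd2`,
#'   `n1`, `n2`.
#' @export
two_sample_test <- function(x1, x2) {
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  if (stats::sd(c(x1 - mean(x1), x2 - mean(x2))) == 0) {
    stop("zero pooled variance")
  }
  ht <- stats::t.test(x1, x2, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean1 = mean(x1), mean2 = mean(x2),
       sd1 = stats::sd(x1), sd2 = stats::sd(x2),
       n1 = length(x1), n2 = length(x2))
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors of length >= 3 with non-zero spread.
#' @return List with `r`, `p`, `n`.
#' @export
correlation_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Multivariate (age + BMI) ordinary least squares fit
#'
#' @param y outcome.
#' @param age,bmi covariates.
#' @return List with `coef` (named: intercept, age, bmi), `se`, `coef_p`,
#'   `p` (overall F-test of the joint null), `n`, `r_squared`.
#' @export
multivariate_fit <- function(y, age, bmi) {
  stopifnot(length(y) >= 4)
  df <- data.frame(y = y, age = age, bmi = bmi)
  X <- stats::model.matrix(~ age + bmi, df)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- stats::lm(y ~ age + bmi, data = df)
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(coef = stats::coef(fit), se = sm$coefficients[, "Std. Error"],
       coef_p = sm$coefficients[, "Pr(>|t|)"],
       p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       n = length(y), r_squared = sm$r.squared)
}

battery_strata <- function(cohort) {
  list(all = rep(TRUE, nrow(cohort)),
       male = cohort$sex == "M",
       female = cohort$sex == "F",
       obese = cohort$obese,
       nonobese = !cohort$obese,
       male_obese = cohort$sex == "M" & cohort$obese,
       male_nonobese = cohort$sex == "M" & !cohort$obese,
       female_obese = cohort$sex == "F" & cohort$obese,
       female_nonobese = cohort$sex == "F" & !cohort$obese)
}

#' Full association battery over sex and obesity strata
#'
#' For every stratum (entire group, by sex, by obesity, sex x obesity)
#' computes: univariate Pearson correlations of each outcome (SFT, BMA, MFI
#' mean, MFI mode) with age and BMI; MFI-vs-BMA and MFI-vs-SFT correlations;
#' and the multivariate age+BMI fit per outcome (overall F-test p). Strata
#' too small for a test yield an `NA` row with the reason recorded. No
#' multiple-testing correction is applied; every p is reported raw.
#'
#' @param cohort a [cohort_measurements()] data.frame.
#' @return A `data.frame` with columns `outcome`, `predictor`, `stratum`,
#'   `n`, `stat`, `p`, `note`.
#' @export
subgroup_battery <- function(cohort) {
  strata <- battery_strata(cohort)
  outcomes <- c("sft", "bma", "mfi_mean", "mfi_mode")
  uni_predictors <- c("age", "bmi")
  cross_pairs <- list(c("mfi_mean", "bma"), c("mfi_mode", "bma"),
                      c("mfi_mean", "sft"), c("mfi_mode", "sft"))
  rows <- list()
  add <- function(outcome, predictor, stratum, n, stat, p, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      outcome = outcome, predictor = predictor, stratum = stratum,
      n = n, stat = stat, p = p, note = note)
  }
  for (sname in names(strata)) {
    idx <- strata[[sname]]
    sub <- cohort[idx, , drop = FALSE]
    n <- nrow(sub)
    for (oc in outcomes) {
      for (pr in uni_predictors) {
        if (n < 3) {
          add(oc, pr, sname, n, NA_real_, NA_real_, "stratum too small")
        } else {
          ct <- tryCatch(correlation_test(sub[[pr]], sub[[oc]]),
                         error = function(e) NULL)
          if (is.null(ct)) add(oc, pr, sname, n, NA_real_, NA_real_, "degenerate stratum")
          else add(oc, pr, sname, n, ct$r, ct$p)
        }
      }
      if (n < 4) {
        add(oc, "age+bmi", sname, n, NA_real_, NA_real_, "stratum too small")
      } else {
        mv <- tryCatch(multivariate_fit(sub[[oc]], sub$age, sub$bmi),
                       error = function(e) NULL)
        if (is.null(mv)) add(oc, "age+bmi", sname, n, NA_real_, NA_real_, "degenerate stratum")
        else add(oc, "age+bmi", sname, n, mv$r_squared, mv$p)
      }
    }
    for (pair in cross_pairs) {
      if (n < 3) {
        add(pair[1], pair[2], sname, n, NA_real_, NA_real_, "stratum too small")
      } else {
        ct <- tryCatch(correlation_test(sub[[pair[2]]], sub[[pair[1]]]),
                       error = function(e) NULL)
        if (is.null(ct)) add(pair[1], pair[2], sname, n, NA_real_, NA_real_, "degenerate stratum")
        else add(pair[1], pair[2], sname, n, ct$r, ct$p)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeatability coefficient of variation
#'
#' Sample standard deviation divided by the mean, in percent.
#'
#' @param x repeated measurements of one quantity (length >= 2).
#' @return CV in percent.
#' @export
reproducibility_cv <- function(x) {
  stopifnot(length(x) >= 2)
  if (mean(x) == 0) stop("zero mean: CV undefined")
  100 * stats::sd(x) / mean(x)
}

#' Segmentation-noise robustness of the association battery
#'
#' Perturbs each measurement column with zero-mean Gaussian noise whose
#' standard deviation is `cv x value` (the measured repeatability of that
#' quantity), recomputes the full battery, repeats `n_exec` times, and
#' averages the p values across executions. Rows are flagged where the
#' significance call (p < 0.05) differs between the noiseless battery and
#' the noise-averaged one.
#'
#' @param cohort a [cohort_measurements()] data.frame.
#' @param cv named fractional CVs for `sft`, `bma`, `mfi_mean`, `mfi_mode`
#'   (e.g. `c(sft = 0.030, bma = 0.034, mfi_mean = 0.032, mfi_mode = 0.041)`).
#' @param n_exec number of noise executions.
#' @param seed integer seed.
#' @param alpha significance level for the change flags.
#' @return The noiseless battery data.frame with added columns `p_noise_avg`
#'   and `sig_changed`.
#' @export
noise_robustness <- function(cohort,
                             cv = c(sft = 0.030, bma = 0.034,
                                    mfi_mean = 0.032, mfi_mode = 0.041),
                             n_exec = 10L, seed = 1L, alpha = 0.05) {
  stopifnot(all(cv >= 0), all(c("sft", "bma", "mfi_mean", "mfi_mode") %in% names(cv)))
  base <- subgroup_battery(cohort)
  acc <- matrix(0, nrow(base), n_exec)
  for (e in seq_len(n_exec)) {
    pert <- cohort
    with_seed(derive_seed(seed, "noise-exec", e), {
      for (col in c("sft", "bma", "mfi_mean", "mfi_mode")) {
        v <- pert[[col]]
        pert[[col]] <- v + stats::rnorm(length(v), 0, cv[[col]] * abs(v))
      }
    })
    acc[, e] <- subgroup_battery(pert)$p
  }
  base$p_noise_avg <- rowMeans(acc)
  base$sig_changed <- !is.na(base$p) &
    ((base$p < alpha) != (base$p_noise_avg < alpha))
  base
}
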