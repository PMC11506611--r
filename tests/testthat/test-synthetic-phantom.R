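# Phantom generator: geometry, intensity model, determinism, cohort sampling.

test_that("degenerate slice (no fat, no bias, no noise) reproduces the intensity model exactly", {
  spec <- small_spec(fat_fraction = 0, bias_amplitude = 0, noise_sigma = 0)
  sl <- rasterize_slice(spec, 1)
  im <- spec$intensity_model
  expect_true(all(sl$image[sl$masks$muscle] == im[["muscle"]]))
  expect_true(all(sl$image[sl$masks$subcutaneous] == im[["fat"]]))
  expect_true(all(sl$image[sl$masks$marrow] == im[["fat"]]))
  expect_true(all(sl$image[!sl$masks$leg] == im[["background"]]))
  cortex <- sl$masks$leg & !sl$masks$subcutaneous & !sl$masks$marrow &
    !sl$masks$muscle
  # the interior non-muscle, non-marrow tissue is the cortical ring
  cortex_in <- cortex & !sl$masks$subcutaneous
  expect_true(all(sl$image[cortex_in] == im[["cortical"]]))
})

test_that("region masks are mutually disjoint and contained in the leg", {
  spec <- small_spec(fat_fraction = 0.3)
  for (s in c(1L, 5L)) {
    sl <- rasterize_slice(spec, s)
    m <- sl$masks
    overlap <- (m$subcutaneous + m$marrow + m$muscle)
    expect_lte(max(overlap), 1)
    expect_true(all(m$leg[m$subcutaneous | m$marrow | m$muscle]))
    expect_true(all(is.finite(sl$image)) && all(sl$image >= 0))
  }
})

test_that("planted marrow disk area is rasterized within 3%", {
  spec <- small_spec(marrow_area = 78.5)
  sl <- rasterize_slice(spec, 1)
  counted <- sum(sl$masks$marrow) * spec$pixel_size^2
  expect_lt(abs(counted - 78.5) / 78.5, 0.03)
})

test_that("same spec and seed give bit-identical slices; different ids differ", {
  spec <- small_spec(fat_fraction = 0.2)
  a <- rasterize_slice(spec, 3, seed = 99L)
  b <- rasterize_slice(spec, 3, seed = 99L)
  expect_identical(a, b)

  t1 <- small_truth(id = "A", seed = 5L)
  t2 <- small_truth(id = "B", seed = 5L)
  s1 <- generate_subject(t1, small_spec())
  s2 <- generate_subject(t2, small_spec())
  expect_false(identical(s1$image, s2$image))
})

test_that("subject stacks carry nine slices with the planted annulus thickness throughout", {
  truth <- small_truth(sft = 5)
  st <- generate_subject(truth, small_spec())
  expect_equal(dim(st$image)[3], 9)
  sf_masks <- lapply(2:8, function(s) st$masks$subcutaneous[, , s])
  res <- compute_sft(sf_masks, st$pixel_size)
  # every slice carries the planted 5 mm annulus despite radius variation
  expect_true(all(abs(res$sft_slice - 5) / 5 < 0.03))
})

test_that("fibula outside the compartment is rejected with a diagnostic", {
  expect_error(rasterize_slice(small_spec(fibula_center = c(0, 27)), 1),
               "geometry overflow")
})

test_that("exact fat-pixel count is planted when marbling is purely clumped", {
  spec <- small_spec(fat_fraction = 0.2, diffuse_fraction = 0,
                     partial_volume_mm = 0, bias_amplitude = 0, noise_sigma = 0)
  sl <- rasterize_slice(spec, 1)
  im <- spec$intensity_model
  nmus <- sum(sl$masks$muscle)
  k <- sum(sl$image[sl$masks$muscle] == im[["fat"]])
  expect_equal(k, round(0.2 * nmus))
  expect_equal(sum(attr(sl, "fat_patches")), round(0.2 * nmus))
})

test_that("cohort manifest matches the configured composition", {
  cfg <- cohort_config(seed = 7L)
  manifest <- generate_truths(cfg)
  expect_equal(nrow(manifest), 107)
  expect_equal(sum(manifest$sex == "M"), 64)
  expect_equal(sum(manifest$sex == "F"), 43)
  # largest-remainder quota at the default proportions
  expect_equal(unname(table(manifest$severity_class)[c("normal", "mild", "moderate", "severe")]),
               c(45L, 45L, 15L, 2L), ignore_attr = TRUE)
  expect_true(all(manifest$true_sft > 0) && all(manifest$true_bma > 0))
  # fixed seed => bit-identical cohort
  expect_identical(manifest, generate_truths(cfg))
})

test_that("zero slopes and zero spread collapse each sex to identical truths", {
  cfg <- cohort_config(
    n_male = 4L, n_female = 4L,
    age = list(M = c(mean = 60, sd = 0), F = c(mean = 50, sd = 0)),
    bmi = list(M = c(mean = 28, sd = 0), F = c(mean = 30, sd = 0)),
    sft = list(M = c(mean = 4.3, sd = 0, min = 1), F = c(mean = 8.9, sd = 0, min = 1)),
    bma = list(M = c(mean = 35.7, sd = 0, min = 4), F = c(mean = 32.6, sd = 0, min = 4)),
    slopes = list(sft_age = c(M = 0, F = 0), sft_bmi = c(M = 0, F = 0),
                  bma_age = c(M = 0, F = 0), bma_bmi = c(M = 0, F = 0),
                  mfi_age = c(M = 0, F = 0), mfi_bmi = c(M = 0, F = 0)),
    seed = 3L)
  m <- generate_truths(cfg)
  for (sx in c("M", "F")) {
    sub <- m[m$sex == sx, c("age", "bmi", "true_sft", "true_bma")]
    expect_true(all(vapply(sub, function(v) length(unique(v)) == 1, logical(1))))
  }
})

test_that("planted regression slopes are recovered from the manifest truth columns", {
  cfg <- cohort_config(
    n_male = 0L, n_female = 200L,
    sft = list(M = c(mean = 4.3, sd = 2.2, min = 1),
               F = c(mean = 8.9, sd = 2.5, min = 0.5)),
    slopes = list(sft_age = c(M = 0, F = 0), sft_bmi = c(M = 0, F = 0.4),
                  bma_age = c(M = 0, F = 0), bma_bmi = c(M = 0, F = 0),
                  mfi_age = c(M = 0, F = 0), mfi_bmi = c(M = 0, F = 0)),
    sampling = "random", seed = 21L)
  m <- generate_truths(cfg)
  fit <- summary(lm(true_sft ~ bmi, data = m))
  est <- fit$coefficients["bmi", ]
  expect_lt(abs(est[["Estimate"]] - 0.4), 3 * est[["Std. Error"]])
})

test_that("subject stacks round-trip through NIfTI volumes", {
  st <- generate_subject(small_truth(), small_spec())
  td <- withr::local_tempdir()
  write_subject_nifti(st, td)
  back <- read_subject_nifti(td, st$truth$subject_id)
  expect_equal(back$pixel_size, st$pixel_size, tolerance = 1e-6)
  expect_equal(back$image, unname(st$image), tolerance = 1e-5)
  for (nm in c("subcutaneous", "marrow", "muscle", "leg")) {
    expect_identical(unname(back$masks[[nm]]), unname(st$masks[[nm]]),
                     info = nm)
  }
})
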