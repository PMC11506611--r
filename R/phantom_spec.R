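# Phantom specification objects: per-slice geometry/intensity parameters,
# per-subject ground truth, and cohort-level sampling configuration.

#' Phantom slice specification
#'
#' Describes the geometry, tissue intensities, and degradation model of a
#' synthetic axial calf slice. The leg is an elliptical muscle compartment
#' wrapped in a subcutaneous fat annulus of constant normal thickness; the
#' fibula is a cortical ring enclosing a marrow disk. A chosen fraction of
#' muscle pixels carries fat intensity in spatially clumped marbling patches.
#'
#' Intensities are arbitrary units chosen to preserve T2-weighted contrast
#' (fat roughly 4x brighter than lean muscle); any ordering with fat > muscle
#' drives the downstream histogram analysis the same way.
#'
#' @param image_size pixels per axis (square slice).
#' @param pixel_size in-plane pixel size, mm.
#' @param n_slices number of axial slices in a stack.
#' @param slice_thickness,slice_gap slice geometry, mm (metadata only).
#' @param leg_radius semi-major radius of the muscle compartment, mm.
#' @param leg_aspect ratio of the minor to major semi-axis of the compartment.
#' @param sf_thickness subcutaneous fat annulus thickness (normal offset), mm.
#' @param fibula_center (row, col) offset of the fibula center from the leg
#'   center, mm; row increases inferiorly (downward in the image).
#' @param marrow_area fibula marrow cross-sectional area, mm^2.
#' @param cortical_rim cortical bone ring thickness, mm.
#' @param fat_fraction planted muscle fat content, 0-1 (fraction of the
#'   muscle's intensity mass shifted from lean to fat).
#' @param diffuse_fraction share of `fat_fraction` spread homogeneously over
#'   all muscle pixels (sub-voxel infiltration, which shifts the lean peak);
#'   the remainder forms clumped marbling patches at full fat intensity.
#' @param clump_scale marbling correlation length, mm.
#' @param partial_volume_mm PSF standard deviation applied to the marbling
#'   indicator (emulates finite resolution mixing fat into neighboring muscle
#'   pixels); 0 disables.
#' @param intensity_model named mean intensities (a.u.) for `background`,
#'   `cortical`, `muscle`, `fat` (fat covers subcutaneous tissue, marrow and
#'   marbling).
#' @param bias_amplitude fractional amplitude of the smooth multiplicative
#'   bias field (0 disables).
#' @param noise_sigma additive noise standard deviation, a.u.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param seed integer seed for the subject's random stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L,
                         pixel_size = 0.7,
                         n_slices = 9L,
                         slice_thickness = 4,
                         slice_gap = 2,
                         leg_radius = 45,
                         leg_aspect = 0.92,
                         sf_thickness = 6,
                         fibula_center = c(-12, 18),
                         marrow_area = 34,
                         cortical_rim = 2,
                         fat_fraction = 0.05,
                         diffuse_fraction = 0.3,
                         clump_scale = 2.5,
                         partial_volume_mm = 0.7,
                         intensity_model = c(background = 5, cortical = 20,
                                             muscle = 100, fat = 400),
                         bias_amplitude = 0.2,
                         noise_sigma = 8,
                         noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(
    image_size = as.integer(image_size), pixel_size = pixel_size,
    n_slices = as.integer(n_slices),
    slice_thickness = slice_thickness, slice_gap = slice_gap,
    leg_radius = leg_radius, leg_aspect = leg_aspect,
    sf_thickness = sf_thickness, fibula_center = fibula_center,
    marrow_area = marrow_area, cortical_rim = cortical_rim,
    fat_fraction = fat_fraction, diffuse_fraction = diffuse_fraction,
    clump_scale = clump_scale,
    partial_volume_mm = partial_volume_mm,
    intensity_model = intensity_model,
    bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
    noise_model = noise_model, seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(
    spec$image_size >= 32, spec$pixel_size > 0, spec$n_slices >= 1,
    spec$leg_radius > 0, spec$leg_aspect > 0, spec$leg_aspect <= 1,
    spec$sf_thickness > 0,
    spec$fat_fraction >= 0, spec$fat_fraction < 1,
    spec$diffuse_fraction >= 0, spec$diffuse_fraction <= 1,
    spec$marrow_area > 0,
    spec$marrow_area < pi * spec$leg_radius^2,
    spec$cortical_rim >= 0,
    all(spec$intensity_model > 0),
    all(c("background", "cortical", "muscle", "fat") %in%
          names(spec$intensity_model)),
    spec$bias_amplitude >= 0, spec$bias_amplitude < 1,
    spec$noise_sigma >= 0
  )
  # the whole leg (annulus included) must fit inside the field of view
  fov_half <- spec$image_size * spec$pixel_size / 2
  if (spec$leg_radius + spec$sf_thickness >= fov_half - 2 * spec$pixel_size) {
    stop("leg plus subcutaneous annulus does not fit in the field of view")
  }
  invisible(spec)
}

#' Per-subject ground truth
#'
#' @param subject_id character id.
#' @param sex `"M"` or `"F"`.
#' @param age years.
#' @param bmi kg/m^2.
#' @param true_sft planted subcutaneous fat thickness, mm.
#' @param true_bma planted fibula marrow area, mm^2.
#' @param true_fat_fraction planted muscle fat fraction, 0-1.
#' @param severity_class one of `"normal"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param seed integer subject seed.
#' @return An object of class `subject_truth`.
#' @export
subject_truth <- function(subject_id, sex, age, bmi, true_sft, true_bma,
                          true_fat_fraction, severity_class, seed = 1L) {
  sex <- match.arg(sex, c("M", "F"))
  severity_class <- match.arg(severity_class, severity_levels(4L))
  stopifnot(age >= 11, age <= 79, bmi >= 19.0, bmi <= 44.3,
            true_sft > 0, true_bma > 0,
            true_fat_fraction >= 0, true_fat_fraction < 1)
  structure(list(subject_id = as.character(subject_id), sex = sex, age = age,
                 bmi = bmi, true_sft = true_sft, true_bma = true_bma,
                 true_fat_fraction = true_fat_fraction,
                 severity_class = severity_class, seed = as.integer(seed)),
            class = "subject_truth")
}

#' Ordered severity level names
#'
#' @param c number of severity levels (3, 4, or 5).
#' @return Character vector from least to most severe.
#' @export
severity_levels <- function(c = 4L) {
  lv <- c("normal", "mild", "moderate", "severe", "very_severe")
  stopifnot(c >= 2, c <= 5)
  lv[seq_len(c)]
}

#' Cohort sampling configuration
#'
#' Defaults reproduce the demographic and morphometric structure of the
#' study cohort being emulated: 64 males and 43 females; male age
#' 57.9 +/- 17.8 y (11-79), female 52.7 +/- 14.6 y (15-78); male BMI
#' 28.4 +/- 4.4 (19.0-38.5), female 30.3 +/- 5.7 (19.7-44.3); subcutaneous
#' fat thickness 4.3 +/- 2.2 mm in males and 8.9 +/- 3.7 mm in females
#' (truncated at 1 mm); marrow area 35.7 +/- 21.1 mm^2 in males and
#' 32.6 +/- 20.0 mm^2 in females (truncated at 4 mm^2); a 4-level fat
#' infiltration severity mixture at proportions 0.42/0.42/0.14/0.02 with
#' per-class muscle fat fractions 0.05/0.15/0.30/0.60.
#'
#' Planted association slopes follow the directions reported for the cohort:
#' SFT falls with age in males and rises with BMI in females; marrow area
#' rises with age (strongly in females) and with BMI in males. Slopes are
#' applied to mean-centered covariates, and the residual spread is reduced so
#' each planted marginal keeps its stated total standard deviation.
#'
#' @param n_male,n_female subject counts.
#' @param age,bmi,sft,bma per-sex distribution parameters: named lists with
#'   `M` and `F` entries, each `c(mean, sd, min, max)` (min/max optional).
#' @param severity_props 4 mixture proportions summing to 1
#'   (normal, mild, moderate, severe).
#' @param fat_fraction_levels per-severity muscle fat fractions.
#' @param slopes named list of per-sex planted slopes: `sft_age`, `sft_bmi`
#'   (mm per y / mm per kg m^-2), `bma_age`, `bma_bmi` (mm^2 per unit),
#'   `mfi_age`, `mfi_bmi` (fat-fraction per unit); each `c(M = , F = )`.
#' @param severity_allocation `"quota"` (largest-remainder exact allocation,
#'   default) or `"multinomial"`.
#' @param sampling `"quantile"` (rank-randomized stratified draws, default)
#'   or `"random"` (iid).
#' @param seed cohort master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_male = 64L, n_female = 43L,
                          age = list(M = c(mean = 57.9, sd = 17.8, min = 11, max = 79),
                                     F = c(mean = 52.7, sd = 14.6, min = 15, max = 78)),
                          bmi = list(M = c(mean = 28.4, sd = 4.4, min = 19.0, max = 38.5),
                                     F = c(mean = 30.3, sd = 5.7, min = 19.7, max = 44.3)),
                          sft = list(M = c(mean = 4.3, sd = 2.2, min = 1),
                                     F = c(mean = 8.9, sd = 3.7, min = 1)),
                          bma = list(M = c(mean = 35.7, sd = 21.1, min = 4),
                                     F = c(mean = 32.6, sd = 20.0, min = 4)),
                          severity_props = c(normal = 0.42, mild = 0.42,
                                             moderate = 0.14, severe = 0.02),
                          fat_fraction_levels = c(normal = 0.05, mild = 0.15,
                                                  moderate = 0.30, severe = 0.60),
                          slopes = list(
                            sft_age = c(M = -0.04, F = 0),
                            sft_bmi = c(M = 0, F = 0.40),
                            bma_age = c(M = 0.25, F = 0.60),
                            bma_bmi = c(M = 1.0, F = 0),
                            mfi_age = c(M = 0, F = 0),
                            mfi_bmi = c(M = 0, F = 0)),
                          severity_allocation = c("quota", "multinomial"),
                          sampling = c("quantile", "random"),
                          seed = 1L) {
  severity_allocation <- match.arg(severity_allocation)
  sampling <- match.arg(sampling)
  cfg <- list(n_male = as.integer(n_male), n_female = as.integer(n_female),
              age = age, bmi = bmi, sft = sft, bma = bma,
              severity_props = severity_props,
              fat_fraction_levels = fat_fraction_levels,
              slopes = slopes,
              severity_allocation = severity_allocation,
              sampling = sampling, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_male >= 0, cfg$n_female >= 0,
    cfg$n_male + cfg$n_female >= 2,
    length(cfg$severity_props) == 4,
    abs(sum(cfg$severity_props) - 1) < 1e-12,
    all(cfg$severity_props >= 0),
    length(cfg$fat_fraction_levels) == 4,
    all(cfg$fat_fraction_levels >= 0), all(cfg$fat_fraction_levels < 1)
  )
  for (nm in c("age", "bmi", "sft", "bma")) {
    for (s in c("M", "F")) {
      par <- cfg[[nm]][[s]]
      stopifnot(is.numeric(par), all(c("mean", "sd") %in% names(par)),
                par[["sd"]] >= 0)
    }
  }
  stopifnot(all(c("sft_age", "sft_bmi", "bma_age", "bma_bmi",
                  "mfi_age", "mfi_bmi") %in% names(cfg$slopes)))
  invisible(cfg)
}
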