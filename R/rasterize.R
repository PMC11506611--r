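# Phantom rasterization: slice synthesis, subject stacks, cohort manifests.

# Distance from points (u, v) to the ellipse (x/a)^2 + (y/b)^2 = 1 with
# a >= b, by Newton iteration on the parametric angle in the first quadrant.
# Intended for points outside or near the ellipse; vectorized.
dist_to_ellipse <- function(u, v, a, b, iter = 30L) {
  pu <- abs(u)
  pv <- abs(v)
  th <- atan2(a * pv, b * pu)
  for (i in seq_len(iter)) {
    ct <- cos(th)
    st <- sin(th)
    f <- (a^2 - b^2) * ct * st - pu * a * st + pv * b * ct
    fp <- (a^2 - b^2) * (ct^2 - st^2) - pu * a * ct - pv * b * st
    step <- f / fp
    step[!is.finite(step)] <- 0
    th <- th - step
    th <- pmin(pmax(th, 0), pi / 2)
  }
  sqrt((a * cos(th) - pu)^2 + (b * sin(th) - pv)^2)
}

#' Rasterize one phantom slice
#'
#' Draws the leg (elliptical muscle compartment plus a subcutaneous annulus of
#' constant normal thickness), the fibula (cortical ring around a marrow disk),
#' clumped fat marbling in the muscle, a smooth multiplicative bias field, and
#' additive noise. Masks are the noise-free, bias-free region labels.
#'
#' @param spec a [phantom_spec()].
#' @param slice_index 1-based slice number, in `[1, n_slices]`.
#' @param seed integer seed for this slice's random stream; defaults to a
#'   stream derived from `spec$seed` and the slice index.
#' @return A list with `image` (matrix, a.u.), `masks` (named list of logical
#'   matrices `subcutaneous`, `marrow`, `muscle`, `leg`), `pixel_size`, and
#'   attributes `bias_field` and `fat_patches` holding the planted truth.
#' @export
rasterize_slice <- function(spec, slice_index,
                            seed = derive_seed(spec$seed, "slice", slice_index)) {
  validate_phantom_spec(spec)
  stopifnot(slice_index >= 1, slice_index <= spec$n_slices)
  n <- spec$image_size
  px <- spec$pixel_size
  ctr <- (n + 1) / 2
  # mm coordinates of pixel centers; row grows inferiorly
  rr <- matrix((seq_len(n) - ctr) * px, n, n)
  cc <- matrix((seq_len(n) - ctr) * px, n, n, byrow = TRUE)

  a <- spec$leg_radius               # LR semi-axis (columns)
  b <- spec$leg_radius * spec$leg_aspect  # AP semi-axis (rows)
  inner <- (cc / a)^2 + (rr / b)^2 <= 1

  # constant normal-thickness annulus: 0 < distance-to-ellipse <= sf_thickness.
  # The exact (Newton) distance is only evaluated on the candidate band
  # around the compartment; elsewhere the offset cannot be reached.
  t_off <- spec$sf_thickness
  band <- !inner &
    (cc / (a + t_off + 2 * px))^2 + (rr / (b + t_off + 2 * px))^2 <= 1
  sf <- matrix(FALSE, n, n)
  if (any(band)) {
    dell <- dist_to_ellipse(cc[band], rr[band], a, b)
    sf[band] <- dell <= t_off
  }
  leg <- inner | sf

  fr <- spec$fibula_center[1]
  fc <- spec$fibula_center[2]
  rm_marrow <- sqrt(spec$marrow_area / pi)
  rf <- rm_marrow + spec$cortical_rim
  ecc <- sqrt((fc / a)^2 + (fr / b)^2)
  if (ecc + rf / min(a, b) >= 1) {
    stop(sprintf(
      "fibula geometry overflow: center offset (%.1f, %.1f) mm with outer radius %.1f mm does not fit inside the muscle compartment (%.1f x %.1f mm)",
      fr, fc, rf, b, a))
  }
  dfib <- sqrt((rr - fr)^2 + (cc - fc)^2)
  marrow <- dfib <= rm_marrow
  fibula <- dfib <= rf
  muscle <- inner & !fibula

  im <- spec$intensity_model
  img <- matrix(im[["background"]], n, n)
  img[sf] <- im[["fat"]]
  img[fibula] <- im[["cortical"]]
  img[marrow] <- im[["fat"]]
  img[muscle] <- im[["muscle"]]

  patches <- matrix(FALSE, n, n)
  with_seed(seed, {
    if (spec$fat_fraction > 0) {
      # diffuse sub-voxel infiltration shifts every muscle pixel; the rest
      # of the fat mass forms clumped marbling patches at full fat intensity
      diffuse <- spec$diffuse_fraction * spec$fat_fraction
      clumped <- (1 - spec$diffuse_fraction) * spec$fat_fraction
      alpha <- matrix(diffuse, n, n)
      nmus <- sum(muscle)
      k <- round(clumped * nmus)
      if (k > 0) {
        field <- smooth_random_field(n, n, spec$clump_scale / px)
        vals <- field[muscle]
        thr <- sort(vals, decreasing = TRUE)[k]
        patches <- muscle & field >= thr
        # resolve ties at the threshold so exactly k pixels are planted
        excess <- sum(patches) - k
        if (excess > 0) {
          tie <- which(patches & field == thr)
          patches[tie[seq_len(excess)]] <- FALSE
        }
        pv <- patches + 0
        if (spec$partial_volume_mm > 0) {
          pv <- as.matrix(EBImage::gblur(pv, sigma = spec$partial_volume_mm / px))
        }
        alpha <- alpha + pv
      }
      alpha <- pmin(pmax(alpha, 0), 1)
      img[muscle] <- im[["muscle"]] +
        (im[["fat"]] - im[["muscle"]]) * alpha[muscle]
    }

    bias <- matrix(1, n, n)
    if (spec$bias_amplitude > 0) {
      u <- (rr / (n * px / 2))
      v <- (cc / (n * px / 2))
      co <- stats::rnorm(5)
      p <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
      p <- p - mean(p[leg])
      p <- p / max(abs(p[leg]))
      bias <- 1 + spec$bias_amplitude * p
      img <- img * bias
    }

    if (spec$noise_sigma > 0) {
      if (spec$noise_model == "gaussian") {
        img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
        img <- pmax(img, 0)
      } else {
        n1 <- matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
        n2 <- matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
        img <- sqrt((img + n1)^2 + n2^2)
      }
    }
    structure(
      list(image = img,
           masks = list(subcutaneous = sf, marrow = marrow,
                        muscle = muscle, leg = leg),
           pixel_size = px),
      bias_field = bias, fat_patches = patches)
  })
}

#' Generate a full image/mask stack for one subject
#'
#' Applies the subject's planted truth (annulus thickness, marrow area, fat
#' fraction) to the base spec and rasterizes all slices with a small smooth
#' slice-to-slice variation (<= 3 percent peak-to-peak) in the compartment
#' radii; the planted annulus thickness and marrow area are held constant so
#' the truth is exactly recoverable.
#'
#' @param truth a [subject_truth()].
#' @param spec base [phantom_spec()]; geometry fields tied to the truth are
#'   overridden.
#' @return An object of class `phantom_stack`: list with `image` and `masks`
#'   (arrays `image_size x image_size x n_slices`; masks is a named list of
#'   logical arrays), `pixel_size`, `slice_z` (mm), `truth`, `spec`.
#' @export
generate_subject <- function(truth, spec = phantom_spec()) {
  stopifnot(inherits(truth, "subject_truth"))
  spec$sf_thickness <- truth$true_sft
  spec$marrow_area <- truth$true_bma
  spec$fat_fraction <- truth$true_fat_fraction
  subject_seed <- derive_seed(spec$seed, "subject-stream", truth$subject_id,
                              truth$seed)
  spec$seed <- subject_seed
  validate_phantom_spec(spec)

  n <- spec$image_size
  ns <- spec$n_slices
  phase <- with_seed(derive_seed(subject_seed, "geometry"),
                     stats::runif(1, 0, 2 * pi))
  img <- array(0, c(n, n, ns))
  masks <- lapply(stats::setNames(nm = c("subcutaneous", "marrow", "muscle", "leg")),
                  function(nm) array(FALSE, c(n, n, ns)))
  for (s in seq_len(ns)) {
    scale_s <- 1 + 0.015 * sin(2 * pi * (s - 1) / max(ns - 1, 1) + phase)
    sp <- spec
    sp$leg_radius <- spec$leg_radius * scale_s
    sp$fibula_center <- spec$fibula_center * scale_s
    sl <- rasterize_slice(sp, s, seed = derive_seed(subject_seed, "slice", s))
    img[, , s] <- sl$image
    for (nm in names(masks)) masks[[nm]][, , s] <- sl$masks[[nm]]
  }
  structure(
    list(image = img, masks = masks, pixel_size = spec$pixel_size,
         slice_z = (seq_len(ns) - 1) * (spec$slice_thickness + spec$slice_gap),
         truth = truth, spec = spec),
    class = "phantom_stack")
}

# Draw per-subject ground truth for one sex.
draw_sex_truths <- function(cfg, sex, n) {
  if (n == 0) {
    return(data.frame(sex = character(0), age = numeric(0), bmi = numeric(0),
                      true_sft = numeric(0), true_bma = numeric(0),
                      redraws = integer(0)))
  }
  par <- function(block) cfg[[block]][[sex]]
  get2 <- function(p, nm, default) if (nm %in% names(p)) p[[nm]] else default
  method <- cfg$sampling
  agep <- par("age")
  bmip <- par("bmi")
  age <- draw_truncnorm(n, agep[["mean"]], agep[["sd"]],
                        get2(agep, "min", -Inf), get2(agep, "max", Inf), method)
  bmi <- draw_truncnorm(n, bmip[["mean"]], bmip[["sd"]],
                        get2(bmip, "min", -Inf), get2(bmip, "max", Inf), method)

  planted <- function(block, slope_age, slope_bmi) {
    p <- par(block)
    explained <- slope_age^2 * agep[["sd"]]^2 + slope_bmi^2 * bmip[["sd"]]^2
    if (explained > p[["sd"]]^2) {
      stop(sprintf("planted %s slopes for sex %s explain more variance than the stated sd", block, sex))
    }
    sd_resid <- sqrt(p[["sd"]]^2 - explained)
    resid <- draw_truncnorm(n, 0, sd_resid, method = method)
    val <- p[["mean"]] + slope_age * (age - agep[["mean"]]) +
      slope_bmi * (bmi - bmip[["mean"]]) + resid
    lo <- get2(p, "min", 0)
    redraws <- 0L
    for (it in 1:100) {
      bad <- which(val < lo)
      if (!length(bad)) break
      redraws <- redraws + length(bad)
      val[bad] <- p[["mean"]] + slope_age * (age[bad] - agep[["mean"]]) +
        slope_bmi * (bmi[bad] - bmip[["mean"]]) + stats::rnorm(length(bad), 0, sd_resid)
    }
    val[val < lo] <- lo
    list(val = val, redraws = redraws)
  }
  sft <- planted("sft", cfg$slopes$sft_age[[sex]], cfg$slopes$sft_bmi[[sex]])
  bma <- planted("bma", cfg$slopes$bma_age[[sex]], cfg$slopes$bma_bmi[[sex]])
  data.frame(sex = rep(sex, n), age = age, bmi = bmi,
             true_sft = sft$val, true_bma = bma$val,
             redraws = rep(sft$redraws + bma$redraws, n))
}

#' Draw a cohort manifest of planted subject truths
#'
#' Samples per-sex demographics and morphometry with the configured planted
#' slopes, allocates the 4-level severity mixture (exact largest-remainder
#' quota by default), and derives per-subject fat fractions.
#'
#' @param config a [cohort_config()].
#' @return A `data.frame` manifest with columns `subject_id, sex, age, bmi,
#'   true_sft, true_bma, true_fat_fraction, severity_class, seed`, and
#'   attribute `redraws` (count of resampled out-of-range draws).
#' @export
generate_truths <- function(config) {
  validate_cohort_config(config)
  with_seed(derive_seed(config$seed, "truths"), {
    males <- draw_sex_truths(config, "M", config$n_male)
    females <- draw_sex_truths(config, "F", config$n_female)
    df <- rbind(males, females)
    n <- nrow(df)
    df$subject_id <- sprintf("S%03d", seq_len(n))

    lv <- severity_levels(4L)
    if (config$severity_allocation == "quota") {
      counts <- quota_allocation(n, config$severity_props)
      sev <- sample(rep(lv, counts))
    } else {
      sev <- sample(lv, n, replace = TRUE, prob = config$severity_props)
    }
    df$severity_class <- sev

    ff <- config$fat_fraction_levels[df$severity_class]
    for (sx in c("M", "F")) {
      i <- df$sex == sx
      if (!any(i)) next
      ff[i] <- ff[i] +
        config$slopes$mfi_age[[sx]] * (df$age[i] - config$age[[sx]][["mean"]]) +
        config$slopes$mfi_bmi[[sx]] * (df$bmi[i] - config$bmi[[sx]][["mean"]])
    }
    df$true_fat_fraction <- pmin(pmax(ff, 0), 0.95)
    df$seed <- vapply(seq_len(n), function(i) derive_seed(config$seed, "subject", i),
                      integer(1))
    redraws <- sum(df$redraws[!duplicated(df$sex)])
    df$redraws <- NULL
    rownames(df) <- NULL
    df <- df[, c("subject_id", "sex", "age", "bmi", "true_sft", "true_bma",
                 "true_fat_fraction", "severity_class", "seed")]
    attr(df, "redraws") <- redraws
    df
  })
}

#' Generate a synthetic cohort
#'
#' Draws the manifest of planted truths and, if `dir` is given, writes each
#' subject's image and multi-label mask stack as NIfTI-1 volumes plus a
#' `manifest.csv`. Without `dir` the cohort is lazy: subjects are rasterized
#' on demand with [cohort_subject()].
#'
#' @param config a [cohort_config()].
#' @param spec base [phantom_spec()] shared by all subjects.
#' @param dir optional output directory for NIfTI volumes and the manifest.
#' @return An object of class `phantom_cohort`: list with `manifest`,
#'   `config`, `spec`, `dir`.
#' @export
generate_cohort <- function(config, spec = phantom_spec(), dir = NULL) {
  manifest <- generate_truths(config)
  cohort <- structure(list(manifest = manifest, config = config, spec = spec,
                           dir = dir),
                      class = "phantom_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    for (i in seq_len(nrow(manifest))) {
      write_subject_nifti(cohort_subject(cohort, i), dir)
    }
  }
  cohort
}

#' Realize one subject of a cohort
#'
#' @param cohort a `phantom_cohort`.
#' @param i row index or subject id.
#' @return A `phantom_stack` (see [generate_subject()]).
#' @export
cohort_subject <- function(cohort, i) {
  m <- cohort$manifest
  if (is.character(i)) i <- match(i, m$subject_id)
  stopifnot(!is.na(i), i >= 1, i <= nrow(m))
  truth <- subject_truth(m$subject_id[i], m$sex[i], m$age[i], m$bmi[i],
                         m$true_sft[i], m$true_bma[i], m$true_fat_fraction[i],
                         m$severity_class[i], m$seed[i])
  generate_subject(truth, cohort$spec)
}

# Mask label encoding used in multi-label NIfTI volumes; cortical bone is
# whatever leg tissue remains (label 4), so the leg layer round-trips.
MASK_LABELS <- c(muscle = 1L, subcutaneous = 2L, marrow = 3L, cortical = 4L)

#' Write a subject stack as NIfTI-1 volumes
#'
#' Writes `<id>_image.nii.gz` and `<id>_mask.nii.gz` (labels: 0 background,
#' 1 muscle, 2 subcutaneous fat, 3 fibula marrow, 4 cortical bone) with the
#' pixel size recorded in the header.
#'
#' @param stack a `phantom_stack`.
#' @param dir output directory.
#' @return Invisibly, the two file paths.
#' @export
write_subject_nifti <- function(stack, dir) {
  id <- stack$truth$subject_id
  lab <- array(0L, dim(stack$image))
  lab[stack$masks$leg] <- MASK_LABELS[["cortical"]]
  for (nm in c("muscle", "subcutaneous", "marrow")) {
    lab[stack$masks[[nm]]] <- MASK_LABELS[[nm]]
  }
  zstep <- stack$spec$slice_thickness + stack$spec$slice_gap
  pd <- c(stack$pixel_size, stack$pixel_size, zstep)
  fi <- file.path(dir, paste0(id, "_image.nii.gz"))
  fm <- file.path(dir, paste0(id, "_mask.nii.gz"))
  nim <- RNifti::asNifti(stack$image)
  RNifti::pixdim(nim) <- pd
  nlab <- RNifti::asNifti(lab)
  RNifti::pixdim(nlab) <- pd
  RNifti::writeNifti(nim, fi)
  RNifti::writeNifti(nlab, fm)
  invisible(c(image = fi, mask = fm))
}

#' Read a subject stack written by [write_subject_nifti()]
#'
#' @param dir directory containing the volumes.
#' @param subject_id subject id.
#' @return A list with `image`, `masks` (logical arrays `subcutaneous`,
#'   `marrow`, `muscle`, and the derived `leg` layer), and `pixel_size`.
#' @export
read_subject_nifti <- function(dir, subject_id) {
  img <- RNifti::readNifti(file.path(dir, paste0(subject_id, "_image.nii.gz")))
  lab <- RNifti::readNifti(file.path(dir, paste0(subject_id, "_mask.nii.gz")))
  px <- RNifti::pixdim(img)[1]
  arr <- array(as.numeric(img), dim(img))
  lab <- array(as.integer(lab), dim(lab))
  masks <- lapply(MASK_LABELS[c("subcutaneous", "marrow", "muscle")],
                  function(v) lab == v)
  masks$leg <- lab > 0
  list(image = arr, masks = masks, pixel_size = px)
}
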