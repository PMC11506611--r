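# Orchestration: simulate -> bias-correct -> measure -> histogram/MFI ->
# cluster -> associate, from one configuration with derived stage seeds.

#' Build a pipeline run configuration
#'
#' @param cohort a [cohort_config()].
#' @param spec a [phantom_spec()].
#' @param bias_method `"polynomial"` or `"n4"`.
#' @param bias_order polynomial order for the polynomial method.
#' @param bin_width histogram bin width, a.u.
#' @param lineshape `"pseudo_gaussian"` or `"gaussian"`.
#' @param clusters `"auto"` (separability rule over 3/4/5) or an integer.
#' @param fuzzifier FCM fuzzifier m.
#' @param n_restarts FCM random restarts.
#' @param robustness_cv named fractional repeatability CVs used for the
#'   noise-robustness battery (defaults to the repeatability of manual
#'   segmentation this pipeline emulates).
#' @param n_exec noise-robustness executions.
#' @param seed master seed; all stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       spec = phantom_spec(),
                       bias_method = c("polynomial", "n4"),
                       bias_order = 3L,
                       bin_width = 2,
                       lineshape = c("pseudo_gaussian", "gaussian"),
                       clusters = 4L,
                       fuzzifier = 2,
                       n_restarts = 10L,
                       robustness_cv = c(sft = 0.030, bma = 0.034,
                                         mfi_mean = 0.032, mfi_mode = 0.041),
                       n_exec = 10L,
                       seed = 1L) {
  bias_method <- match.arg(bias_method)
  lineshape <- match.arg(lineshape)
  cohort$seed <- derive_seed(seed, "cohort")
  spec$seed <- derive_seed(seed, "phantom")
  structure(list(cohort = cohort, spec = spec, bias_method = bias_method,
                 bias_order = as.integer(bias_order), bin_width = bin_width,
                 lineshape = lineshape, clusters = clusters,
                 fuzzifier = fuzzifier, n_restarts = as.integer(n_restarts),
                 robustness_cv = robustness_cv, n_exec = as.integer(n_exec),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  # YAML loses the names of named numeric vectors; serialize them as maps
  as_map <- function(v) as.list(v)
  cohort <- unclass(config$cohort)
  for (nm in c("age", "bmi", "sft", "bma")) {
    cohort[[nm]] <- lapply(cohort[[nm]], as_map)
  }
  cohort$slopes <- lapply(cohort$slopes, as_map)
  cohort$severity_props <- as_map(cohort$severity_props)
  cohort$fat_fraction_levels <- as_map(cohort$fat_fraction_levels)
  spec <- unclass(config$spec)
  spec$intensity_model <- as_map(spec$intensity_model)
  ser <- list(
    cohort = cohort, spec = spec,
    bias_method = config$bias_method, bias_order = config$bias_order,
    bin_width = config$bin_width, lineshape = config$lineshape,
    clusters = config$clusters, fuzzifier = config$fuzzifier,
    n_restarts = config$n_restarts,
    robustness_cv = as.list(config$robustness_cv), n_exec = config$n_exec,
    seed = config$seed)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  s <- yaml::read_yaml(path)
  cohort <- s$cohort
  for (nm in c("age", "bmi", "sft", "bma")) {
    cohort[[nm]] <- lapply(cohort[[nm]], unlist)
  }
  cohort$slopes <- lapply(cohort$slopes, unlist)
  cohort$severity_props <- unlist(cohort$severity_props)
  cohort$fat_fraction_levels <- unlist(cohort$fat_fraction_levels)
  class(cohort) <- "cohort_config"
  validate_cohort_config(cohort)
  spec <- s$spec
  spec$intensity_model <- unlist(spec$intensity_model)
  spec$fibula_center <- unlist(spec$fibula_center)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  cfg <- structure(list(cohort = cohort, spec = spec,
                        bias_method = s$bias_method, bias_order = s$bias_order,
                        bin_width = s$bin_width, lineshape = s$lineshape,
                        clusters = s$clusters, fuzzifier = s$fuzzifier,
                        n_restarts = s$n_restarts,
                        robustness_cv = unlist(s$robustness_cv),
                        n_exec = s$n_exec, seed = s$seed),
                   class = "run_config")
  cfg
}

CENTRAL_SLICES <- 2:8

#' Process one subject stack end to end
#'
#' Bias-corrects the central seven slices, measures SFT and BMA from the
#' truth masks, derives the peripheral muscle ROI inferior to the fibula,
#' builds the averaged normalized histogram, fits the lineshape, and
#' extracts the MFI features.
#'
#' @param stack a `phantom_stack` (or compatible list).
#' @param bias_method,bias_order,bin_width,lineshape processing options
#'   (see [run_config()]).
#' @return A list with `sft`, `bma` (full morphometry results), `profile`,
#'   `fit`, `features`, `roi_pixels`.
#' @export
process_subject <- function(stack, bias_method = "polynomial", bias_order = 3L,
                            bin_width = 2, lineshape = "pseudo_gaussian") {
  slice_names <- as.character(CENTRAL_SLICES)
  get_masks <- function(layer) {
    stats::setNames(lapply(CENTRAL_SLICES, function(s) stack$masks[[layer]][, , s]),
                    slice_names)
  }
  sf_masks <- get_masks("subcutaneous")
  marrow_masks <- get_masks("marrow")
  muscle_masks <- get_masks("muscle")
  leg_masks <- get_masks("leg")

  sft <- compute_sft(sf_masks, stack$pixel_size)
  bma <- compute_bma(marrow_masks, stack$pixel_size)

  corrected <- correct_stack(stack, slices = CENTRAL_SLICES,
                             method = bias_method, order = bias_order)
  rois <- lapply(slice_names, function(s) {
    fibula <- leg_masks[[s]] & !muscle_masks[[s]] & !sf_masks[[s]]
    # the fibula is cortex + marrow: recover it as the non-muscle interior
    fibula <- fibula | marrow_masks[[s]]
    derive_muscle_roi(muscle_masks[[s]], fibula)
  })
  names(rois) <- slice_names
  profile <- averaged_histogram(corrected, rois, bin_width = bin_width)
  fit <- fit_lineshape(profile, model = lineshape)
  features <- extract_features(profile, fit)
  list(sft = sft, bma = bma, profile = profile, fit = fit,
       features = features,
       roi_pixels = sum(vapply(rois, sum, numeric(1))))
}

#' Run the full pipeline
#'
#' Generates the cohort, processes every subject (failures exclude the
#' subject with a recorded reason rather than aborting the run), clusters
#' MFI severity, runs the association battery with its noise-robustness
#' companion, and (optionally) writes all stage outputs as CSV.
#'
#' @param config a [run_config()].
#' @param dir optional output directory; when given, writes `manifest.csv`,
#'   `morphometry.csv`, `mfi_features.csv`, `severity.csv`,
#'   `associations.csv`, `cluster_diagnostics.csv`, and `log.txt`.
#' @param progress print per-stage progress.
#' @return An object of class `pipeline_result`: list with `manifest`,
#'   `morphometry`, `features`, `profiles`, `selection`, `fcm`, `severity`,
#'   `diagnostics`, `measurements`, `associations`, `excluded`, `config`.
#' @export
run_pipeline <- function(config, dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("calfmfi %s | R %s", as.character(utils::packageVersion("calfmfi")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("master seed %d", config$seed))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
    if (progress) message(msg)
  }

  cohort <- generate_cohort(config$cohort, config$spec)
  manifest <- cohort$manifest
  say("simulated cohort manifest: %d subjects (%d redraws)",
      nrow(manifest), attr(manifest, "redraws"))

  rows <- list(); feats <- list(); profiles <- list(); excluded <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    res <- tryCatch({
      stack <- cohort_subject(cohort, i)
      process_subject(stack, config$bias_method, config$bias_order,
                      config$bin_width, config$lineshape)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[id]] <- conditionMessage(res)
      say("subject %s excluded: %s", id, conditionMessage(res))
      next
    }
    rows[[id]] <- data.frame(subject_id = id, sft_mm = res$sft$sft,
                             bma_mm2 = res$bma$bma,
                             t(stats::setNames(res$sft$sft_slice,
                                               paste0("sft_slice_", CENTRAL_SLICES))),
                             t(stats::setNames(res$bma$bma_slice,
                                               paste0("bma_slice_", CENTRAL_SLICES))))
    feats[[id]] <- data.frame(subject_id = id,
                              mean_intensity = res$features$mean_intensity,
                              mode_intensity = res$features$mode_intensity,
                              fwhm = res$features$fwhm,
                              skewness = res$features$skewness,
                              fit_converged = res$fit$converged)
    profiles[[id]] <- res$profile
  }
  morphometry <- do.call(rbind, rows)
  features <- do.call(rbind, feats)
  rownames(morphometry) <- rownames(features) <- NULL
  say("processed %d subjects, %d excluded", nrow(morphometry), length(excluded))

  kept <- manifest[manifest$subject_id %in% features$subject_id, ]
  ft <- feature_table(features$subject_id,
                      features[, c("mean_intensity", "mode_intensity", "fwhm")])
  selection <- select_features(ft)
  say("PCA selected features: %s", paste(selection$top2, collapse = ", "))

  xy <- ft$z[, selection$top2, drop = FALSE]
  fcm_seed <- derive_seed(config$seed, "fcm")
  diagnostics <- NULL
  if (identical(config$clusters, "auto")) {
    sel <- choose_cluster_count(xy, m = config$fuzzifier, seed = fcm_seed,
                                n_restarts = config$n_restarts)
    fcm <- sel$fits[[as.character(sel$c)]]
    diagnostics <- sel$diagnostics
  } else {
    fcm <- fcm_cluster(xy, c = as.integer(config$clusters),
                       m = config$fuzzifier, seed = fcm_seed,
                       n_restarts = config$n_restarts)
  }
  severity <- assign_severity(fcm, profiles = profiles[features$subject_id],
                              subject_id = features$subject_id)
  say("FCM c=%d converged: J = %.4g", fcm$c, fcm$J)

  measurements <- cohort_measurements(kept, morphometry$sft_mm,
                                      morphometry$bma_mm2,
                                      features$mean_intensity,
                                      features$mode_intensity)
  associations <- noise_robustness(measurements, cv = config$robustness_cv,
                                   n_exec = config$n_exec,
                                   seed = derive_seed(config$seed, "robustness"))
  say("association battery: %d rows", nrow(associations))
  say("total %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- structure(list(manifest = manifest, morphometry = morphometry,
                        features = features, profiles = profiles,
                        selection = selection, fcm = fcm, severity = severity,
                        diagnostics = diagnostics,
                        measurements = measurements,
                        associations = associations,
                        excluded = excluded, config = config,
                        log = log_lines),
                   class = "pipeline_result")
  if (!is.null(dir)) write_pipeline_result(out, dir)
  out
}

#' Write pipeline outputs as CSV
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(result$manifest, "manifest.csv")
  w(result$morphometry, "morphometry.csv")
  w(result$features, "mfi_features.csv")
  sev <- data.frame(subject_id = names(result$severity$label),
                    severity = as.character(result$severity$label))
  w(sev, "severity.csv")
  w(result$associations, "associations.csv")
  if (!is.null(result$diagnostics)) w(result$diagnostics, "cluster_diagnostics.csv")
  writeLines(result$log, file.path(dir, "log.txt"))
  invisible(dir)
}
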