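# Orchestration: simulate -> fit -> indices -> histograms -> statistics as a
# single reproducible run, with named phantom presets and CSV/JSON outputs.

#' Analyze a phantom study in memory
#'
#' Runs tensor fitting, index computation, and region histogram metrics for
#' every subject and timepoint, then the full group analysis.
#'
#' @param study A [make_study()] result (or an equivalent list with
#'   `subjects`, `masks`, `dwi`).
#' @param fit_method `"lls"`, `"wlls"` or `"restore"`.
#' @param sigma `"auto"` (estimate from the background mask) or a positive
#'   number; only used by RESTORE.
#' @param alpha Familywise significance threshold.
#' @param specs Optional named list of [histogram_spec()] overrides.
#' @param iqr_type Quartile rule for reported IQRs.
#' @return List: `metrics` (long study table), `analysis`
#'   (from [run_group_analysis()]), `fit_method`, `sigma`.
#' @export
analyze_study <- function(study, fit_method = c("restore", "lls", "wlls"),
                          sigma = "auto", alpha = 0.05, specs = NULL,
                          iqr_type = 7) {
  fit_method <- match.arg(fit_method)
  masks <- study$masks
  region_masks <- Filter(function(m) inherits(m, "region_mask"), masks)
  fit_mask <- Reduce(`|`, lapply(region_masks, function(m) m$mask))
  bmx <- build_bmatrix(study$dwi[[1L]]$baseline$scheme)

  metric_tables <- list()
  for (id in names(study$dwi)) {
    metric_tables[[id]] <- list()
    for (tp in c("baseline", "followup")) {
      dwi <- study$dwi[[id]][[tp]]
      tf <- switch(fit_method,
        lls = fit_tensor_lls(dwi, bmx, fit_mask),
        wlls = fit_tensor_wlls(dwi, bmx, fit_mask),
        restore = {
          sg <- if (identical(sigma, "auto")) {
            if (is.null(masks$background)) stop("sigma='auto' needs a background mask")
            estimate_noise_sigma(dwi, masks$background)
          } else as.numeric(sigma)
          fit_tensor_restore(dwi, bmx, fit_mask, noise_sigma = sg)
        })
      maps <- tensor_to_indices(tf)
      metric_tables[[id]][[tp]] <- region_metrics_table(maps, region_masks, specs)
    }
  }
  st <- study_table(metric_tables, study$subjects)
  list(metrics = st,
       analysis = run_group_analysis(st, study$subjects, alpha = alpha,
                                     iqr_type = iqr_type),
       fit_method = fit_method, sigma = sigma)
}

.presets <- function(preset, seed) {
  switch(preset,
    paper_like = phantom_spec(seed = seed),
    null = phantom_spec(
      grid_shape = c(12L, 12L, 10L),
      eig_patient_bc = c(1.00, 0.70, 0.70) * 1e-3,   # identical groups
      md_rate_patient_bc = 0, md_rate_control = 0,
      seed = seed),
    tiny = phantom_spec(
      grid_shape = c(12L, 12L, 8L),
      n_patients = 3L, n_controls = 4L,
      seed = seed),
    stop("unknown preset: ", preset, " (expected paper_like, null, or tiny)"))
}

#' Build a named phantom preset
#'
#' Presets: `"paper_like"` reproduces the emulated study design (9 patients /
#' 16 controls, 2.2-4.0 / 1.9-4.7 year intervals, Table-1-calibrated
#' compartment distributions and MD rates); `"null"` has identical group
#' distributions and zero longitudinal effects; `"tiny"` is a down-scaled
#' smoke-test study (3 / 4 subjects, minimal grid).
#'
#' @param preset_name One of `"paper_like"`, `"null"`, `"tiny"`.
#' @param seed Integer seed.
#' @param dir Optional directory; when given the study is also written to
#'   disk via [write_study()].
#' @return The [make_study()] result (invisibly carries `spec`).
#' @export
make_fixture <- function(preset_name, seed = 1L, dir = NULL) {
  study <- make_study(.presets(preset_name, seed))
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Run a complete reproducible study
#'
#' Accepts a run configuration (a list, or a path to a JSON file with the
#' same fields), simulates or loads the study, runs the pipeline, and writes
#' `metrics.csv`, `comparisons.csv` (baseline + rate families),
#' `correlations.csv`, `srm.csv` and `run_log.txt` to the output directory.
#' Deterministic given `seed`.
#'
#' @param config List or JSON path. Fields: `preset` (or `phantom`, a list of
#'   [phantom_spec()] arguments; or `study_dir`, a directory written by
#'   [write_study()]), `fit_method`, `sigma`, `alpha`, `seed`, `out_dir`.
#' @return The [analyze_study()] result, invisibly, with `out_dir` attached.
#' @export
run_study <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config stage: config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(list(fit_method = "restore", sigma = "auto",
                                alpha = 0.05, seed = 1L, out_dir = NULL), config)
  if (is.null(cfg$out_dir)) stop("config stage: out_dir is required")

  study <- tryCatch({
    if (!is.null(cfg$preset)) {
      make_fixture(cfg$preset, seed = cfg$seed)
    } else if (!is.null(cfg$phantom)) {
      args <- cfg$phantom
      args$seed <- cfg$seed
      make_study(do.call(phantom_spec, args))
    } else if (!is.null(cfg$study_dir)) {
      read_study(cfg$study_dir)
    } else stop("one of preset / phantom / study_dir is required")
  }, error = function(e) stop("simulate stage: ", conditionMessage(e), call. = FALSE))

  res <- tryCatch(
    analyze_study(study, fit_method = cfg$fit_method, sigma = cfg$sigma,
                  alpha = cfg$alpha),
    error = function(e) stop("analysis stage: ", conditionMessage(e), call. = FALSE))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  an <- res$analysis
  comparisons <- rbind(cbind(family = "baseline", an$baseline),
                       cbind(family = "rate_of_change", an$rate))
  utils::write.csv(res$metrics, file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(comparisons, file.path(cfg$out_dir, "comparisons.csv"), row.names = FALSE)
  utils::write.csv(an$correlations, file.path(cfg$out_dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(an$srm, file.path(cfg$out_dir, "srm.csv"), row.names = FALSE)
  writeLines(c(
    paste0("dtihist ", as.character(utils::packageVersion("dtihist"))),
    paste0("R ", R.version.string),
    paste0("date: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "config:",
    jsonlite::toJSON(cfg[setdiff(names(cfg), "phantom_spec")], auto_unbox = TRUE, null = "null")
  ), file.path(cfg$out_dir, "run_log.txt"))
  res$out_dir <- cfg$out_dir
  invisible(res)
}

#' Read a study written by [write_study()]
#'
#' @param dir Study directory.
#' @return A study list compatible with [analyze_study()] (without ground
#'   truth tensors).
#' @export
read_study <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  first_img <- file.path(dir, paste0(manifest$subject_id[1L], "_baseline_dwi.nii.gz"))
  grid <- dim(read_nifti(first_img)$img)[1:3]
  masks <- list(
    cerebrum = read_mask(file.path(dir, "mask_cerebrum.nii.gz"), "cerebrum", grid),
    brainstem_cerebellum = read_mask(file.path(dir, "mask_brainstem_cerebellum.nii.gz"),
                                     "brainstem_cerebellum", grid))
  masks$background <- !(masks$cerebrum$mask | masks$brainstem_cerebellum$mask)
  dwi <- list()
  for (id in manifest$subject_id) {
    dwi[[id]] <- list()
    for (tp in c("baseline", "followup")) {
      stem <- file.path(dir, paste0(id, "_", tp))
      dwi[[id]][[tp]] <- read_dwi(paste0(stem, "_dwi.nii.gz"),
                                  paste0(stem, ".bval"), paste0(stem, ".bvec"))
    }
  }
  list(subjects = manifest, masks = masks, dwi = dwi)
}
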