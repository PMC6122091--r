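#' @include ensemble.R features.R rangesep.R synthetic.R structure-prep.R
NULL

#' Build a run configuration
#'
#' Programmatic constructor for [RunConfig-class]; see [readRunConfig()]
#' for the file-based route.  Exactly one of `qcLogPaths`, `stickTablePaths`
#' or `recipe` may be given.
#'
#' @param inputMode `"qc_logs"`, `"stick_tables"` or `"synthetic"`.
#' @param qcLogPaths,stickTablePaths,recipe the input source.
#' @param sigmaEv,gridMinNm,gridMaxNm,gridStepNm,energyWeighting broadening.
#' @param confidenceLevel,ciMethod ensemble band options.
#' @param minProminence,shiftToleranceNm,positiveWindowNm feature options.
#' @param experimentalCsv optional experimental reference CSV.
#' @param outDir,seed output directory and root seed.
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(inputMode = "synthetic", qcLogPaths = character(),
                      stickTablePaths = character(), recipe = NULL,
                      sigmaEv = 0.3, gridMinNm = 170, gridMaxNm = 400,
                      gridStepNm = 0.5, energyWeighting = "per_state_energy",
                      confidenceLevel = 0.95, ciMethod = "t",
                      minProminence = 1, shiftToleranceNm = 20,
                      positiveWindowNm = c(220, 240),
                      experimentalCsv = NA_character_, outDir = tempfile("run"),
                      seed = 1) {
  if (inputMode == "synthetic" && is.null(recipe) &&
      length(qcLogPaths) == 0 && length(stickTablePaths) == 0)
    recipe <- ensembleRecipe(seed = seed)
  new("RunConfig", inputMode = inputMode, qcLogPaths = qcLogPaths,
      stickTablePaths = stickTablePaths, recipe = recipe, sigmaEv = sigmaEv,
      gridMinNm = gridMinNm, gridMaxNm = gridMaxNm, gridStepNm = gridStepNm,
      energyWeighting = energyWeighting, confidenceLevel = confidenceLevel,
      ciMethod = ciMethod, minProminence = minProminence,
      shiftToleranceNm = shiftToleranceNm,
      positiveWindowNm = as.numeric(positiveWindowNm),
      experimentalCsv = experimentalCsv, outDir = outDir, seed = seed)
}

#' Read a run configuration from a flat YAML file
#'
#' The config is a flat key-value document with units in the key names
#' (`sigma_eV`, `grid_min_nm`, ...).  Synthetic-recipe fields
#' (`n_snapshots`, `band_centers_eV`, `band_mean_R`, `band_n_states`,
#' `energy_jitter_eV`, `r_jitter_frac`) populate an [EnsembleRecipe-class]
#' when `input_mode: synthetic`.
#'
#' @param path YAML file path.
#' @return a validated [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  seed <- pick("seed", 1)
  recipe <- NULL
  if (identical(pick("input_mode", "synthetic"), "synthetic") ||
      !is.null(y$band_centers_eV)) {
    if (!is.null(y$band_centers_eV)) {
      bands <- data.frame(center_eV = as.numeric(y$band_centers_eV),
                          mean_R = as.numeric(y$band_mean_R),
                          n_states = as.integer(y$band_n_states))
      recipe <- ensembleRecipe(nSnapshots = pick("n_snapshots", 10),
                               bands = bands,
                               energyJitterEv = pick("energy_jitter_eV", 0.05),
                               rJitterFrac = pick("r_jitter_frac", 0.10),
                               seed = pick("recipe_seed", seed))
    } else if (identical(pick("input_mode", "synthetic"), "synthetic")) {
      recipe <- ensembleRecipe(seed = pick("recipe_seed", seed))
    }
  }
  runConfig(inputMode = pick("input_mode", "synthetic"),
            qcLogPaths = as.character(pick("qc_log_paths", character())),
            stickTablePaths = as.character(pick("stick_table_paths",
                                                character())),
            recipe = recipe,
            sigmaEv = pick("sigma_eV", 0.3),
            gridMinNm = pick("grid_min_nm", 170),
            gridMaxNm = pick("grid_max_nm", 400),
            gridStepNm = pick("grid_step_nm", 0.5),
            energyWeighting = pick("energy_weighting", "per_state_energy"),
            confidenceLevel = pick("confidence_level", 0.95),
            ciMethod = pick("ci_method", "t"),
            minProminence = pick("min_prominence", 1),
            shiftToleranceNm = pick("shift_tolerance_nm", 20),
            positiveWindowNm = as.numeric(pick("positive_window_nm",
                                               c(220, 240))),
            experimentalCsv = pick("experimental_csv", NA_character_),
            outDir = pick("out_dir", tempfile("run")), seed = seed)
}

.log_line <- function(log_path, ...) {
  msg <- paste0(...)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  message(msg)
}

#' Run the end-to-end ECD analysis pipeline
#'
#' Parses or generates the snapshot stick spectra, convolves each into a
#' broadened CD spectrum, averages the ensemble with a confidence band,
#' detects peaks and the positive-shoulder diagnostic, and (when an
#' experimental reference is configured) matches calculated against
#' experimental negative peaks.  Writes per-snapshot spectra, the ensemble
#' CSV, the feature/comparison report, a human-readable log, and a
#' machine-readable JSON manifest (config echo, versions, seed, and an MD5
#' checksum for every output file).  Identical configuration and inputs
#' produce byte-identical numeric outputs.
#'
#' @param config a [RunConfig-class].
#' @return (invisibly) a list with `ensemble` ([EnsembleSpectrum-class]),
#'   `peaks`, `positiveFeature`, `report` (a [ComparisonReport-class] or
#'   NULL), and `manifest` (the manifest list).
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config@outDir, "run.log")
  cat("", file = log_path)  # truncate
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sticks <- stage("input", switch(config@inputMode,
    qc_logs = lapply(config@qcLogPaths, parseQcLog),
    stick_tables = lapply(config@stickTablePaths, readStickTable),
    synthetic = generateEnsemble(config@recipe)))
  .log_line(log_path, "input: ", length(sticks), " stick spectrum/spectra (",
            config@inputMode, ")")

  bc <- BroadeningConfig(sigma = config@sigmaEv, gridMin = config@gridMinNm,
                         gridMax = config@gridMaxNm,
                         gridStep = config@gridStepNm,
                         energyWeighting = config@energyWeighting)
  spectra <- stage("convolve", lapply(sticks, convolveSticks, config = bc))
  .log_line(log_path, "convolve: sigma = ", config@sigmaEv, " eV on ",
            config@gridMinNm, "-", config@gridMaxNm, " nm")

  snap_files <- character(length(spectra))
  for (i in seq_along(spectra)) {
    snap_files[i] <- file.path(config@outDir,
                               sprintf("snapshot_%02d.csv", i))
    sp <- spectra[[i]]
    writeLines(c("wavelength_nm,delta_epsilon",
                 sprintf("%.15g,%.15g", sp@grid, sp@values)), snap_files[i])
  }

  ensemble <- stage("ensemble", withCallingHandlers(
    averageSpectra(spectra, confidenceLevel = config@confidenceLevel,
                   method = config@ciMethod, seed = config@seed),
    warning = function(w) {
      .log_line(log_path, "warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  ens_file <- file.path(config@outDir, "ensemble.csv")
  writeEnsembleCsv(ensemble, ens_file)

  mean_spec <- CDSpectrum(ensemble@grid, ensemble@mean, label = "ensemble-mean")
  peaks <- stage("features", findPeaks(mean_spec,
                                       minProminence = config@minProminence))
  pos <- stage("features", positiveFeature(mean_spec,
                                           config@positiveWindowNm))
  neg <- peaks[peaks$sign == "negative", , drop = FALSE]
  .log_line(log_path, "features: ", nrow(neg), " negative / ",
            sum(peaks$sign == "positive"), " positive peak(s); ",
            "positive feature in ", config@positiveWindowNm[1], "-",
            config@positiveWindowNm[2], " nm = ", sprintf("%.3f", pos),
            " M-1cm-1")

  report <- NULL
  report_files <- character()
  if (!is.na(config@experimentalCsv)) {
    exp_sp <- stage("compare", readExperimentalCsv(config@experimentalCsv))
    exp_peaks <- stage("compare",
                       findPeaks(exp_sp, minProminence = config@minProminence))
    report <- stage("compare",
                    matchPeaks(peaks, exp_peaks, signFilter = "negative",
                               toleranceNm = config@shiftToleranceNm))
    report <- addPositiveFeature(report, mean_spec, config@positiveWindowNm)
    rep_txt <- file.path(config@outDir, "comparison.txt")
    rep_csv <- file.path(config@outDir, "matched_pairs.csv")
    writeComparisonReport(report, rep_txt)
    writeMatchedPairsCsv(report, rep_csv)
    report_files <- c(rep_txt, rep_csv)
    .log_line(log_path, "compare: max |shift| = ",
              sprintf("%.2f", report@maxAbsShift), " nm; verdict at ",
              config@shiftToleranceNm, " nm: ", report@verdict)
  }

  feat_file <- file.path(config@outDir, "features.txt")
  writeLines(c(sprintf("n_negative_peaks: %d", nrow(neg)),
               sprintf("n_positive_peaks: %d", sum(peaks$sign == "positive")),
               sprintf("negative_peak_positions_nm: %s",
                       paste(sprintf("%.10g", neg$position_nm),
                             collapse = " ")),
               sprintf("positive_feature_window_nm: %g-%g",
                       config@positiveWindowNm[1], config@positiveWindowNm[2]),
               sprintf("positive_feature_max: %.10g", pos)), feat_file)

  out_files <- c(snap_files, ens_file, feat_file, report_files)
  manifest <- list(
    config = .config_as_list(config),
    seed = config@seed,
    versions = list(ecdtools = as.character(utils::packageVersion("ecdtools")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    outputs = lapply(out_files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  man_file <- file.path(config@outDir, "manifest.json")
  jsonlite::write_json(manifest, man_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .log_line(log_path, "done: ", length(out_files),
            " output file(s) in ", config@outDir)

  invisible(list(ensemble = ensemble, peaks = peaks, positiveFeature = pos,
                 report = report, manifest = manifest))
}

.config_as_list <- function(config) {
  rec <- config@recipe
  list(input_mode = config@inputMode,
       qc_log_paths = config@qcLogPaths,
       stick_table_paths = config@stickTablePaths,
       recipe = if (is.null(rec)) NULL else list(
         n_snapshots = rec@nSnapshots,
         band_centers_eV = rec@bands$center_eV,
         band_mean_R = rec@bands$mean_R,
         band_n_states = rec@bands$n_states,
         energy_jitter_eV = rec@energyJitterEv,
         r_jitter_frac = rec@rJitterFrac,
         seed = rec@seed),
       sigma_eV = config@sigmaEv,
       grid_min_nm = config@gridMinNm, grid_max_nm = config@gridMaxNm,
       grid_step_nm = config@gridStepNm,
       energy_weighting = config@energyWeighting,
       confidence_level = config@confidenceLevel, ci_method = config@ciMethod,
       min_prominence = config@minProminence,
       shift_tolerance_nm = config@shiftToleranceNm,
       positive_window_nm = config@positiveWindowNm,
       experimental_csv = config@experimentalCsv,
       out_dir = config@outDir, seed = config@seed)
}

#' Scan functional parameters along the CAM-B3LYP to B3LYP path
#'
#' Writes the interpolation path as CSV (`point,t,alpha,beta,mu`) and one
#' override stanza file per point, ready for an external excited-state
#' scan.
#'
#' @param nPoints points including endpoints (default 5).
#' @param start,end [RangeSepParams-class] endpoints (defaults:
#'   [camB3LYP()] to [b3lyp()]).
#' @param outDir output directory (created if needed).
#' @return (invisibly) the [parameterPath()] result.
#' @export
scanFunctionals <- function(nPoints = 5, start = camB3LYP(), end = b3lyp(),
                            outDir = tempfile("scan")) {
  path <- parameterPath(start, end, nPoints)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writePathCsv(path, file.path(outDir, "path.csv"))
  for (i in seq_along(path))
    writeLines(emitOverrides(path[[i]]),
               file.path(outDir, sprintf("point_%d_overrides.txt", i)))
  invisible(path)
}
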