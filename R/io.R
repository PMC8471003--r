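#' Write a dataset to spectra + manifest CSV files
#'
#' The spectra file has a `wavelength_nm` column followed by one intensity
#' column per spectrum id; the manifest has one row per spectrum with
#' columns `spectrum_id`, `construct_label`, `fiber_id`, `rebuild_id`,
#' `rep_index`, `exposure_ms`, `role`.
#'
#' @param dataset An `lss_dataset`.
#' @param spectra_file,manifest_file Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, spectra_file, manifest_file) {
  stopifnot(inherits(dataset, "lss_dataset"))
  wide <- data.frame(wavelength_nm = dataset$wavelengths)
  mat <- dataset$spectra
  colnames(mat) <- dataset$manifest$spectrum_id
  wide <- cbind(wide, as.data.frame(mat))
  utils::write.csv(wide, spectra_file, row.names = FALSE)
  utils::write.csv(dataset$manifest, manifest_file, row.names = FALSE)
  invisible(c(spectra = spectra_file, manifest = manifest_file))
}

#' Read a dataset from spectra + manifest CSV files
#'
#' Validates the file contract written by [write_dataset()]: every
#' manifest row must reference an existing spectrum column, labels must be
#' valid construct labels, and intensities must be finite and
#' non-negative. Validation errors report the offending manifest line.
#'
#' @param spectra_file,manifest_file Input CSV paths.
#' @return An `lss_dataset`.
#' @export
read_dataset <- function(spectra_file, manifest_file) {
  if (!file.exists(spectra_file)) stop("missing file: ", spectra_file, call. = FALSE)
  if (!file.exists(manifest_file)) stop("missing file: ", manifest_file, call. = FALSE)
  wide <- utils::read.csv(spectra_file, check.names = FALSE)
  man <- utils::read.csv(manifest_file, stringsAsFactors = FALSE,
                         colClasses = c(construct_label = "character"))
  required <- c("spectrum_id", "construct_label", "fiber_id", "rebuild_id",
                "exposure_ms", "role")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"rep_index" %in% names(man)) man$rep_index <- NA_integer_
  if (!"wavelength_nm" %in% names(wide)) {
    stop("spectra file lacks the wavelength_nm column", call. = FALSE)
  }
  wl <- wide$wavelength_nm
  if (any(diff(wl) <= 0)) {
    stop("wavelength_nm must be strictly increasing", call. = FALSE)
  }
  orphan <- which(!man$spectrum_id %in% names(wide))
  if (length(orphan)) {
    stop(sprintf(
      "manifest line %d references absent spectrum id '%s'",
      orphan[1] + 1L, man$spectrum_id[orphan[1]]), call. = FALSE)
  }
  bad_label <- which(!is.na(man$construct_label) & man$role == "tissue" &
                       !grepl("^[01]{8}$", man$construct_label))
  if (length(bad_label)) {
    stop(sprintf("manifest line %d has malformed construct label '%s'",
                 bad_label[1] + 1L, man$construct_label[bad_label[1]]),
         call. = FALSE)
  }
  spectra <- as.matrix(wide[, man$spectrum_id, drop = FALSE])
  if (any(!is.finite(spectra)) || any(spectra < 0)) {
    stop("spectra contain non-finite or negative intensities", call. = FALSE)
  }
  dimnames(spectra) <- NULL
  structure(
    list(wavelengths = wl, spectra = spectra, manifest = man,
         design_name = NA_character_),
    class = "lss_dataset"
  )
}

#' Extract one spectrum from a dataset as a Spectrum object
#'
#' @param dataset An `lss_dataset`.
#' @param spectrum_id A manifest spectrum id.
#' @return A [spectrum()].
#' @export
dataset_spectrum <- function(dataset, spectrum_id) {
  i <- match(spectrum_id, dataset$manifest$spectrum_id)
  if (is.na(i)) stop("unknown spectrum id: ", spectrum_id, call. = FALSE)
  row <- dataset$manifest[i, ]
  lab <- if (is.na(row$construct_label) || row$role != "tissue") NULL else
    row$construct_label
  spectrum(dataset$wavelengths, dataset$spectra[, i],
           fiber_id = row$fiber_id, construct_label = lab,
           rebuild_id = row$rebuild_id, exposure_ms = row$exposure_ms)
}

#' Pipeline configuration
#'
#' Bundles everything needed for a reproducible end-to-end run:
#' simulate -> preprocess -> train -> evaluate -> rank.
#'
#' @param study Study name (see [study_design()]).
#' @param fiber_specs Character vector of fiber specs to assess, e.g.
#'   `c("R1", "R5", "R1R5")`.
#' @param n_wavelengths Grid length of the simulation (the full instrument
#'   grid has 3587 samples; shorter grids trade spectral resolution for
#'   speed).
#' @param seed Master seed; the simulation and each training replicate
#'   derive their seeds from it.
#' @param calibrate_spectra Divide tissue spectra by a simulated
#'   reflectance-standard spectrum before training (off by default;
#'   normalized-only spectra carry the same class information).
#' @param design Optional [study_design()] override.
#' @param model Optional [tissue_optical_model()] override.
#' @param cnn Optional [cnn_config()] override (`input_length` is derived
#'   automatically from the grid and each fiber spec).
#' @param exclusion_threshold Passed to [summarize_replicates()]; default
#'   chance level.
#' @param out_dir Optional directory for the CSV/JSON report bundle.
#' @return An object of class `lss_pipeline_config`.
#' @export
pipeline_config <- function(study = "binary",
                            fiber_specs = c("R1", "R5", "R1R5"),
                            n_wavelengths = 3587L, seed = 1L,
                            calibrate_spectra = FALSE, design = NULL,
                            model = NULL, cnn = NULL,
                            exclusion_threshold = NULL, out_dir = NULL) {
  if (is.null(design)) design <- study_design(study)
  if (is.null(model)) {
    model <- tissue_optical_model(default_wavelength_grid(n_wavelengths))
  }
  lapply(fiber_specs, parse_fiber_spec)  # validates each spec
  structure(
    list(study = design$name, fiber_specs = fiber_specs,
         n_wavelengths = as.integer(n_wavelengths), seed = as.integer(seed),
         calibrate_spectra = calibrate_spectra, design = design,
         model = model, cnn = cnn,
         exclusion_threshold = exclusion_threshold, out_dir = out_dir),
    class = "lss_pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Simulates the study dataset, optionally calibrates it against a
#' simulated reflectance standard, trains replicate CNNs for every fiber
#' spec, evaluates them with the proximal-credit statistic, summarizes
#' replicates with low-accuracy exclusion, and ranks the fiber specs. All
#' stages are seeded from `config$seed`, so two runs with the same config
#' produce identical results. When `config$out_dir` is set, a report
#' bundle is written: `replicate_accuracies.csv`, `ranking.csv`,
#' `confusion_<spec>.csv` per fiber spec, and `results.json`.
#'
#' @param config An [pipeline_config()].
#' @return List with `dataset`, per-spec `summaries`, `evaluations`,
#'   `confusions` (replicate-aggregated), `ranking`, and `log` (derived
#'   seeds, early-stop epochs, exclusions).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lss_pipeline_config"))
  design <- config$design
  model <- config$model
  dataset <- simulate_study(design, model, seed = config$seed)
  if (isTRUE(config$calibrate_spectra)) {
    ref <- reference_spectrum(model, seed = config$seed + 10000L)
    ref <- mean_normalize(ref)
    dataset$spectra <- apply(dataset$spectra, 2, function(v) {
      (v / mean(v)) / ref$intensities
    })
  }
  grid_n <- length(dataset$wavelengths)
  summaries <- list()
  evaluations <- list()
  confusions <- list()
  log_rows <- list()
  for (k in seq_along(config$fiber_specs)) {
    spec <- config$fiber_specs[k]
    fibers <- parse_fiber_spec(spec)
    cfg <- if (is.null(config$cnn)) cnn_config(input_length = grid_n * length(fibers))
           else {
             tmp <- config$cnn
             tmp$input_length <- as.integer(grid_n * length(fibers))
             cnn_layer_dims(tmp)
             tmp
           }
    base_seed <- config$seed + 1000L * k
    reps <- train_replicates(dataset, design, cfg, fibers, base_seed)
    evals <- evaluate_replicates(reps, design)
    summ <- summarize_replicates(evals, n_classes = length(design$classes),
                                 exclusion_threshold = config$exclusion_threshold)
    conf <- Reduce(`+`, lapply(evals, `[[`, "confusion"))
    summaries[[spec]] <- summ
    evaluations[[spec]] <- evals
    confusions[[spec]] <- conf
    log_rows[[spec]] <- data.frame(
      fiber_spec = spec,
      replicate = seq_along(reps),
      seed = vapply(reps, `[[`, integer(1), "seed"),
      epochs = vapply(reps, function(r) as.integer(r$epochs), integer(1)),
      stopped_early = vapply(reps, `[[`, logical(1), "stopped_early"),
      accuracy = vapply(evals, `[[`, numeric(1), "accuracy"),
      excluded = seq_along(reps) %in% summ$excluded$replicate,
      stringsAsFactors = FALSE
    )
  }
  ranking <- rank_fiber_combinations(summaries)
  log <- do.call(rbind, log_rows)
  rownames(log) <- NULL
  result <- list(dataset = dataset, summaries = summaries,
                 evaluations = evaluations, confusions = confusions,
                 ranking = ranking, log = log, config = config)
  if (!is.null(config$out_dir)) write_report_bundle(result, config$out_dir)
  result
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$log,
                   file.path(out_dir, "replicate_accuracies.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$ranking),
                   file.path(out_dir, "ranking.csv"), row.names = FALSE)
  for (spec in names(result$confusions)) {
    utils::write.csv(as.data.frame(result$confusions[[spec]]),
                     file.path(out_dir, paste0("confusion_", spec, ".csv")),
                     row.names = TRUE)
  }
  json <- list(
    study = result$config$study,
    seed = result$config$seed,
    ranking = as.data.frame(result$ranking),
    pair_minus_single_gap = attr(result$ranking, "pair_minus_single_gap"),
    summaries = lapply(result$summaries, function(s) {
      list(mean = s$mean, sd = s$sd, n_used = s$n_used,
           accuracies = s$accuracies)
    })
  )
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
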