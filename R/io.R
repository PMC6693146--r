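# Formats and pipeline plumbing: mzML and JSON-lines scan I/O, feature
# matrix / label CSVs, YAML pipeline configuration, and the end-to-end
# experiment runner with a reproducibility manifest.

#' Read a centroided mzML file into a scan series
#'
#' @param path Path to an mzML file with centroid spectra.
#' @return A [scan_series()].
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  if (!file.exists(path)) stop("file not found: ", path)
  h <- tryCatch({
    f <- mzR::openMSfile(path)
    on.exit(mzR::close(f))
    list(header = mzR::header(f), peaks = mzR::peaks(f))
  }, error = function(e) stop("failed to parse mzML '", path, "': ",
                              conditionMessage(e)))
  hd <- h$header
  if (any(hd$centroided %in% FALSE))
    stop("profile-mode spectra are not supported; ",
         "supply centroided mzML data")
  pk <- h$peaks
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(pk, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("mz", "intensity")
    p
  })
  times <- if (all(is.finite(hd$retentionTime))) hd$retentionTime
           else seq_along(scans)
  pol <- if (all(hd$polarity %in% 0)) "negative" else "positive"
  rng <- c(min(50, floor(min(c(1200, unlist(lapply(scans, function(p)
    p[, "mz"])))))), 1200)
  scan_series(times, scans, polarity = pol, mz_range = rng,
              meta = list(source = path))
}

#' Write a scan series to mzML
#'
#' @param series A [scan_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(series, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("writing mzML requires the mzR package")
  n <- length(series$times)
  pol <- if (identical(series$polarity, "negative")) 0L else 1L
  hd <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = pol,
    peaksCount = vapply(series$peaks, nrow, integer(1)),
    totIonCurrent = tic(series),
    retentionTime = series$times,
    basePeakMZ = vapply(series$peaks, function(p)
      if (nrow(p)) p[which.max(p[, "intensity"]), "mz"] else 0, numeric(1)),
    basePeakIntensity = vapply(series$peaks, function(p)
      if (nrow(p)) max(p[, "intensity"]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = series$mz_range[1], highMZ = series$mz_range[2],
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(object = lapply(series$peaks, function(p) {
    m <- as.matrix(p); colnames(m) <- NULL; m
  }), file = path, header = hd)
  invisible(path)
}

#' Write scan series to a JSON-lines file
#'
#' Compact internal format: one JSON object per scan with fields
#' `pellet_id`, `time`, `mz`, `intensity`.
#'
#' @param series List of [scan_series()] (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scans_jsonl <- function(series, path) {
  if (inherits(series, "scan_series")) series <- list(series)
  con <- file(path, "w")
  on.exit(close(con))
  for (ss in series) {
    pid <- ss$meta$pellet_id %||% NA_character_
    for (i in seq_along(ss$times)) {
      p <- ss$peaks[[i]]
      writeLines(jsonlite::toJSON(list(
        pellet_id = pid, time = ss$times[i],
        mz = round(as.numeric(p[, "mz"]), 6),
        intensity = as.numeric(p[, "intensity"])
      ), auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read scan series from a JSON-lines file
#'
#' @param path Path written by [write_scans_jsonl()].
#' @return List of [scan_series()], one per pellet id.
#' @export
read_scans_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  pids <- vapply(recs, function(r) as.character(r$pellet_id), character(1))
  lapply(split(recs, factor(pids, levels = unique(pids))), function(rr) {
    times <- vapply(rr, function(r) r$time, numeric(1))
    peaks <- lapply(rr, function(r)
      cbind(mz = as.numeric(r$mz), intensity = as.numeric(r$intensity)))
    o <- order(times)
    scan_series(times[o], peaks[o],
                meta = list(pellet_id = rr[[1]]$pellet_id))
  })
}

#' Write a feature matrix (and labels) to CSV
#'
#' Bin columns are labelled at the grid's decimal precision
#' (e.g. `mz_400.1`) so CSV round-trips cannot drift.
#'
#' @param fm A [feature_matrix()].
#' @param matrix_path,labels_path Output CSV paths (labels optional).
#' @return `matrix_path`, invisibly.
#' @export
write_feature_matrix <- function(fm, matrix_path, labels_path = NULL) {
  df <- data.frame(individual_id = rownames(fm$x), fm$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, matrix_path, row.names = FALSE)
  if (!is.null(labels_path))
    utils::write.csv(fm$labels, labels_path, row.names = FALSE)
  invisible(matrix_path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param matrix_path,labels_path CSV paths; if `labels_path` is `NULL`,
#'   labels must be supplied separately.
#' @param grid The [bin_grid()] the columns live on (reconstructed from
#'   column labels when omitted).
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(matrix_path, labels_path, grid = NULL) {
  df <- utils::read.csv(matrix_path, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (is.null(grid)) {
    mzs <- as.numeric(sub("^mz_", "", colnames(x)))
    w <- stats::median(diff(mzs))
    grid <- bin_grid(mzs[1], mzs[length(mzs)], w)
  }
  labels <- labels[match(rownames(x), labels$individual_id), , drop = FALSE]
  rownames(labels) <- NULL
  feature_matrix(x, labels, grid)
}

#' Pipeline configuration
#'
#' Bundles preprocessing, classification and diagnostics parameters with
#' validation; round-trips losslessly through YAML.
#'
#' @param lockmass Lockmass reference m/z (554.26 or 325.19; default
#'   554.26).
#' @param threshold Intensity threshold in counts (default `3e5`).
#' @param mz_start,mz_end,bin_width Bin grid parameters (defaults 400,
#'   1100, 0.1).
#' @param target Label column to classify (default `"class"`).
#' @param mode Random-forest evaluation mode (default `"all_data"`).
#' @param n_trees Trees per forest (default 500).
#' @param top_k Discriminant bins to report (default 5).
#' @param r_min Isotopomer correlation threshold (default 0.9).
#' @param n_shuffles Randomisation-test shuffles (default 50; 0 disables
#'   the test).
#' @param seed Root seed for every random stage.
#' @param simulate Optional named list of [sim_config()] arguments; when
#'   present, [run_experiment()] generates its input data.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(lockmass = 554.26, threshold = 3e5,
                            mz_start = 400, mz_end = 1100, bin_width = 0.1,
                            target = "class",
                            mode = c("all_data", "split_70_30"),
                            n_trees = 500, top_k = 5, r_min = 0.9,
                            n_shuffles = 50, seed = 1L, simulate = NULL) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, bin_width > 0, mz_end > mz_start,
            n_trees >= 1, top_k >= 1, r_min > 0, r_min <= 1,
            n_shuffles >= 0)
  structure(list(lockmass = lockmass, threshold = threshold,
                 mz_start = mz_start, mz_end = mz_end,
                 bin_width = bin_width, target = target, mode = mode,
                 n_trees = as.integer(n_trees), top_k = as.integer(top_k),
                 r_min = r_min, n_shuffles = as.integer(n_shuffles),
                 seed = as.integer(seed), simulate = simulate),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a validated
#'   `pipeline_config`; `write_pipeline_config()` returns `path`
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full experiment pipeline
#'
#' Simulate (optional) -> preprocess -> classify (random forest in the
#' configured mode, plus PCA+DFA) -> diagnostics (top discriminant bins,
#' isotopomer pairs, optional randomisation test), writing a report
#' bundle and a reproducibility manifest (config hash, seeds, versions)
#' under `out_dir`.
#'
#' @param config A [pipeline_config()] whose `simulate` entry is set, or
#'   `series`/`truth` supplied directly.
#' @param series,truth Input scan series and ground truth; defaults to
#'   simulating from `config$simulate`.
#' @param out_dir Output directory, or `NULL` for no files.
#' @return List of class `experiment_bundle`: `fm`, `rf`, `lda`,
#'   `importance`, `pairs`, `randomisation` (or `NULL`), `manifest`.
#' @export
run_experiment <- function(config, series = NULL, truth = NULL,
                           out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(series)) {
      if (is.null(config$simulate))
        stop("no input data and no simulate section in the config")
      sc <- do.call(sim_config, config$simulate)
      sim <- simulate_dataset(sc)
      series <- sim$series
      truth <- sim$truth
    }
    stage <- "preprocess"
    grid <- bin_grid(config$mz_start, config$mz_end, config$bin_width)
    fm <- preprocess_dataset(series, truth, grid,
                             lockmass = config$lockmass,
                             threshold = config$threshold)
    stage <- "classify"
    rf <- rf_fit_evaluate(fm, config$target, config$mode,
                          seed = config$seed, n_trees = config$n_trees)
    lda <- pca_lda(fm, config$target,
                   n_components = min(12L, nrow(fm$x) - 1L))
    stage <- "diagnostics"
    imp <- top_discriminant_bins(rf, k = config$top_k,
                                 r_min = config$r_min)
    pairs <- isotopomer_pairs(fm, r_min = config$r_min)
    rnd <- if (config$n_shuffles > 0)
      randomisation_test(fm, config$target, config$n_shuffles,
                         seed = config$seed)
    else NULL
    list(fm = fm, rf = rf, lda = lda, importance = imp, pairs = pairs,
         randomisation = rnd)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("reimsfp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(config),
    n_samples = nrow(result$fm$x),
    n_bins = ncol(result$fm$x))
  result$manifest <- manifest
  class(result) <- "experiment_bundle"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_matrix(result$fm, file.path(out_dir, "matrix.csv"),
                         file.path(out_dir, "labels.csv"))
    utils::write.csv(as.data.frame(result$rf$report$confusion),
                     file.path(out_dir, "confusion.csv"))
    jsonlite::write_json(report_as_list(result$rf$report),
                         file.path(out_dir, "classification_report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(result$importance$top,
                     file.path(out_dir, "importance_top.csv"),
                     row.names = FALSE)
    utils::write.csv(result$pairs[result$pairs$verdict != "unrelated", ],
                     file.path(out_dir, "isotopomer_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(ld1 = result$lda$scores[, 1],
                                ld2 = if (ncol(result$lda$scores) > 1)
                                  result$lda$scores[, 2] else 0,
                                class = result$lda$truth),
                     file.path(out_dir, "dfa_scores.csv"),
                     row.names = FALSE)
    if (!is.null(result$randomisation))
      jsonlite::write_json(
        unclass(result$randomisation),
        file.path(out_dir, "randomisation.json"),
        auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

report_as_list <- function(report) {
  list(confusion = apply(report$confusion, 1, as.list),
       per_class_accuracy = as.list(report$per_class_accuracy),
       overall_accuracy = report$overall_accuracy,
       mode = report$mode, seed = report$seed, n = report$n)
}

# md5 of the canonical YAML rendering of the config
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}
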