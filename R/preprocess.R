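# Spectral preprocessing: burn-event detection, thresholded aggregation,
# single-point lockmass recalibration, fixed-grid binning, total-ion
# normalisation and per-individual averaging. Re-implements the vendor
# (LiveID / Offline Model Builder) processing chain in the open.

#' Fixed m/z bin grid
#'
#' Inclusive grid of points at `mz_start + k * width`,
#' k = 0 ... n_points - 1, with `n_points = round((end - start) / width) + 1`.
#' The standard 400-1100 m/z window gives 7001 points at 0.1 Da and
#' 14001 points at 0.05 Da.
#'
#' @param mz_start,mz_end Window bounds in Da (defaults 400 and 1100).
#' @param width Bin width in Da, typically 0.1 or 0.05.
#' @return Object of class `bin_grid` with fields `mz_start`, `mz_end`,
#'   `width`, `n_points` and `centers`.
#' @export
bin_grid <- function(mz_start = 400, mz_end = 1100, width = 0.1) {
  stopifnot(mz_end > mz_start, width > 0)
  n <- round((mz_end - mz_start) / width) + 1L
  structure(list(mz_start = mz_start, mz_end = mz_end, width = width,
                 n_points = as.integer(n),
                 centers = mz_start + (seq_len(n) - 1L) * width),
            class = "bin_grid")
}

#' @export
format.bin_grid <- function(x, ...) {
  sprintf("bin_grid [%g, %g] Da @ %g Da (%d points)",
          x$mz_start, x$mz_end, x$width, x$n_points)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Detect burn events in a scan series
#'
#' A burn event is a maximal run of scans whose total ion current exceeds
#' the detection threshold `median(TIC) + baseline_fraction * (max(TIC) -
#' median(TIC))`. Anchoring the threshold at the median TIC makes
#' detection robust to the constant ion current contributed by the
#' continuously infused lockmass reference; with a zero baseline it
#' reduces to a plain fraction-of-maximum cut. Runs separated by fewer
#' than `hysteresis` below-threshold scans are merged, so a single-scan
#' dip inside a burn does not split the event.
#'
#' @param series A [scan_series()].
#' @param baseline_fraction Threshold as a fraction of the maximum TIC
#'   (default 0.1).
#' @param hysteresis Minimum number of consecutive below-threshold scans
#'   required to end an event (default 2).
#' @return List of `burn_event` objects with fields `start_index`,
#'   `end_index`, `peak_index`, `tic_peak`. All-zero TIC gives an empty
#'   list.
#' @export
detect_burn_events <- function(series, baseline_fraction = 0.1,
                               hysteresis = 2L) {
  if (!inherits(series, "scan_series")) stop("series must be a scan_series")
  if (length(series$times) == 0) stop("series is empty")
  tics <- tic(series)
  if (max(tics) <= 0) return(list())
  med <- stats::median(tics)
  thr <- med + baseline_fraction * (max(tics) - med)
  above <- tics > thr
  if (!any(above)) return(list())
  r <- rle(above)
  # merge short below-threshold gaps between above-threshold runs
  if (length(r$lengths) > 2) {
    inner <- seq(2L, length(r$lengths) - 1L)
    gaps <- inner[!r$values[inner] & r$lengths[inner] < hysteresis]
    r$values[gaps] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    pk <- i0 - 1L + which.max(tics[i0:i1])
    structure(list(start_index = i0, end_index = i1, peak_index = pk,
                   tic_peak = tics[pk]),
              class = "burn_event")
  })
}

#' Aggregate a burn event into one peak list
#'
#' Applies the instrument intensity threshold per scan, then sums surviving
#' centroids per m/z value over the member scans of the event: the vendor
#' software's "spectral data above the intensity threshold summed for each
#' data point". Sub-threshold centroids are discarded before summation.
#'
#' @param series A [scan_series()].
#' @param event A `burn_event` from [detect_burn_events()], or `NULL` to
#'   aggregate over all scans.
#' @param threshold Intensity threshold in counts (default `3e5`).
#' @return Two-column matrix (`mz`, `intensity`) sorted by m/z; may have
#'   zero rows.
#' @export
aggregate_burn <- function(series, event = NULL, threshold = 3e5) {
  if (!inherits(series, "scan_series")) stop("series must be a scan_series")
  idx <- if (is.null(event)) seq_along(series$peaks)
         else seq.int(event$start_index, event$end_index)
  if (length(idx) < 1) stop("event must contain at least one scan")
  kept <- lapply(series$peaks[idx], function(p) {
    p[p[, "intensity"] > threshold, , drop = FALSE]
  })
  all <- do.call(rbind, kept)
  if (is.null(all) || nrow(all) == 0)
    return(cbind(mz = numeric(0), intensity = numeric(0)))
  agg <- rowsum(all[, "intensity"], group = all[, "mz"])
  mz <- as.numeric(rownames(agg))
  o <- order(mz)
  cbind(mz = mz[o], intensity = as.numeric(agg)[o])
}

#' Single-point lockmass correction
#'
#' Rescales the m/z axis so the observed reference ion (the strongest peak
#' within `search_window` of `reference`) lands exactly on the reference
#' m/z: all m/z are multiplied by `reference / observed`. A multiplicative
#' (gain) model is used because time-of-flight mass error scales with m/z.
#' Typical references are leu-enkephalin \[M-H\]- at 554.26 or the
#' propan-2-ol background ion at 325.19.
#'
#' @param peaks Two-column matrix (`mz`, `intensity`).
#' @param reference Reference m/z (default 554.26).
#' @param search_window Half-width of the search window in Da
#'   (default 0.25).
#' @return The corrected peak matrix. If no peak falls in the window the
#'   input is returned unchanged with attribute `uncorrectable = TRUE` and
#'   a warning.
#' @export
lockmass_correct <- function(peaks, reference = 554.26,
                             search_window = 0.25) {
  if (nrow(peaks) == 0) {
    warning("empty peak list: lockmass reference not found; ",
            "spectrum left uncorrected")
    attr(peaks, "uncorrectable") <- TRUE
    return(peaks)
  }
  inwin <- which(abs(peaks[, "mz"] - reference) <= search_window)
  if (length(inwin) == 0) {
    warning(sprintf(
      "no peak within %.3g Da of lockmass %.4f; spectrum left uncorrected",
      search_window, reference))
    attr(peaks, "uncorrectable") <- TRUE
    return(peaks)
  }
  obs <- peaks[inwin[which.max(peaks[inwin, "intensity"])], "mz"]
  out <- peaks
  out[, "mz"] <- out[, "mz"] * (reference / obs)
  attr(out, "lockmass_used") <- reference
  out
}

#' Bin a peak list onto a fixed grid
#'
#' Each centroid's intensity is added to the nearest grid point, with ties
#' (a centroid exactly halfway between two points) assigned to the lower
#' point. Centroids outside `[mz_start - width/2, mz_end + width/2)` are
#' discarded.
#'
#' @param peaks Two-column matrix (`mz`, `intensity`).
#' @param grid A [bin_grid()].
#' @return Object of class `binned_spectrum`: list with `grid`, `values`
#'   (length `grid$n_points`), `normalised` flag, and provenance fields.
#' @export
bin_spectrum <- function(peaks, grid) {
  if (!inherits(grid, "bin_grid")) stop("grid must be a bin_grid")
  values <- numeric(grid$n_points)
  if (nrow(peaks) > 0) {
    u <- (peaks[, "mz"] - grid$mz_start) / grid$width
    idx <- ceiling(u - 0.5)              # nearest point, ties to lower
    keep <- u >= -0.5 & u < grid$n_points - 0.5
    idx <- pmax(idx[keep], 0L) + 1L      # left edge belongs to bin 1
    if (length(idx) > 0) {
      acc <- rowsum(peaks[keep, "intensity"], group = idx)
      values[as.integer(rownames(acc))] <- as.numeric(acc)
    }
  }
  structure(list(grid = grid, values = values, normalised = FALSE,
                 provenance = character(0),
                 lockmass_used = attr(peaks, "lockmass_used")),
            class = "binned_spectrum")
}

#' Total-ion normalisation of a binned spectrum
#'
#' Scales the vector to unit sum (TIC normalisation), the stand-in for the
#' vendor software's undocumented normalise/scale step. Any per-bin
#' standardisation happens later at feature-matrix level.
#'
#' @param binned A `binned_spectrum`.
#' @param total Target sum (default 1).
#' @return The normalised `binned_spectrum`.
#' @export
normalise_spectrum <- function(binned, total = 1) {
  if (!inherits(binned, "binned_spectrum"))
    stop("binned must be a binned_spectrum")
  s <- sum(binned$values)
  if (s <= 0)
    stop("cannot normalise an all-zero spectrum (no signal in the window)")
  binned$values <- binned$values / s * total
  binned$normalised <- TRUE
  binned
}

#' Average the binned spectra of one individual's pellets
#'
#' Arithmetic per-bin mean over pellet spectra on a common grid; the
#' typical protocol averages three or four pellet burns per individual
#' before any multivariate analysis.
#'
#' @param spectra List of `binned_spectrum` objects on identical grids.
#' @return A `binned_spectrum` whose provenance records the contributing
#'   pellets.
#' @export
average_individual <- function(spectra) {
  if (length(spectra) < 1) stop("at least one spectrum is required")
  g <- spectra[[1]]$grid
  for (sp in spectra) {
    if (!inherits(sp, "binned_spectrum"))
      stop("all elements must be binned_spectrum objects")
    if (!identical(unclass(sp$grid)[c("mz_start", "mz_end", "width")],
                   unclass(g)[c("mz_start", "mz_end", "width")]))
      stop("cannot average spectra on different grids")
  }
  vals <- rowMeans(vapply(spectra, `[[`, numeric(g$n_points), "values"))
  structure(list(grid = g, values = vals,
                 normalised = all(vapply(spectra, `[[`, logical(1),
                                         "normalised")),
                 provenance = unlist(lapply(spectra, `[[`, "provenance")),
                 lockmass_used = spectra[[1]]$lockmass_used),
            class = "binned_spectrum")
}

#' Preprocess simulated or imported scan series into a feature matrix
#'
#' Runs the full chain per pellet — burn detection, thresholded
#' aggregation, lockmass correction, binning, TIC normalisation — then
#' averages pellets per individual and assembles the samples-by-bins
#' feature matrix with labels.
#'
#' @param series List of [scan_series()], one per pellet.
#' @param truth Ground-truth data.frame with columns `sample_id`,
#'   `individual_id`, `class` (plus covariates), one row per pellet, in
#'   the same order as `series`.
#' @param grid A [bin_grid()].
#' @param lockmass Reference m/z, or `NA` to skip correction
#'   (default 554.26).
#' @param lockmass_window Search half-width in Da (default 0.25).
#' @param threshold Intensity threshold in counts (default `3e5`).
#' @param baseline_fraction Burn-detection threshold fraction
#'   (default 0.1).
#' @param normalise TIC-normalise each pellet spectrum (default `TRUE`).
#' @return A [feature_matrix()]: rows are individuals, columns m/z bins.
#' @export
preprocess_dataset <- function(series, truth, grid = bin_grid(),
                               lockmass = 554.26, lockmass_window = 0.25,
                               threshold = 3e5, baseline_fraction = 0.1,
                               normalise = TRUE) {
  stopifnot(length(series) == nrow(truth))
  pellet_spectra <- vector("list", length(series))
  for (i in seq_along(series)) {
    ev <- detect_burn_events(series[[i]], baseline_fraction)
    pk <- if (length(ev) == 0) {
      cbind(mz = numeric(0), intensity = numeric(0))
    } else {
      # a series may hold several burns (several pellets in sequence);
      # sum their aggregated peak lists
      agg <- lapply(ev, function(e) aggregate_burn(series[[i]], e, threshold))
      if (length(agg) == 1) agg[[1]] else {
        all <- do.call(rbind, agg)
        acc <- rowsum(all[, "intensity"], group = all[, "mz"])
        mz <- as.numeric(rownames(acc))
        o <- order(mz)
        cbind(mz = mz[o], intensity = as.numeric(acc)[o])
      }
    }
    if (!is.na(lockmass) && nrow(pk) > 0)
      pk <- lockmass_correct(pk, lockmass, lockmass_window)
    sp <- bin_spectrum(pk, grid)
    sp$provenance <- truth$sample_id[i]
    if (normalise && sum(sp$values) > 0) sp <- normalise_spectrum(sp)
    pellet_spectra[[i]] <- sp
  }
  inds <- unique(truth$individual_id)
  rows <- matrix(0, nrow = length(inds), ncol = grid$n_points,
                 dimnames = list(inds, format_bin_labels(grid)))
  for (j in seq_along(inds)) {
    sel <- which(truth$individual_id == inds[j])
    rows[j, ] <- average_individual(pellet_spectra[sel])$values
  }
  lab_cols <- setdiff(names(truth), c("sample_id", "pellet", "drift"))
  labels <- unique(truth[lab_cols])
  labels <- labels[match(inds, labels$individual_id), , drop = FALSE]
  rownames(labels) <- NULL
  feature_matrix(rows, labels, grid)
}

#' Feature matrix container
#'
#' Samples-by-bins matrix of normalised intensities plus per-sample labels
#' and the bin grid.
#'
#' @param x Numeric matrix, rows = samples (rownames = sample ids).
#' @param labels data.frame with column `individual_id` matching rownames
#'   of `x`, a `class` column, and any covariates.
#' @param grid The [bin_grid()] the columns live on.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels, grid) {
  stopifnot(is.matrix(x), nrow(x) == nrow(labels))
  if (any(!is.finite(x))) stop("feature matrix must have no missing values")
  if (!"individual_id" %in% names(labels))
    stop("labels must contain an individual_id column")
  if (!identical(as.character(labels$individual_id), rownames(x)))
    stop("labels must align with matrix rows")
  structure(list(x = x, labels = labels, grid = grid),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d bins (%s)\n",
              nrow(x$x), ncol(x$x), format(x$grid)))
  cat("labels:", paste(setdiff(names(x$labels), "individual_id"),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Subset a feature matrix by sample
#' @param fm A `feature_matrix`.
#' @param i Row (sample) indices or logical mask.
#' @return The subsetted `feature_matrix`.
#' @export
fm_subset <- function(fm, i) {
  feature_matrix(fm$x[i, , drop = FALSE],
                 fm$labels[i, , drop = FALSE], fm$grid)
}

format_bin_labels <- function(grid) {
  dec <- max(0L, ceiling(-log10(grid$width)))
  sprintf(paste0("mz_%.", dec, "f"), grid$centers)
}

same_grid <- function(a, b) {
  identical(unclass(a)[c("mz_start", "mz_end", "width")],
            unclass(b)[c("mz_start", "mz_end", "width")])
}
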