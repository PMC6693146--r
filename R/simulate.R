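# Synthetic REIMS scan-series generator.
#
# Emulates negative-ion acquisitions at 1 scan/s over 50-1200 m/z: each
# faecal-pellet burn is a 2-5 s burst of ion current carrying a lipid-like
# peak profile (concentrated at 600-900 m/z), with monoisotopic + first-13C
# isotopomer centroid pairs, log-normal individual- and pellet-level
# variation, covariate effects, additive chemical noise and run-level m/z
# calibration drift.

# 13C - 12C mass difference (Da) and natural 13C abundance.
C13_SPACING <- 1.00336
C13_ABUNDANCE <- 0.0107

#' Define a simulated peak template
#'
#' A template describes one molecular species: a monoisotopic centroid plus
#' its first \eqn{^{13}}C isotopomer at +1.00336 Da with intensity ratio
#' \eqn{0.0107 \times} `carbon_count` (binomial single-substitution
#' approximation at natural abundance).
#'
#' @param mz_mono Monoisotopic m/z in Da; must lie in the instrument range
#'   \[50, 1200\].
#' @param mean_log_intensity Mean natural-log intensity (log counts) of the
#'   monoisotopic centroid aggregated over one burn.
#' @param carbon_count Integer carbon count (>= 1); sets the isotopomer
#'   intensity ratio.
#' @param class_effects Named numeric vector of multiplicative intensity
#'   factors per class label (>= 0). Unlisted classes get factor 1.
#' @param covariate_effects Named numeric vector of multiplicative factors
#'   keyed by covariate level (e.g. `c(F = 1.5)`); unlisted levels get 1.
#' @param coregulation_group Optional integer; templates sharing a group id
#'   share their individual- and pellet-level random effects, emulating
#'   co-regulated molecular species (used to plant correlated,
#'   non-isotopic ion pairs).
#' @return An object of class `peak_template`.
#' @export
peak_template <- function(mz_mono, mean_log_intensity, carbon_count,
                          class_effects = NULL, covariate_effects = NULL,
                          coregulation_group = NA_integer_) {
  stopifnot(is.numeric(mz_mono), length(mz_mono) == 1L)
  if (mz_mono < 50 || mz_mono > 1200)
    stop("mz_mono must lie within the instrument range [50, 1200] Da")
  if (!is.numeric(carbon_count) || carbon_count < 1 ||
      carbon_count != round(carbon_count))
    stop("carbon_count must be an integer >= 1")
  check_factors <- function(x, what) {
    if (is.null(x)) return(numeric(0))
    x <- unlist(x)
    if (is.null(names(x)) || any(!is.finite(x)) || any(x < 0))
      stop(what, " must be a named vector of finite non-negative factors")
    x
  }
  structure(list(
    mz_mono = mz_mono,
    mean_log_intensity = mean_log_intensity,
    carbon_count = as.integer(carbon_count),
    class_effects = check_factors(class_effects, "class_effects"),
    covariate_effects = check_factors(covariate_effects, "covariate_effects"),
    coregulation_group = as.integer(coregulation_group)
  ), class = "peak_template")
}

#' Build a lipid-like peak profile
#'
#' Generates a reproducible set of peak templates emulating the faecal REIMS
#' fingerprint: most peaks drawn in the phospholipid-dominated 600-900 m/z
#' region, the rest in 400-600 m/z, with log-intensities spanning roughly a
#' decade and carbon counts typical of glycerophospholipids. A subset of
#' peaks carries class-specific multiplicative effects, assigned round-robin
#' across classes.
#'
#' @param classes Character vector of class labels.
#' @param n_peaks Total number of templates (default 60).
#' @param n_discriminant Number of class-affected templates (default 20).
#' @param effect_size Multiplicative intensity factor applied to the
#'   affected class for each discriminant peak (default 4).
#' @param sex_effect Multiplicative factor applied to females on a few
#'   peaks (default 1.5; set to 1 to disable).
#' @param seed Integer seed controlling template placement.
#' @return List of [peak_template()] objects. Discriminant templates are
#'   marked with attribute `"discriminant_class"`.
#' @export
lipid_peak_profile <- function(classes, n_peaks = 60, n_discriminant = 20,
                               effect_size = 4, sex_effect = 1.5, seed = 1L) {
  stopifnot(length(classes) >= 1, n_peaks >= 1, n_discriminant <= n_peaks)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  n_hi <- round(0.75 * n_peaks)                  # 600-900 m/z lipid region
  mz <- c(runif(n_hi, 600, 900), runif(n_peaks - n_hi, 400, 600))
  # keep the lockmass windows (leu-enkephalin 554.26, propan-2-ol 325.19)
  # free of analyte monoisotopic or isotopomer centroids
  mz <- ifelse(abs(mz - 554.26) < 1.6, mz + 3.2, mz)
  mz <- ifelse(abs(mz - 325.19) < 1.6, mz + 3.2, mz)
  # keep mono and isotope centroids of different templates well separated
  # (> 2 bins at 0.1 Da) so planted bins don't collide on the grid
  mz <- sort(mz)
  iter <- 0L
  while (any(diff(mz) < 2.5) && (iter <- iter + 1L) < 100L) {
    bad <- which(diff(mz) < 2.5) + 1L
    mz[bad] <- mz[bad] + 2.5
    mz <- sort(pmin(mz, 1100))
  }
  mz <- round(mz, 2)
  logi <- rnorm(n_peaks, mean = log(5e6), sd = 0.8)
  carbons <- sample(30:50, n_peaks, replace = TRUE)
  disc <- if (n_discriminant > 0) sample(n_peaks, n_discriminant) else integer(0)
  sexy <- sample(setdiff(seq_len(n_peaks), disc),
                 min(6L, n_peaks - n_discriminant))
  out <- vector("list", n_peaks)
  for (i in seq_len(n_peaks)) {
    ce <- NULL
    dc <- NA_character_
    if (i %in% disc) {
      dc <- classes[(match(i, disc) - 1L) %% length(classes) + 1L]
      ce <- stats::setNames(effect_size, dc)
    }
    cov_e <- if (i %in% sexy && sex_effect != 1) c(F = sex_effect) else NULL
    tpl <- peak_template(mz[i], logi[i], carbons[i],
                         class_effects = ce, covariate_effects = cov_e)
    attr(tpl, "discriminant_class") <- dc
    out[[i]] <- tpl
  }
  out
}

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic REIMS dataset generator.
#'
#' @param classes Character vector of class labels (>= 1).
#' @param n_individuals_per_class Individuals per class (>= 1).
#' @param pellets_per_individual Pellets burned per individual (default 3,
#'   matching the typical three-to-four-pellet protocol).
#' @param peaks List of [peak_template()] objects; defaults to
#'   [lipid_peak_profile()] over `classes`.
#' @param individual_sd SD of the per-individual, per-peak log-intensity
#'   random effect (default 0.4).
#' @param pellet_sd SD of the per-pellet, per-peak log-intensity random
#'   effect (default 0.2).
#' @param noise_floor Mean intensity (counts) of additive chemical-noise
#'   centroids scattered across every scan (default 2e4; 0 disables noise).
#' @param calibration_drift Half-width (Da) of the uniform per-run additive
#'   m/z calibration offset; each pellet burn is one acquisition run.
#'   Default 0.02, bounded at 0.05.
#' @param burn_duration_s Burn length in seconds, within \[1, 10\]
#'   (default 4; protocol range 2-5 s).
#' @param scan_rate_hz Scan rate (default 1 scan/s).
#' @param covariates Named list of covariate level vectors assigned to
#'   individuals (default `list(sex = c("F", "M"))`).
#' @param lockmass_mz m/z of the continuously infused lockmass reference
#'   ion present in every scan (default 554.26, leu-enkephalin \[M-H\]-;
#'   `NA` disables it).
#' @param lockmass_intensity Per-scan intensity of the reference ion
#'   (default 2e6 counts, comfortably above the 3e5 instrument threshold).
#' @param seed Integer seed; mandatory. Identical seeds give bit-identical
#'   datasets.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(classes, n_individuals_per_class,
                       pellets_per_individual = 3L,
                       peaks = lipid_peak_profile(classes),
                       individual_sd = 0.4, pellet_sd = 0.2,
                       noise_floor = 2e4, calibration_drift = 0.02,
                       burn_duration_s = 4, scan_rate_hz = 1,
                       covariates = list(sex = c("F", "M")),
                       lockmass_mz = 554.26, lockmass_intensity = 2e6,
                       seed) {
  if (length(classes) < 1) stop("classes must contain at least one label")
  if (length(peaks) < 1) stop("at least one peak template is required")
  if (n_individuals_per_class < 1 || pellets_per_individual < 1)
    stop("counts must be >= 1")
  if (individual_sd < 0 || pellet_sd < 0) stop("SDs must be >= 0")
  if (noise_floor < 0) stop("noise_floor must be >= 0")
  if (burn_duration_s < 1 || burn_duration_s > 10)
    stop("burn_duration_s must lie within [1, 10] s")
  if (abs(calibration_drift) > 0.05)
    stop("calibration_drift bound must not exceed 0.05 Da")
  if (missing(seed)) stop("seed is mandatory")
  structure(list(
    classes = as.character(classes),
    n_individuals_per_class = as.integer(n_individuals_per_class),
    pellets_per_individual = as.integer(pellets_per_individual),
    peaks = peaks,
    individual_sd = individual_sd, pellet_sd = pellet_sd,
    noise_floor = noise_floor, calibration_drift = calibration_drift,
    burn_duration_s = burn_duration_s, scan_rate_hz = scan_rate_hz,
    covariates = covariates, lockmass_mz = lockmass_mz,
    lockmass_intensity = lockmass_intensity, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Construct a scan series
#'
#' Time-ordered centroided scans from one acquisition (here: one pellet
#' burn embedded in baseline scans).
#'
#' @param times Numeric vector of scan times (s), strictly increasing.
#' @param peaks List (one element per scan) of two-column matrices with
#'   columns `mz` and `intensity`.
#' @param polarity Ion polarity; only `"negative"` is modelled.
#' @param mz_range Acquisition m/z range (default `c(50, 1200)`).
#' @param meta Optional named list of provenance fields (pellet id, drift).
#' @return Object of class `scan_series`.
#' @export
scan_series <- function(times, peaks, polarity = "negative",
                        mz_range = c(50, 1200), meta = list()) {
  stopifnot(length(times) == length(peaks))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("scan times must be strictly increasing")
  for (p in peaks) {
    if (nrow(p) == 0) next
    if (any(p[, "intensity"] < 0)) stop("intensities must be >= 0")
    if (any(p[, "mz"] < mz_range[1] | p[, "mz"] > mz_range[2]))
      stop("m/z values must lie within the acquisition range")
  }
  structure(list(times = times, peaks = peaks, polarity = polarity,
                 mz_range = mz_range, meta = meta),
            class = "scan_series")
}

#' Total ion current of a scan series
#' @param series A `scan_series`.
#' @return Numeric vector, one TIC value per scan.
#' @export
tic <- function(series) {
  vapply(series$peaks, function(p) sum(p[, "intensity"]), numeric(1))
}

#' Simulate a REIMS dataset
#'
#' Generates one scan series per pellet plus a ground-truth table. Each
#' burn is a truncated-Gaussian burst of total ion current embedded in
#' near-zero baseline scans; every template emits a monoisotopic centroid
#' at `mz_mono + drift` and a first-isotopomer centroid at
#' `mz_mono + 1.00336 + drift` with intensity ratio
#' `0.0107 * carbon_count`. Per-individual and per-pellet log-normal
#' multipliers are applied per peak (shared within a coregulation group),
#' and chemical-noise centroids are scattered over every scan.
#'
#' @param config A [sim_config()].
#' @return List with elements `series` (list of [scan_series()], one per
#'   pellet) and `truth` (data.frame: sample_id, individual_id, class,
#'   pellet, covariates, drift).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  rs <- local_rng(config$seed)
  on.exit(restore_rng(rs))

  cls <- config$classes
  n_ind <- config$n_individuals_per_class
  n_pel <- config$pellets_per_individual
  tpl <- config$peaks
  n_tpl <- length(tpl)
  groups <- vapply(tpl, function(t) t$coregulation_group, integer(1))
  # random-effect slots: one per coregulation group, one per ungrouped peak
  slot <- ifelse(is.na(groups),
                 seq_len(n_tpl) + max(0L, groups, na.rm = TRUE),
                 groups)
  slot <- match(slot, unique(slot))
  n_slot <- max(slot)

  mz_mono <- vapply(tpl, function(t) t$mz_mono, numeric(1))
  base_log <- vapply(tpl, function(t) t$mean_log_intensity, numeric(1))
  iso_ratio <- C13_ABUNDANCE *
    vapply(tpl, function(t) t$carbon_count, numeric(1))

  class_log <- function(t, cl) {
    f <- t$class_effects[cl]
    if (is.na(f)) 0 else log(f)
  }
  cov_log <- function(t, levels) {
    f <- t$covariate_effects[levels]
    sum(log(f[!is.na(f)]))
  }

  series <- list()
  truth <- list()
  idx <- 0L
  for (ci in seq_along(cls)) {
    for (ii in seq_len(n_ind)) {
      ind_id <- sprintf("%s_%02d", cls[ci], ii)
      cov_levels <- vapply(config$covariates, function(lv) {
        lv[(ii - 1L) %% length(lv) + 1L]
      }, character(1))
      eta_ind <- stats::rnorm(n_slot, 0, config$individual_sd)
      fixed_log <- base_log +
        vapply(tpl, class_log, numeric(1), cl = cls[ci]) +
        vapply(tpl, cov_log, numeric(1), levels = cov_levels)
      for (pi in seq_len(n_pel)) {
        idx <- idx + 1L
        eta_pel <- stats::rnorm(n_slot, 0, config$pellet_sd)
        drift <- if (config$calibration_drift == 0) 0 else
          stats::runif(1, -config$calibration_drift, config$calibration_drift)
        amp <- exp(fixed_log + eta_ind[slot] + eta_pel[slot])
        pid <- sprintf("%s_p%d", ind_id, pi)
        series[[idx]] <- simulate_burn_series(
          mz_mono + drift, amp, iso_ratio, config, pellet_id = pid,
          drift = drift)
        truth[[idx]] <- data.frame(
          sample_id = pid, individual_id = ind_id, class = cls[ci],
          pellet = pi, t(cov_levels), drift = drift,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(series = series, truth = truth)
}

# One pellet: baseline scans, a truncated-Gaussian burst over the burn
# window (per-scan weights sum to 1 so the aggregated burn recovers the
# pellet amplitudes), then trailing baseline scans.
simulate_burn_series <- function(mz, amp, iso_ratio, config, pellet_id,
                                 drift) {
  dt <- 1 / config$scan_rate_hz
  n_burn <- max(1L, round(config$burn_duration_s * config$scan_rate_hz))
  n_base <- 5L
  n_scan <- n_base + n_burn + n_base
  times <- seq_len(n_scan) * dt
  # truncated Gaussian TIC profile across the burn window
  u <- seq(-1.5, 1.5, length.out = n_burn)
  w <- exp(-u^2 / 2)
  w <- w / sum(w)
  burn_idx <- n_base + seq_len(n_burn)

  mz_all <- c(mz, mz + C13_SPACING)
  amp_all <- c(amp, amp * iso_ratio)
  keep <- mz_all >= 50 & mz_all <= 1200
  mz_all <- mz_all[keep]
  amp_all <- amp_all[keep]
  o <- order(mz_all)
  mz_all <- mz_all[o]
  amp_all <- amp_all[o]

  # the lockmass reference ion is infused continuously: present in every
  # scan at constant intensity, subject to the same run-level drift
  lock <- if (!is.na(config$lockmass_mz)) {
    cbind(mz = config$lockmass_mz + drift,
          intensity = config$lockmass_intensity)
  } else {
    cbind(mz = numeric(0), intensity = numeric(0))
  }
  scans <- vector("list", n_scan)
  for (s in seq_len(n_scan)) {
    b <- match(s, burn_idx)
    signal <- if (!is.na(b)) {
      cbind(mz = mz_all, intensity = amp_all * w[b])
    } else {
      cbind(mz = numeric(0), intensity = numeric(0))
    }
    noise <- simulate_noise_scan(config$noise_floor)
    p <- rbind(signal, lock, noise)
    scans[[s]] <- p[order(p[, "mz"]), , drop = FALSE]
  }
  scan_series(times, scans,
              meta = list(pellet_id = pellet_id, drift = drift))
}

simulate_noise_scan <- function(noise_floor) {
  if (noise_floor <= 0) return(cbind(mz = numeric(0), intensity = numeric(0)))
  n <- stats::rpois(1, 30)
  if (n == 0) return(cbind(mz = numeric(0), intensity = numeric(0)))
  cbind(mz = stats::runif(n, 50, 1200),
        intensity = stats::rexp(n, 1 / noise_floor))
}

# Seed scoping: isolate the generator's RNG stream from the caller's.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
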