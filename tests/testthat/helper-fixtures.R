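# Shared fixture builders. Tests that only exercise mechanics use a small
# two-class profile on a narrow grid to stay fast; planted-signal tests
# state their own conditions.

# deterministic hand-built peak list
peaklist <- function(mz, intensity) cbind(mz = mz, intensity = intensity)

# a minimal two-class simulation with a handful of peaks
small_profile <- function(classes = c("A", "B"), effect = 4) {
  list(
    peak_template(620.00, log(5e6), 40),
    peak_template(655.30, log(4e6), 36),
    peak_template(701.10, log(6e6), 44),
    peak_template(733.40, log(5e6), 38,
                  class_effects = stats::setNames(effect, classes[1])),
    peak_template(810.20, log(4e6), 42,
                  class_effects = stats::setNames(effect, classes[2]))
  )
}

small_config <- function(seed, classes = c("A", "B"), n_ind = 6,
                         pellets = 2, effect = 4, ...) {
  sim_config(classes, n_ind, pellets,
             peaks = small_profile(classes, effect), seed = seed, ...)
}

small_matrix <- function(seed = 1, threshold = 3e5, drift = 0.02, ...) {
  cfg <- small_config(seed, calibration_drift = drift, ...)
  sim <- simulate_dataset(cfg)
  preprocess_dataset(sim$series, sim$truth, threshold = threshold)
}

# a synthetic scan series with hand-placed TIC bursts, for burn detection
burst_series <- function(tic_profile, mz = 600) {
  peaks <- lapply(tic_profile, function(v) {
    if (v <= 0) cbind(mz = numeric(0), intensity = numeric(0))
    else cbind(mz = mz, intensity = v)
  })
  scan_series(seq_along(tic_profile), peaks)
}

# brute-force burn finder: contiguous runs of scans above the
# median-anchored threshold (independent oracle for detect_burn_events,
# no hysteresis cases)
brute_burns <- function(tics, frac = 0.1) {
  above <- tics > median(tics) + frac * (max(tics) - median(tics))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}
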