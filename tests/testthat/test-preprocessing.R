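test_that("burn detection finds each TIC burst once and only once", {
  # no signal at all: zero events, not an error
  empty <- burst_series(rep(0, 30))
  expect_identical(detect_burn_events(empty), list())

  # three well-separated Gaussian bursts
  g <- function(center, h) h * exp(-(seq_len(60) - center)^2 / 2)
  tics <- g(10, 1e6) + g(30, 8e5) + g(50, 1.2e6)
  tics[tics < 1] <- 0
  s <- burst_series(tics)
  ev <- detect_burn_events(s)
  expect_length(ev, 3)
  expect_equal(vapply(ev, `[[`, numeric(1), "peak_index"), c(10, 30, 50))
  # oracle: brute-force threshold scan
  oracle <- brute_burns(tic(s))
  expect_equal(vapply(ev, `[[`, numeric(1), "start_index"), oracle$start)
  expect_equal(vapply(ev, `[[`, numeric(1), "end_index"), oracle$end)

  # events are disjoint and ordered
  bounds <- unlist(lapply(ev, function(e) c(e$start_index, e$end_index)))
  expect_true(all(diff(bounds) >= 0))

  # a one-scan dip inside a burn does not split the event
  dip <- c(0, 0, 5e5, 6e5, 1e4, 6e5, 5e5, 0, 0)
  expect_length(detect_burn_events(burst_series(dip)), 1)

  expect_error(scan_series(c(1, 1), list(peaklist(600, 1), peaklist(600, 1))),
               "strictly increasing")
})

test_that("aggregation thresholds per scan, then sums per m/z", {
  s <- scan_series(1:2, list(peaklist(c(500, 600), c(4e5, 1e5)),
                             peaklist(500, 4e5)))
  agg <- aggregate_burn(s, NULL)          # NULL event = all scans
  expect_equal(agg, peaklist(500, 8e5))   # 600 is sub-threshold, dropped

  # threshold 0 conserves total intensity
  agg0 <- aggregate_burn(s, NULL, threshold = 0)
  expect_equal(sum(agg0[, "intensity"]), sum(tic(s)))

  # empty result is allowed
  expect_equal(nrow(aggregate_burn(s, NULL, threshold = 1e9)), 0)
})

test_that("lockmass correction is multiplicative, exact and idempotent", {
  # already on reference: identity
  pk <- peaklist(c(500.00, 554.26, 700.00), c(1e6, 2e6, 1e6))
  expect_equal(lockmass_correct(pk), pk, ignore_attr = TRUE)

  # uniform +0.02 shift: hand-computed gain 554.26/554.28
  shifted <- peaklist(c(500.02, 554.28, 700.02), c(1e6, 2e6, 1e6))
  corr <- lockmass_correct(shifted)
  expect_equal(unname(corr[2, "mz"]), 554.26, tolerance = 1e-12)
  expect_equal(corr[, "mz"], shifted[, "mz"] * (554.26 / 554.28),
               tolerance = 1e-12, ignore_attr = TRUE)
  # residual of correcting an additive shift multiplicatively:
  # 0.02 * (1 - 500/554.26) = 0.00196 Da, inside the 0.005 Da budget
  expect_lt(abs(corr[1, "mz"] - 500.00), 0.005)

  # idempotence to 1e-9 relative
  twice <- lockmass_correct(corr)
  expect_lt(max(abs(twice[, "mz"] / corr[, "mz"] - 1)), 1e-9)

  # no reference in window: unchanged, flagged, warned
  lone <- peaklist(c(500, 700), c(1e6, 1e6))
  expect_warning(un <- lockmass_correct(lone), "uncorrected")
  expect_true(attr(un, "uncorrectable"))
  expect_equal(un[, "mz"], lone[, "mz"], ignore_attr = TRUE)
})

test_that("bin grid geometry matches the printed point counts", {
  expect_identical(bin_grid(400, 1100, 0.1)$n_points, 7001L)
  expect_identical(bin_grid(400, 1100, 0.05)$n_points, 14001L)
  g <- bin_grid(400, 1100, 0.1)
  expect_equal(g$centers[1], 400)
  expect_equal(g$centers[7001], 1100)
})

test_that("binning assigns to nearest point, ties to lower, edges half-open", {
  g <- bin_grid(400, 410, 0.1)
  b <- bin_spectrum(peaklist(c(400.04, 400.06, 409.96), c(1, 2, 8)), g)
  expect_equal(b$values[1], 1)       # 400.04 -> 400.0
  expect_equal(b$values[2], 2)       # 400.06 -> 400.1
  expect_equal(b$values[101], 8)     # 409.96 -> 410.0

  # width-1 grid keeps the halfway arithmetic exact in floating point
  g1 <- bin_grid(400, 410, 1)
  t1 <- bin_spectrum(peaklist(c(400.5, 401.5, 402.25), c(1, 2, 4)), g1)
  expect_equal(t1$values[1:3], c(1, 2, 4))   # ties go to the lower point
  # outside [start - w/2, end + w/2) discarded; left edge included
  t2 <- bin_spectrum(peaklist(c(399.5, 399.25, 410.5, 410.25),
                              c(1, 2, 4, 8)), g1)
  expect_equal(t2$values[1], 1)              # left edge 399.5 included
  expect_equal(t2$values[11], 8)             # 410.5 excluded, 410.25 kept
  expect_equal(sum(t2$values), 9)            # 399.25 below the window

  expect_equal(bin_spectrum(peaklist(numeric(0), numeric(0)),
                            bin_grid())$values, numeric(7001))
})

test_that("binning with threshold 0 conserves in-window intensity", {
  fmcfg <- small_config(seed = 8)
  sim <- simulate_dataset(fmcfg)
  s <- sim$series[[1]]
  agg <- aggregate_burn(s, NULL, threshold = 0)
  g <- bin_grid()
  inwin <- agg[agg[, "mz"] >= g$mz_start - g$width / 2 &
               agg[, "mz"] < g$mz_end + g$width / 2, , drop = FALSE]
  expect_equal(sum(bin_spectrum(agg, g)$values), sum(inwin[, "intensity"]))
})

test_that("TIC normalisation and its invariances", {
  g <- bin_grid(400, 400.2, 0.1)
  b <- bin_spectrum(peaklist(c(400, 400.1, 400.2), c(2, 2, 6)), g)
  expect_equal(normalise_spectrum(b)$values, c(0.2, 0.2, 0.6))

  # scaling the input by any c > 0 changes nothing after normalisation
  b4 <- b; b4$values <- b4$values * 0.25
  expect_equal(normalise_spectrum(b4)$values, normalise_spectrum(b)$values)

  zero <- bin_spectrum(peaklist(numeric(0), numeric(0)), g)
  expect_error(normalise_spectrum(zero), "all-zero")
})

test_that("individual averaging equals the per-bin mean and checks grids", {
  g <- bin_grid(400, 402, 0.1)
  mk <- function(v) structure(list(grid = g, values = v, normalised = TRUE,
                                   provenance = "p", lockmass_used = NULL),
                              class = "binned_spectrum")
  v1 <- runif(g$n_points); v2 <- runif(g$n_points); v3 <- runif(g$n_points)
  expect_equal(average_individual(list(mk(v1)))$values, v1)
  expect_equal(average_individual(list(mk(v1), mk(v1), mk(v1)))$values, v1)
  # brute-force per-bin mean
  expect_equal(average_individual(list(mk(v1), mk(v2), mk(v3)))$values,
               (v1 + v2 + v3) / 3)
  g2 <- bin_grid(400, 402, 0.05)
  mk2 <- structure(list(grid = g2, values = numeric(g2$n_points),
                        normalised = TRUE, provenance = "q",
                        lockmass_used = NULL), class = "binned_spectrum")
  expect_error(average_individual(list(mk(v1), mk2)), "different grids")
})

test_that("full preprocessing is invariant to uniform intensity scaling", {
  cfg <- small_config(seed = 31, noise_floor = 0)
  sim <- simulate_dataset(cfg)
  fm1 <- preprocess_dataset(sim$series, sim$truth, threshold = 0)
  quartered <- lapply(sim$series, function(s) {
    s$peaks <- lapply(s$peaks, function(p) {
      p[, "intensity"] <- p[, "intensity"] * 0.25; p
    })
    s
  })
  fm2 <- preprocess_dataset(quartered, sim$truth, threshold = 0)
  expect_identical(fm1$x, fm2$x)
})

test_that("on drift-free data, lockmass correction on/off is a no-op", {
  cfg <- small_config(seed = 13, calibration_drift = 0)
  sim <- simulate_dataset(cfg)
  on <- preprocess_dataset(sim$series, sim$truth, lockmass = 554.26)
  off <- preprocess_dataset(sim$series, sim$truth, lockmass = NA)
  expect_equal(on$x, off$x, tolerance = 1e-12)
})

test_that("simulated drift is removed end to end by the lockmass stage", {
  cfg <- small_config(seed = 41, calibration_drift = 0.05, noise_floor = 0)
  sim <- simulate_dataset(cfg)
  # undo the (additive, known) drift by hand to get the ideal reference
  undrifted <- lapply(sim$series, function(s) {
    d <- s$meta$drift
    s$peaks <- lapply(s$peaks, function(p) {
      p[, "mz"] <- p[, "mz"] - d; p
    })
    s
  })
  on <- preprocess_dataset(sim$series, sim$truth)
  ref <- preprocess_dataset(undrifted, sim$truth)
  # the fixture's peaks sit away from bin boundaries, so the corrected
  # drifted data must land on the same bins as the ideal reference
  cossim <- vapply(seq_len(nrow(on$x)), function(i) {
    sum(on$x[i, ] * ref$x[i, ]) /
      sqrt(sum(on$x[i, ]^2) * sum(ref$x[i, ]^2))
  }, numeric(1))
  expect_gt(min(cossim), 0.999)
})
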