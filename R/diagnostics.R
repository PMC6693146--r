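# Interpretive diagnostics: permutation-importance ranking of discriminant
# m/z bins (with isotopomer-pair collapsing for display), label
# randomisation ("pseudospecies") null tests, isotopomer cross-correlation,
# and annotation of misclassified samples.

#' Rank the most discriminant m/z bins
#'
#' Ranks bins by permutation importance (mean decrease in out-of-bag
#' accuracy when a bin's values are permuted, aggregated over all trees of
#' the forest). The top bins are screened for isotopomer pairs by
#' cross-correlation: when two top bins form an isotopic pair, both remain
#' in the model, but the display list keeps only the monoisotopic member,
#' so `display` walks the ranking, skips any bin whose isotopic partner is
#' already listed, and returns `k` distinct molecular species. Per-class
#' intensity summaries (median, quartiles, 5-95% whiskers) accompany each
#' displayed bin.
#'
#' @param rf An `rf_result` fitted with `importance = TRUE` (or a raw
#'   `randomForest` model via `fm`).
#' @param fm Feature matrix the forest was trained on; defaults to the one
#'   stored in `rf`.
#' @param k Number of bins to report (default 5).
#' @param spacing Isotopomer spacing in Da (default 1.00336).
#' @param r_min,ratio_band Passed to [isotopomer_pairs()] for pair
#'   screening.
#' @return Object of class `importance_report`: `ranked` (data.frame of
#'   bin m/z and importance, non-increasing), `top` (first `k` raw),
#'   `display` (isotopomer-collapsed top `k`), `pair_annotations`, and
#'   `class_summaries`.
#' @export
top_discriminant_bins <- function(rf, fm = NULL, k = 5,
                                  spacing = 1.00336, r_min = 0.9,
                                  ratio_band = c(0.1, 1.0)) {
  if (inherits(rf, "rf_result")) {
    model <- rf$model
    if (is.null(fm)) fm <- rf$fm
    target <- rf$target
  } else {
    model <- rf
    target <- "class"
  }
  if (is.null(fm)) stop("a feature_matrix is required")
  imp <- model$importance
  if (is.null(imp) || !"MeanDecreaseAccuracy" %in% colnames(imp))
    stop("the forest was not grown with importance = TRUE")
  if (k > ncol(fm$x)) stop("k exceeds the number of bins")
  score <- imp[, "MeanDecreaseAccuracy"]
  o <- order(score, decreasing = TRUE)
  ranked <- data.frame(bin = colnames(fm$x)[o],
                       mz = fm$grid$centers[o],
                       importance = as.numeric(score[o]),
                       stringsAsFactors = FALSE)

  # screen an ample head of the ranking for isotopomer pairs
  head_n <- min(nrow(ranked), max(4L * k, 20L))
  cand_idx <- o[seq_len(head_n)]
  pairs <- isotopomer_pairs(fm, spacing = spacing, r_min = r_min,
                            ratio_band = ratio_band,
                            restrict = cand_idx)
  iso <- pairs[pairs$verdict == "isotopic", , drop = FALSE]
  partner_of <- function(bin_mz) {
    hit <- which(abs(iso$mz_a - bin_mz) < fm$grid$width / 2 |
                 abs(iso$mz_b - bin_mz) < fm$grid$width / 2)
    if (length(hit) == 0) return(NA_real_)
    h <- iso[hit[1], ]
    if (abs(h$mz_a - bin_mz) < fm$grid$width / 2) h$mz_b else h$mz_a
  }

  # display list: walk the ranking; for a bin belonging to an isotopic
  # pair, display the monoisotopic (lighter) member only, and never list
  # both members of a pair
  labels_all <- format_bin_labels(fm$grid)
  display <- character(0)
  display_mz <- numeric(0)
  ann <- list()
  for (i in seq_len(nrow(ranked))) {
    if (length(display) >= k) break
    bz <- ranked$mz[i]
    pz <- partner_of(bz)
    is_mono <- is.na(pz) || bz < pz
    show_mz <- if (is_mono) bz else pz
    dup <- any(abs(display_mz - show_mz) < fm$grid$width / 2)
    ann[[length(ann) + 1L]] <- data.frame(
      bin = ranked$bin[i], mz = bz, partner_mz = pz,
      monoisotopic = is_mono, displayed = !dup && is_mono,
      stringsAsFactors = FALSE)
    if (!dup) {
      j <- which.min(abs(fm$grid$centers - show_mz))
      display <- c(display, labels_all[j])
      display_mz <- c(display_mz, fm$grid$centers[j])
    }
  }
  ann <- do.call(rbind, ann)

  y <- factor(fm$labels[[target]])
  summaries <- lapply(display, function(b) {
    v <- fm$x[, b]
    do.call(rbind, lapply(levels(y), function(cl) {
      q <- stats::quantile(v[y == cl], c(0.05, 0.25, 0.5, 0.75, 0.95))
      data.frame(bin = b, class = cl, q05 = q[[1]], q25 = q[[2]],
                 median = q[[3]], q75 = q[[4]], q95 = q[[5]],
                 stringsAsFactors = FALSE)
    }))
  })
  structure(list(ranked = ranked, top = ranked[seq_len(k), ],
                 display = display,
                 display_mz = display_mz,
                 pair_annotations = ann,
                 class_summaries = do.call(rbind, summaries),
                 k = k, target = target),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("importance_report: top-%d discriminant bins for '%s'\n",
              x$k, x$target))
  print(x$top, row.names = FALSE)
  cat("displayed (isotopomer-collapsed):",
      paste(x$display, collapse = ", "), "\n")
  invisible(x)
}

#' Label-randomisation ("pseudospecies") null test
#'
#' Permutes the class labels `n_shuffles` times, reruns the all-data
#' random-forest evaluation on each permutation, and compares the
#' true-label accuracy against the resulting null distribution. A workflow
#' with real signal sits above the null's 95th percentile; the null mean
#' sits at chance (1/k for balanced classes).
#'
#' @param fm A [feature_matrix()].
#' @param target Label column (default `"class"`).
#' @param n_shuffles Number of label permutations (default 50).
#' @param seed Integer seed.
#' @param n_trees Trees per forest (default 250: a chance-level OOB
#'   estimate stabilises with fewer trees than the headline classifier).
#' @return Object of class `randomisation_test`: `null_accuracies`,
#'   `true_accuracy`, `chance` (100/k), `null_p95`, and `significant`
#'   (true accuracy above the null 95th percentile).
#' @export
randomisation_test <- function(fm, target = "class", n_shuffles = 50,
                               seed, n_trees = 250) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (missing(seed)) stop("seed is mandatory")
  true_acc <- rf_fit_evaluate(fm, target, "all_data", seed = seed,
                              n_trees = n_trees,
                              importance = FALSE)$report$overall_accuracy
  y <- fm$labels[[target]]
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  null_acc <- vapply(seq_len(n_shuffles), function(s) {
    fm_perm <- fm
    fm_perm$labels[[target]] <- sample(y)
    sub_seed <- sample.int(.Machine$integer.max, 1)
    rf_fit_evaluate(fm_perm, target, "all_data", seed = sub_seed,
                    n_trees = n_trees,
                    importance = FALSE)$report$overall_accuracy
  }, numeric(1))
  k <- nlevels(factor(y))
  p95 <- stats::quantile(null_acc, 0.95, names = FALSE)
  structure(list(null_accuracies = null_acc, true_accuracy = true_acc,
                 chance = 100 / k, null_mean = mean(null_acc),
                 null_p95 = p95, significant = true_acc > p95,
                 n_shuffles = n_shuffles, seed = seed),
            class = "randomisation_test")
}

#' @export
print.randomisation_test <- function(x, ...) {
  cat(sprintf(
    "randomisation_test: true %.1f%% vs null mean %.1f%% (chance %.1f%%),\n",
    x$true_accuracy, x$null_mean, x$chance))
  cat(sprintf("  null 95th percentile %.1f%% -> %s\n", x$null_p95,
              if (x$significant) "signal detected" else "no signal"))
  invisible(x)
}

#' Isotopomer cross-correlation analysis
#'
#' For every bin pair separated by the 13C spacing (rounded to a whole-bin
#' offset), computes the Pearson correlation of intensities across samples
#' and the median intensity ratio. A pair is called `"isotopic"` when the
#' correlation reaches `r_min` and the median ratio of the heavier to the
#' lighter bin falls inside `ratio_band` (the range expected for first-13C
#' isotopomers of C10-C90 species); `"correlated_non_isotopic"` when
#' correlated but the ratio is wrong (same molecular class, not a
#' 12C/13C pair); otherwise `"unrelated"`. Zero-variance bins are skipped.
#'
#' @param fm A [feature_matrix()] with >= 10 samples.
#' @param spacing Isotopomer spacing in Da (default 1.00336).
#' @param r_min Correlation threshold (default 0.9).
#' @param ratio_band Admissible median ratio range (default `c(0.1, 1.0)`).
#' @param restrict Optional vector of column indices: only pairs touching
#'   these bins are evaluated.
#' @param min_support Minimum fraction of samples in which both bins must
#'   carry signal for a correlated verdict (default 0.5). A genuine
#'   analyte appears in essentially every spectrum of a cohort; sparse
#'   noise bins co-occurring in one or two samples produce degenerate
#'   perfect correlations and are not assessable.
#' @return data.frame with columns `mz_a`, `mz_b`, `pearson_r`,
#'   `median_ratio`, `support`, `verdict`; attribute `n_candidates`
#'   counts evaluated pairs and `n_skipped` the zero-variance skips.
#' @export
isotopomer_pairs <- function(fm, spacing = 1.00336, r_min = 0.9,
                             ratio_band = c(0.1, 1.0), restrict = NULL,
                             min_support = 0.5) {
  if (!inherits(fm, "feature_matrix")) stop("fm must be a feature_matrix")
  n <- nrow(fm$x)
  if (n < 10) stop("at least 10 samples are required")
  # the true m/z of a binned peak is only known to half a bin width, so
  # the isotopomer may land either floor or ceiling of (spacing / width)
  # bins up; scan both whole-bin offsets
  offsets <- unique(c(floor(spacing / fm$grid$width),
                      ceiling(spacing / fm$grid$width)))
  offsets <- as.integer(offsets[offsets >= 1])
  if (length(offsets) == 0) stop("spacing is below one bin width")
  p <- ncol(fm$x)
  sds <- apply(fm$x, 2, stats::sd)
  pieces <- list()
  n_cand <- 0L
  n_skipped <- 0L
  for (off in offsets) {
    a_idx <- seq_len(max(0L, p - off))
    if (!is.null(restrict)) {
      rst <- unique(as.integer(restrict))
      a_idx <- a_idx[a_idx %in% rst | (a_idx + off) %in% rst]
    }
    live <- sds[a_idx] > 0 & sds[a_idx + off] > 0
    n_skipped <- n_skipped + sum(!live)
    a_idx <- a_idx[live]
    if (length(a_idx) == 0) next
    A <- fm$x[, a_idx, drop = FALSE]
    B <- fm$x[, a_idx + off, drop = FALSE]
    r <- vapply(seq_along(a_idx), function(j)
      stats::cor(A[, j], B[, j]), numeric(1))
    support <- colMeans(A > 0 & B > 0)
    med_ratio <- vapply(seq_along(a_idx), function(j) {
      nz <- A[, j] > 0
      if (!any(nz)) return(NA_real_)
      stats::median(B[nz, j] / A[nz, j])
    }, numeric(1))
    verdict <- ifelse(
      !is.na(r) & r >= r_min & support >= min_support,
      ifelse(!is.na(med_ratio) &
               med_ratio >= ratio_band[1] & med_ratio <= ratio_band[2],
             "isotopic", "correlated_non_isotopic"),
      "unrelated")
    n_cand <- n_cand + length(a_idx)
    pieces[[length(pieces) + 1L]] <- data.frame(
      mz_a = fm$grid$centers[a_idx],
      mz_b = fm$grid$centers[a_idx + off],
      pearson_r = r, median_ratio = med_ratio,
      support = support, verdict = verdict,
      stringsAsFactors = FALSE)
  }
  out <- if (length(pieces) == 0) {
    data.frame(mz_a = numeric(0), mz_b = numeric(0),
               pearson_r = numeric(0), median_ratio = numeric(0),
               support = numeric(0), verdict = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, pieces)
  }
  out <- out[order(out$mz_a, out$mz_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- n_cand
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Annotate misclassified samples in the top discriminant bins
#'
#' For every misclassified sample of a classification run, reports its
#' intensity in each displayed top bin together with the true-class median
#' and whether the sample sits above or below it — misclassified samples
#' tend to cluster away from their class median in the discriminant bins.
#'
#' @param rf An `rf_result`.
#' @param importance An `importance_report` from the same matrix.
#' @param fm Feature matrix; defaults to the one stored in `rf`.
#' @return data.frame (possibly zero rows) with columns `individual_id`,
#'   `true_class`, `predicted_class`, `bin`, `intensity`, `class_median`,
#'   `position` ("above"/"below").
#' @export
annotate_misclassified <- function(rf, importance, fm = NULL) {
  if (!inherits(rf, "rf_result")) stop("rf must be an rf_result")
  if (!inherits(importance, "importance_report"))
    stop("importance must be an importance_report")
  if (is.null(fm)) fm <- rf$fm
  if (!all(importance$display %in% colnames(fm$x)))
    stop("importance report does not match the feature matrix")
  ids <- rownames(fm$x)[rf$test_idx]
  if (!all(ids %in% rownames(fm$x)))
    stop("classification result does not match the feature matrix")
  y_all <- factor(fm$labels[[rf$target]])
  mis <- which(rf$predicted != rf$truth)
  if (length(mis) == 0) {
    return(data.frame(individual_id = character(0),
                      true_class = character(0),
                      predicted_class = character(0), bin = character(0),
                      intensity = numeric(0), class_median = numeric(0),
                      position = character(0), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (m in mis) {
    sid <- ids[m]
    cl <- as.character(rf$truth[m])
    for (b in importance$display) {
      med <- stats::median(fm$x[y_all == cl, b])
      v <- fm$x[sid, b]
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sid, true_class = cl,
        predicted_class = as.character(rf$predicted[m]), bin = b,
        intensity = v, class_median = med,
        position = if (v >= med) "above" else "below",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
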