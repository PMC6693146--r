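# Classification: PCA-seeded discriminant function analysis (the
# visual/discrimination track) and random-forest classification with
# out-of-bag, 70/30-split and hold-out evaluation (the accuracy track).

#' PCA-seeded discriminant function analysis
#'
#' Fits PCA on the full feature matrix (per-bin mean-centred, no
#' unit-variance scaling by default), then linear discriminant analysis on
#' the top `n_components` principal-component scores. The discriminant
#' axes are eigenvectors of \eqn{W^{-1} B} where `W` is the pooled
#' within-class scatter (ridge-regularised by `ridge * trace(W)` on the
#' diagonal, so degenerate noiseless inputs are handled) and `B` the
#' between-class scatter. Samples are classified by the nearest class
#' mean in the discriminant space (resubstitution).
#'
#' @param fm A [feature_matrix()].
#' @param target Label column to discriminate (default `"class"`).
#' @param n_components Number of principal components fed to the DFA
#'   (default 12).
#' @param scale. Unit-variance scale bins before PCA (default `FALSE`).
#' @param ridge Ridge factor applied to the within-class scatter
#'   (default `1e-6`).
#' @return Object of class `pca_lda` with per-sample discriminant scores
#'   (`scores`, first two columns are the plotting axes), `class_means`,
#'   discriminant `axes`, `predicted`, `accuracy` (resubstitution, %),
#'   and the fitted `pca`.
#' @export
pca_lda <- function(fm, target = "class", n_components = 12,
                    scale. = FALSE, ridge = 1e-6) {
  if (!inherits(fm, "feature_matrix")) stop("fm must be a feature_matrix")
  y <- factor(fm$labels[[target]])
  if (nlevels(y) < 2) stop("at least 2 classes are required")
  n <- nrow(fm$x)
  if (n <= n_components)
    stop("n_samples must exceed n_components")
  keep <- which(apply(fm$x, 2, stats::sd) > 0)
  pca <- stats::prcomp(fm$x[, keep, drop = FALSE], center = TRUE,
                       scale. = scale., rank. = n_components)
  sc <- pca$x[, seq_len(min(n_components, ncol(pca$x))), drop = FALSE]
  p <- ncol(sc)
  k <- nlevels(y)

  mu <- rowsum(sc, y) / as.vector(table(y))
  centred <- sc - mu[y, , drop = FALSE]
  W <- crossprod(centred) / max(1, n - k)
  grand <- colMeans(sc)
  dm <- sweep(mu, 2, grand)
  B <- crossprod(dm * sqrt(as.vector(table(y)))) / max(1, k - 1)
  tr <- sum(diag(W))
  trB <- sum(diag(B))
  Wr <- W + diag(if (tr > 0) ridge * tr else 1e-12, p)
  if (tr <= 1e-10 * max(trB, 1e-300))
    warning("within-class scatter is (near-)singular relative to the ",
            "between-class scatter; ridge regularisation applied")
  e <- eigen(solve(Wr, B))
  ndisc <- min(k - 1, p)
  axes <- Re(e$vectors[, seq_len(ndisc), drop = FALSE])
  colnames(axes) <- paste0("LD", seq_len(ndisc))
  # normalise axes to unit within-class variance (canonical scaling)
  wvar <- sqrt(pmax(diag(t(axes) %*% Wr %*% axes), 1e-300))
  axes <- sweep(axes, 2, wvar, "/")

  scores <- sc %*% axes
  cm <- mu %*% axes
  d2 <- outer(rowSums(scores^2), rowSums(cm^2), "+") -
    2 * scores %*% t(cm)
  pred <- factor(rownames(cm)[max.col(-d2, ties.method = "first")],
                 levels = levels(y))
  structure(list(scores = scores, class_means = cm, axes = axes,
                 eigenvalues = Re(e$values[seq_len(ndisc)]),
                 predicted = pred, truth = y,
                 accuracy = 100 * mean(pred == y),
                 pca = pca, pc_cols = keep, target = target),
            class = "pca_lda")
}

#' @export
print.pca_lda <- function(x, ...) {
  cat(sprintf("PCA(%d)+DFA on '%s': %d samples, %d classes, ",
              ncol(x$pca$x), x$target, length(x$truth),
              nlevels(x$truth)))
  cat(sprintf("resubstitution accuracy %.1f%%\n", x$accuracy))
  invisible(x)
}

#' Build a classification report
#'
#' Confusion matrix in row-percentages (each true-class row sums to 100),
#' per-class accuracy (the diagonal) and overall accuracy (the
#' sample-weighted mean of the diagonal).
#'
#' @param truth,predicted Factors of equal length on the same levels.
#' @param mode Evaluation mode label.
#' @param seed Seed used for the evaluation.
#' @return Object of class `classification_report`.
#' @export
classification_report <- function(truth, predicted, mode, seed = NA_integer_) {
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  counts <- table(truth = truth, predicted = predicted)
  rs <- rowSums(counts)
  confusion <- sweep(100 * counts, 1, pmax(rs, 1L), "/")
  per_class <- diag(confusion)
  overall <- 100 * mean(predicted == truth)
  structure(list(confusion = as.matrix(confusion),
                 counts = as.matrix(counts),
                 per_class_accuracy = per_class,
                 overall_accuracy = overall,
                 mode = mode, seed = seed, n = length(truth)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report [%s] n = %d, overall accuracy %.1f%%\n",
              x$mode, x$n, x$overall_accuracy))
  print(round(x$confusion, 1))
  invisible(x)
}

#' Random-forest classification of a feature matrix
#'
#' Two evaluation designs: `"all_data"` grows the forest on every sample
#' and reports the out-of-bag confusion matrix (each sample predicted by
#' the trees that never saw it), the standard all-data estimate;
#' `"split_70_30"` draws a stratified random 70% training set and reports
#' the confusion on the held-out 30%.
#'
#' Trees are grown on stratified, equal-size subsamples drawn without
#' replacement (0.632 of the smallest class per class) rather than plain
#' bootstrap. Plain-bootstrap OOB voting under-represents a sample's own
#' class among the trees that vote for it, which biases the chance-level
#' accuracy on label-permuted data well below 1/k; stratified subsampling
#' removes that deficit so a no-signal evaluation sits at chance, and it
#' guards against class imbalance at the same time.
#'
#' @param fm A [feature_matrix()].
#' @param target Label column to classify (default `"class"`).
#' @param mode `"all_data"` or `"split_70_30"`.
#' @param seed Integer seed (mandatory: forests and splits are random).
#' @param n_trees Number of trees (default 500).
#' @param importance Grow with permutation importance bookkeeping
#'   (default `TRUE`; needed by [top_discriminant_bins()]).
#' @return Object of class `rf_result`: the fitted `model`, the
#'   [classification_report()] `report`, and the evaluation frame.
#' @export
rf_fit_evaluate <- function(fm, target = "class",
                            mode = c("all_data", "split_70_30"),
                            seed, n_trees = 500, importance = TRUE) {
  if (!inherits(fm, "feature_matrix")) stop("fm must be a feature_matrix")
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  # canonical sample order: results do not depend on input row order
  fm <- fm_subset(fm, order(rownames(fm$x)))
  y <- factor(fm$labels[[target]])
  if (any(table(y) == 0)) y <- droplevels(y)
  x <- fm$x
  if (nlevels(y) == 1) {
    # degenerate single-class input: classification is trivial
    report <- classification_report(y, y, mode, seed)
    return(structure(list(model = NULL, report = report, fm = fm,
                          target = target, truth = y,
                          test_idx = seq_along(y), predicted = y,
                          mode = mode, seed = seed),
                     class = "rf_result"))
  }
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))

  if (mode == "all_data") {
    model <- grow_forest(x, y, n_trees, importance)
    report <- classification_report(y, model$predicted, mode, seed)
    test_idx <- seq_along(y)
  } else {
    tab <- table(y)
    if (any(tab < 5))
      stop("split_70_30 requires at least 5 samples per class")
    train <- unlist(lapply(levels(y), function(cl) {
      i <- which(y == cl)
      sample(i, max(1L, round(0.7 * length(i))))
    }))
    test_idx <- setdiff(seq_along(y), train)
    if (any(!levels(y) %in% y[train]))
      stop("a class is absent from the training split")
    model <- grow_forest(x[train, , drop = FALSE], droplevels(y[train]),
                         n_trees, importance)
    pred <- stats::predict(model, x[test_idx, , drop = FALSE])
    report <- classification_report(y[test_idx], pred, mode, seed)
  }
  structure(list(model = model, report = report, fm = fm, target = target,
                 truth = y, test_idx = test_idx,
                 predicted = if (mode == "all_data") model$predicted
                             else stats::predict(
                               model, x[test_idx, , drop = FALSE]),
                 mode = mode, seed = seed),
            class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Predict held-out samples with a forest trained elsewhere
#'
#' Trains a random forest on `train` only and classifies every sample of
#' `test` with the `predict` machinery — the design used to classify
#' samples from populations absent from the original data set.
#'
#' @param train,test [feature_matrix()] objects on identical grids; every
#'   class present in `test` must exist in `train`.
#' @param target Label column (default `"class"`).
#' @param seed Integer seed.
#' @param n_trees Number of trees (default 500).
#' @return An `rf_result` whose report has mode `"holdout_predict"`.
#' @export
rf_predict_holdout <- function(train, test, target = "class", seed,
                               n_trees = 500) {
  if (!inherits(train, "feature_matrix") || !inherits(test, "feature_matrix"))
    stop("train and test must be feature_matrix objects")
  if (!same_grid(train$grid, test$grid))
    stop("train and test grids differ")
  if (missing(seed)) stop("seed is mandatory")
  train <- fm_subset(train, order(rownames(train$x)))
  ytr <- factor(train$labels[[target]])
  yte <- as.character(test$labels[[target]])
  if (!all(yte %in% levels(ytr)))
    stop("test contains classes absent from training: ",
         paste(setdiff(unique(yte), levels(ytr)), collapse = ", "))
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  model <- grow_forest(train$x, ytr, n_trees, importance = FALSE)
  pred <- stats::predict(model, test$x)
  report <- classification_report(factor(yte, levels = levels(ytr)),
                                  pred, "holdout_predict", seed)
  structure(list(model = model, report = report, fm = test, target = target,
                 truth = factor(yte, levels = levels(ytr)),
                 test_idx = seq_len(nrow(test$x)), predicted = pred,
                 mode = "holdout_predict", seed = seed),
            class = "rf_result")
}

# stratified equal-size subsampling without replacement: unbiased OOB
# chance level and robustness to class imbalance
grow_forest <- function(x, y, n_trees, importance) {
  ss <- rep(max(1L, ceiling(0.632 * min(table(y)))), nlevels(y))
  randomForest::randomForest(x, y, ntree = n_trees,
                             importance = importance,
                             strata = y, sampsize = ss, replace = FALSE)
}
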