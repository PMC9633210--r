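#' Build the CV-like validation plan
#'
#' Randomly partitions the samples into `n_folds` near-equal folds and
#' enumerates all choose(n_folds, 2) combinations of 2 test folds versus
#' the remaining 3 training folds (10 combinations for 5 folds), so each
#' sample appears in a test set exactly 4 times.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param seed RNG seed for the fold assignment.
#' @param n_folds number of folds (default 5).
#' @return a list of class `cv_plan` with `folds` (named integer fold per
#'   sample) and `combos` (list of `list(train =, test =)` fold-id pairs in
#'   deterministic order).
#' @export
make_cv_plan <- function(sample_ids, seed = 1L, n_folds = 5L) {
  n <- length(sample_ids)
  if (n < 2 * n_folds) stop("need at least 10 samples for the CV-like plan")
  set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  names(folds) <- sample_ids
  test_sets <- utils::combn(n_folds, 2, simplify = FALSE)
  combos <- lapply(test_sets, function(ts)
    list(train = setdiff(seq_len(n_folds), ts), test = ts))
  structure(list(folds = folds, combos = combos, n_folds = n_folds,
                 seed = seed),
            class = "cv_plan")
}

#' Select top features by one-way ANOVA
#'
#' Ranks features by the p-value of a one-way ANOVA F-test of the feature
#' across subgroup labels and returns the `top_n` smallest; ties are
#' broken by the larger F statistic, then by feature id.
#'
#' @param m numeric matrix (samples x features) or `omics_matrix`.
#' @param labels group labels (>= 2 groups present).
#' @param top_n number of features to return; if larger than the feature
#'   count, all features are returned with a warning.
#' @return character vector of selected feature ids, best first.
#' @export
anova_select <- function(m, labels, top_n) {
  v <- if (inherits(m, "omics_matrix")) as_bare_matrix(m) else m
  f <- droplevels(factor(labels))
  if (nlevels(f) < 2) stop("need at least two groups for ANOVA selection")
  n <- nrow(v)
  k <- nlevels(f)
  if (any(table(f) < 1) || n <= k) stop("too few samples per group")
  # vectorized one-way ANOVA across all feature columns
  gm <- rowsum(v, f) / as.vector(table(f))
  grand <- colMeans(v)
  ssb <- colSums(as.vector(table(f)) * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(v, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  p[!is.finite(Fstat)] <- 1
  ord <- order(p, -Fstat, colnames(v))
  if (top_n > ncol(v)) {
    warning(sprintf("top_n = %d exceeds %d features; returning all",
                    top_n, ncol(v)))
    top_n <- ncol(v)
  }
  colnames(v)[ord[seq_len(top_n)]]
}

#' Omics-specific scaling recipe for classification
#'
#' mRNA and promoter-methylation features get median scale normalization
#' followed by robust scale normalization; miRNA features get median scale
#' normalization followed by per-feature unit (l2) scaling. Parameters are
#' fit on the given matrix itself, so training, test and external sets are
#' each scaled independently.
#'
#' @param m an `omics_matrix` whose kind determines the recipe
#'   (`mrna_counts`/`methylation_promoter`/`expression_intensity` vs
#'   `mirna_counts`).
#' @return the scaled `omics_matrix`.
#' @export
scale_for_classifier <- function(m) {
  kind <- omics_kind(m)
  if (kind %in% c("mrna_counts", "methylation_promoter",
                  "methylation_beta", "expression_intensity")) {
    step1 <- median_scale(m)$matrix
    robust_scale(step1)$matrix
  } else if (kind == "mirna_counts") {
    v <- as_bare_matrix(median_scale(m)$matrix)
    nrm <- sqrt(colSums(v * v))
    flat <- nrm == 0
    if (any(flat)) warning("constant miRNA features left at zero")
    omics_matrix(sweep(v, 2, ifelse(flat, 1, nrm), "/"), "latent")
  } else {
    stop(sprintf("no classifier scaling recipe for kind '%s'", kind))
  }
}

#' Fit an RBF-kernel SVM with grid-searched hyperparameters
#'
#' 5-fold cross-validated grid search over cost and gamma (defaults
#' 2^-5..2^5 and 2^-7..2^3), best pair by CV accuracy, refit on all
#' training data. Features are standardized internally by the SVM (its
#' stock behavior), which keeps the gamma grid on the scale it was
#' designed for. Fold split and therefore the selected pair are
#' deterministic given `seed`.
#'
#' @param x numeric matrix of scaled, feature-selected training data.
#' @param labels class labels (>= 2 classes).
#' @param cost_grid,gamma_grid hyperparameter grids.
#' @param seed RNG seed for the CV folds.
#' @return a list of class `svm_model` with the fitted `e1071::svm`
#'   object, the selected `cost`/`gamma`, the grid `cv_accuracy` table
#'   and the training feature ids.
#' @export
fit_svm <- function(x, labels, cost_grid = 2^(-5:5),
                    gamma_grid = 2^(-7:3), seed = 1L) {
  f <- droplevels(factor(labels))
  if (nlevels(f) < 2) stop("need at least two classes to fit the SVM")
  set.seed(seed)
  n <- nrow(x)
  folds <- sample(rep(1:5, length.out = n))
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    hits <- 0L
    for (fd in 1:5) {
      tr <- folds != fd
      if (length(unique(f[tr])) < 2) next
      fit <- suppressWarnings(
        e1071::svm(x[tr, , drop = FALSE], f[tr],
                   kernel = "radial", cost = grid$cost[i],
                   gamma = grid$gamma[i], scale = TRUE))
      hits <- hits + sum(stats::predict(
        fit, x[!tr, , drop = FALSE]) == f[!tr])
    }
    hits / n
  }, numeric(1))
  best <- which.max(acc)
  fit <- suppressWarnings(
    e1071::svm(x, f, kernel = "radial", cost = grid$cost[best],
               gamma = grid$gamma[best], scale = TRUE))
  structure(list(fit = fit, cost = grid$cost[best],
                 gamma = grid$gamma[best],
                 cv_accuracy = cbind(grid, accuracy = acc),
                 feature_ids = colnames(x), levels = levels(f)),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  if (!identical(colnames(newdata), object$feature_ids))
    newdata <- newdata[, object$feature_ids, drop = FALSE]
  stats::predict(object$fit, newdata)
}
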