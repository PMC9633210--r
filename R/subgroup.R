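#' Screen bottleneck features by univariate Cox regression
#'
#' Fits one univariate Cox proportional-hazards model per feature against
#' the survival outcome and keeps the features whose Wald p-value is at
#' most `alpha` (features with p greater than the threshold are screened
#' out). Constant or non-convergent features are dropped with a warning.
#'
#' @param b numeric matrix of bottleneck (or other) features, samples x
#'   features, rownames matching `surv$sample_id`.
#' @param surv survival data frame with columns `sample_id`, `time`,
#'   `event`.
#' @param alpha retention threshold on the Wald p-value (default 0.10).
#' @return a list of class `feature_screen` with `p` (named per-feature
#'   p-values), `kept` (feature ids with p <= alpha) and `alpha`.
#' @export
screen_features_cox <- function(b, surv, alpha = 0.10) {
  surv <- align_survival(surv, rownames(b))
  if (sum(surv$event) < 1) stop("need at least one event")
  y <- survival::Surv(surv$time, surv$event)
  p <- vapply(seq_len(ncol(b)), function(j) {
    x <- b[, j]
    if (stats::sd(x) == 0) return(NA_real_)
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ x)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    z <- fit$coefficients[1] / sqrt(fit$var[1, 1])
    if (!is.finite(z)) return(NA_real_)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  names(p) <- colnames(b)
  if (anyNA(p))
    warning(sprintf("%d constant or non-convergent features dropped",
                    sum(is.na(p))))
  kept <- names(p)[!is.na(p) & p <= alpha]
  if (!length(kept))
    stop("no feature passed Cox screening; consider a larger alpha")
  structure(list(p = p, kept = kept, alpha = alpha),
            class = "feature_screen")
}

#' k-means clustering with restarts
#'
#' Lloyd's algorithm, best of `n_restarts` random starts (lowest total
#' within-cluster sum of squares), deterministic given `seed`.
#'
#' @param features numeric matrix, samples x features.
#' @param k number of clusters (>= 2).
#' @param seed integer RNG seed.
#' @param n_restarts number of random restarts.
#' @return integer cluster labels named by sample.
#' @export
kmeans_cluster <- function(features, k, seed = 1L, n_restarts = 20L) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(features)) stop("k exceeds the number of samples")
  set.seed(seed)
  # Lloyd restarts on degenerate inputs (duplicated rows) emit benign
  # empty-cluster warnings; the best-WCSS restart is still well defined
  km <- suppressWarnings(
    stats::kmeans(features, centers = k, nstart = n_restarts,
                  iter.max = 100L, algorithm = "Lloyd"))
  labels <- km$cluster
  names(labels) <- rownames(features)
  attr(labels, "tot_withinss") <- km$tot.withinss
  labels
}

calinski_harabasz <- function(features, labels) {
  n <- nrow(features)
  k <- length(unique(labels))
  if (k < 2 || n <= k) return(NA_real_)
  centroid <- colMeans(features)
  ssb <- 0
  ssw <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    cg <- colMeans(features[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * sum((cg - centroid)^2)
    ssw <- ssw + sum(sweep(features[idx, , drop = FALSE], 2, cg)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the number of clusters by silhouette and Calinski-Harabasz
#'
#' Runs k-means for each candidate K and records the mean silhouette width
#' and the Calinski-Harabasz score of the resulting labels. The chosen K
#' maximizes the silhouette, ties broken by the higher Calinski-Harabasz
#' score and then by the smaller K.
#'
#' @param features numeric matrix, samples x features.
#' @param k_candidates integer vector of K values to scan (default 2:6).
#' @param seed RNG seed (one k-means run per K, offset per candidate).
#' @param n_restarts restarts per k-means run.
#' @return a list of class `cluster_selection` with a `report` data frame
#'   (k, silhouette, calinski_harabasz), the `chosen_k`, and the label
#'   vectors per K in `labels`.
#' @export
select_k <- function(features, k_candidates = 2:6, seed = 1L,
                     n_restarts = 20L) {
  if (nrow(features) < max(k_candidates) + 1)
    stop("need at least max(k_candidates) + 1 samples")
  if (all(stats::dist(utils::head(features, 50)) == 0))
    stop("degenerate input: all rows identical")
  d <- stats::dist(features)
  labels <- lapply(k_candidates, function(k)
    kmeans_cluster(features, k, seed = seed + k, n_restarts))
  names(labels) <- as.character(k_candidates)
  report <- do.call(rbind, lapply(seq_along(k_candidates), function(i) {
    lab <- labels[[i]]
    sil <- mean(cluster::silhouette(as.integer(lab), d)[, "sil_width"])
    data.frame(k = k_candidates[i], silhouette = sil,
               calinski_harabasz = calinski_harabasz(features, lab))
  }))
  ord <- order(-report$silhouette, -report$calinski_harabasz, report$k)
  chosen <- report$k[ord[1]]
  structure(list(report = report, chosen_k = chosen, labels = labels),
            class = "cluster_selection")
}

#' Orient cluster labels by observed hazard
#'
#' Names the cluster with the larger estimated hazard "high" and the other
#' "low" (K = 2), or relabels clusters `1..K` in increasing-hazard order
#' (K > 2). Hazard order comes from a univariate Cox fit on the cluster
#' indicator; clusters without events fall back to ordering by median
#' observed time (longer time = lower risk).
#'
#' @param labels integer cluster labels named by sample.
#' @param surv survival data frame (`sample_id`, `time`, `event`).
#' @return a list of class `subgroup_assignment` with `sample_ids`,
#'   `label` (factor `low`/`high` for K = 2, integer risk rank otherwise),
#'   `k`, and the cluster-to-risk `mapping`.
#' @export
orient_risk_labels <- function(labels, surv) {
  surv <- align_survival(surv, names(labels))
  groups <- sort(unique(labels))
  k <- length(groups)
  per_group_events <- vapply(groups, function(g)
    sum(surv$event[labels == g]), numeric(1))
  if (all(per_group_events >= 1) && k >= 2) {
    y <- survival::Surv(surv$time, surv$event)
    f <- factor(labels, levels = groups)
    fit <- suppressWarnings(survival::coxph(y ~ f))
    lp <- c(0, stats::coef(fit))  # log hazard per group vs first
  } else {
    lp <- -vapply(groups, function(g)
      stats::median(surv$time[labels == g]), numeric(1))
  }
  risk_rank <- rank(lp, ties.method = "first")
  names(risk_rank) <- as.character(groups)
  if (k == 2) {
    lab <- factor(ifelse(risk_rank[as.character(labels)] == 2,
                         "high", "low"), levels = c("low", "high"))
  } else {
    lab <- as.integer(risk_rank[as.character(labels)])
  }
  names(lab) <- names(labels)
  structure(list(sample_ids = names(labels), label = lab, k = k,
                 mapping = risk_rank),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("subgroup assignment: %d samples, K = %d\n",
              length(x$label), x$k))
  print(table(x$label))
  invisible(x)
}
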