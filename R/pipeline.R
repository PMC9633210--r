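#' Preprocess a multiomics cohort for integration
#'
#' Applies the full preprocessing chain: zero filters on the count layers
#' (features with more than `max_zero_frac` zeros, then samples), promoter
#' aggregation of CpG betas, missing-value filters on the promoter matrix
#' (features then samples), KNN imputation of the remainder, restriction
#' of all layers to the common samples, per-sample unit (l2) scaling of
#' each layer, and stacking into one feature matrix.
#'
#' @param cohort a list with `mrna`, `mirna`, `methylation_cpg` omics
#'   matrices plus `cpg_annotation`/`gene_annotation` tables (e.g. a
#'   `synthetic_cohort`), or the same with a precomputed
#'   `methylation_promoter` element instead of the CpG pieces.
#' @param max_zero_frac zero-fraction threshold for the count filters.
#' @param max_missing_frac missing-fraction threshold for methylation.
#' @param knn_k neighbours for [knn_impute()].
#' @param window_bp promoter window for
#'   [aggregate_promoter_methylation()].
#' @return a list of class `preprocessed_cohort` with `layers` (named
#'   list of filtered, imputed matrices on their raw scale) and `stacked`
#'   (unit-scaled, sample-aligned stacked matrix with block structure).
#' @export
preprocess_cohort <- function(cohort, max_zero_frac = 0.2,
                              max_missing_frac = 0.2, knn_k = 10L,
                              window_bp = 1500L) {
  mrna <- filter_zero_samples(
    filter_zero_features(cohort$mrna, max_zero_frac), max_zero_frac)
  mirna <- filter_zero_samples(
    filter_zero_features(cohort$mirna, max_zero_frac), max_zero_frac)
  if (!is.null(cohort$methylation_promoter)) {
    prom <- cohort$methylation_promoter
  } else {
    prom <- aggregate_promoter_methylation(
      cohort$methylation_cpg, cohort$cpg_annotation,
      cohort$gene_annotation, window_bp = window_bp)
  }
  prom <- knn_impute(filter_missing(prom, max_missing_frac), k = knn_k)
  ids <- Reduce(intersect, list(sample_ids(mrna), sample_ids(mirna),
                                sample_ids(prom)))
  if (!length(ids)) stop("no samples survive preprocessing in all layers")
  layers <- list(
    mrna = keep_kind(as_bare_matrix(mrna)[ids, , drop = FALSE], mrna),
    mirna = keep_kind(as_bare_matrix(mirna)[ids, , drop = FALSE], mirna),
    methylation = keep_kind(as_bare_matrix(prom)[ids, , drop = FALSE],
                            prom))
  stacked <- stack_omics(lapply(layers, unit_scale_samples))
  structure(list(layers = layers, stacked = stacked, sample_ids = ids),
            class = "preprocessed_cohort")
}

#' @export
print.preprocessed_cohort <- function(x, ...) {
  cat(sprintf("preprocessed cohort: %d samples; features: %s\n",
              length(x$sample_ids),
              paste(sprintf("%s %d", names(x$layers),
                            vapply(x$layers, ncol, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Discover survival subgroups from multiomics data
#'
#' The main fitting function. Preprocesses the cohort, reduces the
#' stacked omics features to a low-dimensional representation —
#' autoencoder bottleneck (default), PCA scores, or an SNF fused network
#' — screens the representation features by univariate Cox regression
#' (p <= `alpha` kept; skipped for SNF, which clusters the fused network
#' directly), clusters samples by k-means with silhouette/Calinski-
#' Harabasz selection of K (spectral clustering with eigengap selection
#' for SNF), orients the clusters into low/high risk by observed hazard,
#' and evaluates the separation (log-rank, C-index, IPCW Brier).
#'
#' @param cohort a cohort as accepted by [preprocess_cohort()], with a
#'   `survival` data frame (`sample_id`, `time`, `event`).
#' @param method `"autoencoder"`, `"pca"` or `"snf"`.
#' @param ae an [ae_spec()] for the autoencoder method.
#' @param alpha Cox screening threshold on the Wald p-value.
#' @param k_candidates candidate cluster numbers.
#' @param n_components PCA components; default the autoencoder bottleneck
#'   width (clamped to rank).
#' @param snf an [snf_config()] for the SNF method.
#' @param seed seed for clustering (and spectral embedding k-means).
#' @param preprocessed optionally a precomputed `preprocessed_cohort`, to
#'   share preprocessing across methods.
#' @return an object of class `subtype_fit`: the assignment (`label`),
#'   the `evaluation` (`survival_evaluation`), the cluster-selection
#'   `report`, the screening result, the representation matrix, the
#'   preprocessed data and the trained model where applicable.
#' @export
subtype_fit <- function(cohort, method = c("autoencoder", "pca", "snf"),
                        ae = ae_spec(), alpha = 0.10, k_candidates = 2:6,
                        n_components = NULL, snf = snf_config(),
                        seed = 1L, preprocessed = NULL) {
  method <- match.arg(method)
  pp <- if (is.null(preprocessed)) preprocess_cohort(cohort) else
    preprocessed
  surv <- align_survival(cohort$survival, pp$sample_ids)
  model <- NULL
  screen <- NULL
  selection <- NULL
  if (method == "snf") {
    aff <- lapply(pp$layers, function(l)
      snf_affinity(unit_scale_samples(l), snf))
    fused <- snf_fuse(aff, snf)
    labels <- spectral_cluster(fused, n_clusters = NULL,
                               k_candidates = k_candidates, seed = seed)
    features <- fused
    chosen_k <- attr(labels, "chosen_k")
    report <- NULL
  } else {
    if (method == "autoencoder") {
      model <- train_autoencoder(pp$stacked, ae)
      features <- encode(model, pp$stacked)
    } else {
      nc <- if (is.null(n_components))
        ae$hidden_sizes[(length(ae$hidden_sizes) + 1L) %/% 2L] else
          n_components
      features <- suppressWarnings(pca_reduce(pp$stacked, nc))
    }
    screen <- screen_features_cox(features, surv, alpha = alpha)
    kept <- features[, screen$kept, drop = FALSE]
    selection <- select_k(kept, k_candidates = k_candidates, seed = seed)
    labels <- selection$labels[[as.character(selection$chosen_k)]]
    chosen_k <- selection$chosen_k
    report <- selection$report
  }
  assignment <- orient_risk_labels(labels, surv)
  evaluation <- evaluate_survival(
    stats::setNames(assignment$label, assignment$sample_ids), surv)
  structure(list(method = method, label = assignment$label,
                 assignment = assignment, evaluation = evaluation,
                 chosen_k = chosen_k, report = report, screen = screen,
                 features = features, model = model, preprocessed = pp,
                 survival = surv, seed = seed, ae = ae, alpha = alpha),
            class = "subtype_fit")
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat(sprintf("multiomics subtype fit (%s): %d samples, K = %d\n",
              x$method, length(x$label), x$chosen_k))
  print(table(x$label))
  cat(sprintf("log-rank p = %.3g, C-index = %.3f, Brier = %.3f\n",
              x$evaluation$logrank_p, x$evaluation$c_index,
              x$evaluation$brier_score))
  invisible(x)
}

#' @export
summary.subtype_fit <- function(object, ...) {
  cat(sprintf("Subgroup discovery by %s\n", object$method))
  if (!is.null(object$screen))
    cat(sprintf("Cox screening: %d / %d features kept at p <= %.2f\n",
                length(object$screen$kept), length(object$screen$p),
                object$screen$alpha))
  if (!is.null(object$report)) {
    cat("Cluster-number scan:\n")
    print(object$report, row.names = FALSE)
  }
  print(object$evaluation)
  invisible(object)
}

#' Kaplan-Meier plot of a subtype fit
#'
#' @param x a `subtype_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.subtype_fit <- function(x, ...) {
  km <- x$evaluation$km_curves
  cols <- seq_along(km) + 1L
  graphics::plot(NA, xlim = c(0, max(x$survival$time)), ylim = c(0, 1),
                 xlab = "days", ylab = "survival probability",
                 main = sprintf("%s subgroups (log-rank p = %.2g)",
                                x$method, x$evaluation$logrank_p), ...)
  for (i in seq_along(km))
    graphics::lines(km[[i]]$time, km[[i]]$surv, type = "s", col = cols[i],
                    lwd = 2)
  graphics::legend("topright", legend = names(km), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Compare discovery methods on one cohort
#'
#' Fits the autoencoder pipeline and the PCA and SNF alternatives on the
#' same preprocessed data and tabulates their survival separation.
#'
#' @inheritParams subtype_fit
#' @param ... passed on to [subtype_fit()].
#' @return a data frame with one row per method (method, k, logrank_p,
#'   c_index, brier), plus the fits in the `"fits"` attribute.
#' @export
compare_methods <- function(cohort, ae = ae_spec(), seed = 1L, ...) {
  pp <- preprocess_cohort(cohort)
  fits <- list(
    autoencoder = subtype_fit(cohort, "autoencoder", ae = ae, seed = seed,
                              preprocessed = pp, ...),
    pca = subtype_fit(cohort, "pca", ae = ae, seed = seed,
                      preprocessed = pp, ...),
    snf = subtype_fit(cohort, "snf", ae = ae, seed = seed,
                      preprocessed = pp, ...))
  out <- do.call(rbind, lapply(names(fits), function(m) {
    ev <- fits[[m]]$evaluation
    data.frame(method = m, k = fits[[m]]$chosen_k,
               logrank_p = ev$logrank_p, c_index = ev$c_index,
               brier = ev$brier_score)
  }))
  attr(out, "fits") <- fits
  out
}

# ANOVA-select per omics block, scale, and assemble the classifier matrix
# for the given sample set. Selection feature ids refer to layer columns.
build_classifier_matrix <- function(layers, ids, selected) {
  mats <- lapply(names(selected), function(nm) {
    l <- layers[[nm]]
    sc <- scale_for_classifier(
      keep_kind(as_bare_matrix(l)[ids, , drop = FALSE], l))
    as_bare_matrix(sc)[, selected[[nm]], drop = FALSE]
  })
  do.call(cbind, mats)
}

#' Internal validation by the CV-like plan
#'
#' For each of the 10 train/test fold combinations: retrain the
#' autoencoder on the training samples only (seed = `seed` + combo
#' index), rediscover training subgroups (Cox screening + k-means), select
#' the top ANOVA features per omics (default 50 mRNA, 30 miRNA, 50
#' methylation) on the independently scaled training layers, fit an
#' RBF-SVM on the stacked selected features, predict the test samples'
#' subgroup, and evaluate the survival separation of true-label training
#' groups and predicted test groups. Combinations whose training labels
#' collapse to one class are skipped with a warning.
#'
#' @param cohort a cohort accepted by [preprocess_cohort()] with
#'   `survival`.
#' @param ae an [ae_spec()] used for every per-combo autoencoder.
#' @param top_n named feature counts per omics layer.
#' @param cost_grid,gamma_grid SVM grids (see [fit_svm()]).
#' @param k number of clusters per combination. The validation verifies
#'   the discovered subgroup structure, so it inherits the discovery
#'   cluster number (default 2); set `k = NULL` to re-select K per
#'   combination over `k_candidates` instead.
#' @param k_candidates candidate cluster numbers, used when `k = NULL`.
#' @param omics_sets which feature sets to classify with: `"multi"`
#'   and/or single layer names (`"mrna"`, `"mirna"`, `"methylation"`).
#' @param seed base seed: fold plan and per-combo training.
#' @param alpha Cox screening threshold.
#' @param preprocessed optional precomputed `preprocessed_cohort`.
#' @return a list of class `validation_summary`: `per_combo` (data frame
#'   of per-combination metrics per omics set) and `summary` (per omics
#'   set and train/test: geometric-mean log-rank p, mean and sd of
#'   C-index and Brier).
#' @export
cross_validate <- function(cohort, ae = ae_spec(), top_n = c(
  mrna = 50L, mirna = 30L, methylation = 50L),
  cost_grid = 2^(-5:5), gamma_grid = 2^(-7:3),
  k = 2L, k_candidates = 2:6, omics_sets = "multi", seed = 1L,
  alpha = 0.10, preprocessed = NULL) {
  pp <- if (is.null(preprocessed)) preprocess_cohort(cohort) else
    preprocessed
  surv <- align_survival(cohort$survival, pp$sample_ids)
  plan <- make_cv_plan(pp$sample_ids, seed = seed)
  stacked <- as_bare_matrix(pp$stacked)
  rows <- list()
  for (i in seq_along(plan$combos)) {
    combo <- plan$combos[[i]]
    tr_ids <- names(plan$folds)[plan$folds %in% combo$train]
    te_ids <- names(plan$folds)[plan$folds %in% combo$test]
    tr_surv <- align_survival(surv, tr_ids)
    te_surv <- align_survival(surv, te_ids)
    ae_i <- ae
    ae_i$seed <- ae$seed + i
    res <- tryCatch({
      model <- suppressWarnings(
        train_autoencoder(stacked[tr_ids, , drop = FALSE], ae_i))
      bt <- encode(model, stacked[tr_ids, , drop = FALSE])
      screen <- screen_features_cox(bt, tr_surv, alpha = alpha)
      kept <- bt[, screen$kept, drop = FALSE]
      lab <- if (is.null(k)) {
        sel <- select_k(kept, k_candidates = k_candidates,
                        seed = seed + i)
        sel$labels[[as.character(sel$chosen_k)]]
      } else {
        kmeans_cluster(kept, k, seed = seed + i)
      }
      orient_risk_labels(lab, tr_surv)
    }, error = function(e) e)
    if (inherits(res, "error") ||
        length(unique(res$label)) < 2) {
      warning(sprintf("combo %d skipped: %s", i,
                      if (inherits(res, "error")) conditionMessage(res)
                      else "single-class training labels"))
      next
    }
    tr_lab <- stats::setNames(res$label, res$sample_ids)
    for (os in omics_sets) {
      lnames <- if (os == "multi") names(pp$layers) else os
      selected <- lapply(stats::setNames(lnames, lnames), function(nm) {
        sc <- scale_for_classifier(keep_kind(
          as_bare_matrix(pp$layers[[nm]])[tr_ids, , drop = FALSE],
          pp$layers[[nm]]))
        suppressWarnings(anova_select(sc, tr_lab[tr_ids],
                                      top_n = top_n[[nm]]))
      })
      xtr <- build_classifier_matrix(pp$layers, tr_ids, selected)
      xte <- build_classifier_matrix(pp$layers, te_ids, selected)
      svm <- fit_svm(xtr, tr_lab[tr_ids], cost_grid, gamma_grid,
                     seed = seed + i)
      pred <- stats::setNames(predict(svm, xte), te_ids)
      ev_tr <- tryCatch(evaluate_survival(tr_lab[tr_ids], tr_surv),
                        error = function(e) NULL)
      ev_te <- tryCatch(evaluate_survival(pred, te_surv),
                        error = function(e) NULL)
      if (is.null(ev_te) || is.null(ev_tr)) {
        warning(sprintf(
          "combo %d (%s): degenerate train or test grouping, skipped",
          i, os))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        combo = i, omics = os,
        train_logrank_p = ev_tr$logrank_p, train_c_index = ev_tr$c_index,
        train_brier = ev_tr$brier_score,
        test_logrank_p = ev_te$logrank_p, test_c_index = ev_te$c_index,
        test_brier = ev_te$brier_score)
    }
  }
  if (!length(rows)) stop("no CV combination produced a usable model")
  per_combo <- do.call(rbind, rows)
  summarize <- function(d) data.frame(
    omics = d$omics[1], n_combos = nrow(d),
    train_logrank_geomean_p = geometric_mean_p(d$train_logrank_p),
    train_c_index_mean = mean(d$train_c_index),
    train_c_index_sd = stats::sd(d$train_c_index),
    train_brier_mean = mean(d$train_brier),
    train_brier_sd = stats::sd(d$train_brier),
    test_logrank_geomean_p = geometric_mean_p(d$test_logrank_p),
    test_c_index_mean = mean(d$test_c_index),
    test_c_index_sd = stats::sd(d$test_c_index),
    test_brier_mean = mean(d$test_brier),
    test_brier_sd = stats::sd(d$test_brier))
  summ <- do.call(rbind, lapply(split(per_combo, per_combo$omics),
                                summarize))
  rownames(summ) <- NULL
  structure(list(per_combo = per_combo, summary = summ, plan = plan),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("CV-like internal validation (%d combinations)\n",
              length(unique(x$per_combo$combo))))
  d <- x$summary
  for (i in seq_len(nrow(d)))
    cat(sprintf(paste0("  %s test: log-rank geo-mean p = %.3g, ",
                       "C-index = %.3f +/- %.3f, Brier = %.3f +/- %.3f\n"),
                d$omics[i], d$test_logrank_geomean_p[i],
                d$test_c_index_mean[i], d$test_c_index_sd[i],
                d$test_brier_mean[i], d$test_brier_sd[i]))
  invisible(x)
}

#' Transfer discovered subgroup labels to an external expression cohort
#'
#' Restricts the discovery cohort's mRNA layer and the external
#' expression matrix to their common genes, selects the top `top_n` genes
#' by ANOVA against the discovered subgroup on the full (independently
#' scaled) discovery cohort, fits an RBF-SVM on the discovery samples and
#' predicts a subgroup label for every external sample. If external
#' survival data are supplied the transferred labels are evaluated.
#'
#' @param fit a `subtype_fit` from [subtype_fit()].
#' @param expression external `omics_matrix` (kind
#'   `expression_intensity`, samples x genes).
#' @param surv optional external survival data frame.
#' @param top_n number of mRNA features for the classifier (default 50;
#'   fewer common genes triggers a warning and uses all).
#' @param cost_grid,gamma_grid SVM grids.
#' @param seed RNG seed for the SVM grid search.
#' @return a list of class `label_transfer` with `labels` (factor per
#'   external sample), `genes` (classifier genes), `svm`, and
#'   `evaluation` (a `survival_evaluation`, or `NULL` without survival).
#' @export
transfer_labels <- function(fit, expression, surv = NULL, top_n = 50L,
                            cost_grid = 2^(-5:5), gamma_grid = 2^(-7:3),
                            seed = 1L) {
  stopifnot(inherits(fit, "subtype_fit"))
  disc <- fit$preprocessed$layers$mrna
  common <- intersect(feature_ids(disc), feature_ids(expression))
  if (!length(common)) stop("empty gene intersection with the discovery cohort")
  if (length(common) < top_n) {
    warning(sprintf("only %d common genes; using all of them",
                    length(common)))
    top_n <- length(common)
  }
  lab <- stats::setNames(fit$label, fit$assignment$sample_ids)
  disc_sc <- scale_for_classifier(
    keep_kind(as_bare_matrix(disc)[, common, drop = FALSE], disc))
  genes <- anova_select(disc_sc, lab, top_n = top_n)
  ext_sc <- scale_for_classifier(
    keep_kind(as_bare_matrix(expression)[, common, drop = FALSE],
              expression))
  svm <- fit_svm(as_bare_matrix(disc_sc)[, genes, drop = FALSE], lab,
                 cost_grid, gamma_grid, seed = seed)
  pred <- stats::setNames(
    predict(svm, as_bare_matrix(ext_sc)[, genes, drop = FALSE]),
    sample_ids(expression))
  ev <- if (!is.null(surv))
    evaluate_survival(pred, align_survival(surv, names(pred))) else NULL
  structure(list(labels = pred, genes = genes, svm = svm,
                 evaluation = ev),
            class = "label_transfer")
}

#' @export
predict.subtype_fit <- function(object, expression, surv = NULL, ...) {
  transfer_labels(object, expression, surv = surv, ...)
}
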