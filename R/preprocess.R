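#' Remove features with too many zero values
#'
#' For count layers, drops every feature whose fraction of zero values
#' exceeds `max_zero_frac` (default 0.2: a feature that is zero in more
#' than 20% of samples is excluded). Feature order is preserved.
#'
#' @param m an `omics_matrix` of kind `mrna_counts` or `mirna_counts`.
#' @param max_zero_frac maximum tolerated zero fraction per feature.
#' @return the filtered `omics_matrix`.
#' @export
filter_zero_features <- function(m, max_zero_frac = 0.2) {
  stopifnot(omics_kind(m) %in% c("mrna_counts", "mirna_counts"))
  frac <- colMeans(as_bare_matrix(m) == 0)
  keep <- frac <= max_zero_frac
  if (!any(keep))
    stop(sprintf("all features exceed the %.0f%% zero threshold",
                 100 * max_zero_frac))
  keep_kind(as_bare_matrix(m)[, keep, drop = FALSE], m)
}

#' Remove samples with too many zero values
#'
#' Applied after [filter_zero_features()]: drops samples whose zero
#' fraction across the remaining features exceeds `max_zero_frac`.
#'
#' @inheritParams filter_zero_features
#' @return the filtered `omics_matrix`.
#' @export
filter_zero_samples <- function(m, max_zero_frac = 0.2) {
  stopifnot(omics_kind(m) %in% c("mrna_counts", "mirna_counts"))
  frac <- rowMeans(as_bare_matrix(m) == 0)
  keep <- frac <= max_zero_frac
  if (!any(keep))
    stop(sprintf("all samples exceed the %.0f%% zero threshold",
                 100 * max_zero_frac))
  keep_kind(as_bare_matrix(m)[keep, , drop = FALSE], m)
}

#' Remove features, then samples, with too many missing values
#'
#' For promoter methylation: features missing in more than
#' `max_missing_frac` of samples are dropped first, then samples missing in
#' more than `max_missing_frac` of the remaining features.
#'
#' @param m an `omics_matrix` (kind `methylation_promoter` or
#'   `methylation_beta`).
#' @param max_missing_frac maximum tolerated missing fraction.
#' @param axis `"both"` (default, features then samples), `"features"`, or
#'   `"samples"`.
#' @return the filtered `omics_matrix`.
#' @export
filter_missing <- function(m, max_missing_frac = 0.2,
                           axis = c("both", "features", "samples")) {
  axis <- match.arg(axis)
  v <- as_bare_matrix(m)
  if (axis %in% c("both", "features")) {
    keep <- colMeans(is.na(v)) <= max_missing_frac
    if (!any(keep))
      stop(sprintf("all features exceed the %.0f%% missing threshold",
                   100 * max_missing_frac))
    v <- v[, keep, drop = FALSE]
  }
  if (axis %in% c("both", "samples")) {
    keep <- rowMeans(is.na(v)) <= max_missing_frac
    if (!any(keep))
      stop(sprintf("all samples exceed the %.0f%% missing threshold",
                   100 * max_missing_frac))
    v <- v[keep, , drop = FALSE]
  }
  keep_kind(v, m)
}

#' Aggregate CpG beta values over gene promoters
#'
#' The promoter is the 1500 bp immediately upstream of the transcription
#' start site, strand-aware and inclusive: \[TSS-window, TSS\] on the
#' + strand, \[TSS, TSS+window\] on the - strand (1-based coordinates).
#' Each gene with at least one in-window CpG gets one feature whose value
#' is the mean beta of its in-window CpGs; missing betas are excluded from
#' the mean, and a cell is missing only when all in-window CpGs are
#' missing. Genes without in-window CpGs are dropped.
#'
#' @param cpg an `omics_matrix` of kind `methylation_beta`.
#' @param cpg_ann data frame with columns `probe_id`, `chromosome`,
#'   `position`.
#' @param gene_ann data frame with columns `gene_id`, `chromosome`, `tss`,
#'   `strand`.
#' @param window_bp promoter window size upstream of the TSS.
#' @return an `omics_matrix` of kind `methylation_promoter` (samples x
#'   genes).
#' @export
aggregate_promoter_methylation <- function(cpg, cpg_ann, gene_ann,
                                           window_bp = 1500L) {
  stopifnot(omics_kind(cpg) == "methylation_beta")
  if (!nrow(cpg_ann) || !nrow(gene_ann)) stop("empty annotation table")
  if (any(gene_ann$tss < 1) || any(cpg_ann$position < 1))
    stop("annotation coordinates must be 1-based positive")
  if (!all(gene_ann$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  ann <- cpg_ann[cpg_ann$probe_id %in% feature_ids(cpg), , drop = FALSE]
  if (!nrow(ann)) stop("no annotated CpG probes present in the matrix")

  plus <- gene_ann$strand == "+"
  prom_start <- ifelse(plus, pmax(gene_ann$tss - window_bp, 1L),
                       gene_ann$tss)
  prom_end <- ifelse(plus, gene_ann$tss, gene_ann$tss + window_bp)
  promoters <- GenomicRanges::GRanges(
    seqnames = gene_ann$chromosome,
    ranges = IRanges::IRanges(start = prom_start, end = prom_end))
  probes <- GenomicRanges::GRanges(
    seqnames = ann$chromosome,
    ranges = IRanges::IRanges(start = ann$position, width = 1L))
  hits <- GenomicRanges::findOverlaps(probes, promoters)
  if (!length(hits)) stop("no CpG falls in any promoter window")

  v <- as_bare_matrix(cpg)[, ann$probe_id, drop = FALSE]
  pr <- S4Vectors::queryHits(hits)
  gn <- S4Vectors::subjectHits(hits)
  genes <- sort(unique(gn))
  out <- matrix(NA_real_, nrow(v), length(genes),
                dimnames = list(rownames(v), gene_ann$gene_id[genes]))
  grp <- split(pr, match(gn, genes))
  for (j in seq_along(genes)) {
    cols <- grp[[as.character(j)]]
    out[, j] <- rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  omics_matrix(out, "methylation_promoter")
}

#' K-nearest-feature imputation of missing values
#'
#' Each missing cell (sample s, feature f) is replaced by the mean, in
#' sample s, of the k features nearest to f in Euclidean distance computed
#' over co-observed samples (distances averaged per co-observed sample so
#' different overlaps are comparable). Features that have no co-observed
#' partner with an observed value in s fall back to the feature mean, with
#' a warning.
#'
#' @param m an `omics_matrix` with `NA` missing cells.
#' @param k number of neighbouring features.
#' @return the completed `omics_matrix` (no missing cells).
#' @export
knn_impute <- function(m, k = 10L) {
  v <- as_bare_matrix(m)
  miss_cols <- which(colSums(is.na(v)) > 0)
  if (!length(miss_cols)) return(m)
  fmean <- colMeans(v, na.rm = TRUE)
  fellback <- FALSE
  for (j in miss_cols) {
    dif <- v - v[, j]
    d2 <- colMeans(dif * dif, na.rm = TRUE)  # mean over co-observed samples
    d2[j] <- Inf
    miss_rows <- which(is.na(v[, j]))
    ord <- order(d2)
    for (i in miss_rows) {
      cand <- ord[!is.na(v[i, ord]) & is.finite(d2[ord])]
      if (!length(cand)) {
        v[i, j] <- fmean[j]
        fellback <- TRUE
      } else {
        v[i, j] <- mean(v[i, cand[seq_len(min(k, length(cand)))]])
      }
    }
  }
  if (fellback)
    warning("some cells had no co-observed neighbours; feature mean used")
  keep_kind(v, m)
}

#' Unit-scale each sample to l2 norm one
#'
#' Divides each sample row by its Euclidean norm so every sample lies on
#' the unit sphere. Zero rows are left at zero with a warning. `norm =
#' "l2sq"` divides by the squared norm instead (a variant some write-ups
#' print; it does not produce unit vectors and is off by default).
#'
#' @param m an `omics_matrix` without missing values.
#' @param norm `"l2"` (default) or `"l2sq"`.
#' @return the scaled `omics_matrix`.
#' @export
unit_scale_samples <- function(m, norm = c("l2", "l2sq")) {
  norm <- match.arg(norm)
  v <- as_bare_matrix(m)
  if (anyNA(v)) stop("unit_scale_samples: missing values present")
  nrm <- sqrt(rowSums(v * v))
  if (any(nrm == 0)) warning("zero-norm samples left unscaled")
  div <- ifelse(nrm == 0, 1, if (norm == "l2") nrm else nrm^2)
  keep_kind(v / div, m)
}

#' Median scale normalization
#'
#' Per feature: subtract the median and divide by the median absolute
#' deviation mad(x) = median(|x_i - median(x)|), without the 1.4826
#' normal-consistency constant. Features with mad 0 are divided by 1 and
#' flagged.
#'
#' @param m an `omics_matrix` without missing values (or a bare numeric
#'   matrix, samples x features).
#' @return list with `matrix` (same class as input) and `params` (data
#'   frame with per-feature `median`, `mad`, and a `flat` flag).
#' @export
median_scale <- function(m) {
  v <- if (inherits(m, "omics_matrix")) as_bare_matrix(m) else m
  if (anyNA(v)) stop("median_scale: missing values present")
  med <- apply(v, 2, stats::median)
  mad0 <- apply(sweep(v, 2, med), 2, function(z) stats::median(abs(z)))
  flat <- mad0 == 0
  out <- sweep(sweep(v, 2, med), 2, ifelse(flat, 1, mad0), "/")
  params <- data.frame(feature = colnames(v), median = med, mad = mad0,
                       flat = flat, row.names = NULL)
  # standardized values are no longer counts or betas
  list(matrix = if (inherits(m, "omics_matrix")) omics_matrix(out, "latent")
       else out,
       params = params)
}

#' Robust (interquartile-trimmed) scale normalization
#'
#' Per feature: center by the mean of the values lying between the 25th and
#' 75th percentiles (inclusive) and divide by the standard deviation of
#' that same trimmed set. A trimmed sd of 0 divides by 1 and flags the
#' feature; a trimmed set with fewer than 2 values falls back to the full
#' mean/sd with a warning.
#'
#' @inheritParams median_scale
#' @return list with `matrix` and `params` (per-feature `trimmed_mean`,
#'   `trimmed_sd`, `flat` flag).
#' @export
robust_scale <- function(m) {
  v <- if (inherits(m, "omics_matrix")) as_bare_matrix(m) else m
  if (anyNA(v)) stop("robust_scale: missing values present")
  fellback <- FALSE
  st <- apply(v, 2, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    tr <- x[x >= q[1] & x <= q[2]]
    if (length(tr) < 2) {
      fellback <<- TRUE
      tr <- x
    }
    c(mean(tr), stats::sd(tr))
  })
  if (fellback)
    warning("trimmed set smaller than 2; full mean/sd used for some features")
  mu <- st[1, ]
  sdv <- st[2, ]
  flat <- !is.finite(sdv) | sdv == 0
  out <- sweep(sweep(v, 2, mu), 2, ifelse(flat, 1, sdv), "/")
  params <- data.frame(feature = colnames(v), trimmed_mean = mu,
                       trimmed_sd = ifelse(is.finite(sdv), sdv, 0),
                       flat = flat, row.names = NULL)
  list(matrix = if (inherits(m, "omics_matrix")) omics_matrix(out, "latent")
       else out,
       params = params)
}

#' Collapse array probes to gene symbols by averaging
#'
#' For expression-intensity matrices: each gene's value is the mean of its
#' probes; probes without a mapping are dropped.
#'
#' @param m an `omics_matrix` of kind `expression_intensity` with probe
#'   feature ids.
#' @param probe_to_gene named character vector mapping probe id to gene
#'   symbol.
#' @return an `omics_matrix` with one feature per gene symbol.
#' @export
collapse_probes_to_genes <- function(m, probe_to_gene) {
  stopifnot(omics_kind(m) == "expression_intensity")
  if (!length(probe_to_gene)) stop("empty probe-to-gene mapping")
  v <- as_bare_matrix(m)
  mapped <- intersect(colnames(v), names(probe_to_gene))
  if (!length(mapped)) stop("no probes map to any gene")
  v <- v[, mapped, drop = FALSE]
  genes <- probe_to_gene[mapped]
  agg <- t(rowsum(t(v), group = genes) / as.vector(table(genes)[
    sort(unique(genes))]))
  keep_kind(agg, m)
}
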