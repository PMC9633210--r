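#' Construct an omics matrix
#'
#' A light container for a samples-by-features numeric matrix tagged with the
#' omics kind it carries. Sample identifiers live in the rownames, feature
#' identifiers in the colnames; missing values are `NA`. Methylation kinds
#' must have non-missing values in \[0, 1\].
#'
#' @param values numeric matrix, samples in rows, features in columns; must
#'   have unique, non-empty row and column names.
#' @param kind one of `"mrna_counts"`, `"mirna_counts"`, `"methylation_beta"`,
#'   `"methylation_promoter"`, `"expression_intensity"`, `"latent"`.
#' @return an object of class `omics_matrix` (a matrix with a `kind`
#'   attribute).
#' @export
omics_matrix <- function(values, kind) {
  kinds <- c("mrna_counts", "mirna_counts", "methylation_beta",
             "methylation_promoter", "expression_intensity", "latent")
  kind <- match.arg(kind, kinds)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample rownames and feature colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature identifiers")
  if (kind %in% c("methylation_beta", "methylation_promoter")) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("methylation values must lie in [0, 1]")
  }
  structure(values, kind = kind, class = c("omics_matrix", class(values)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d samples x %d features", omics_kind(x),
              nrow(x), ncol(x)))
  nmiss <- sum(is.na(x))
  if (nmiss > 0) cat(sprintf(", %d missing cells", nmiss))
  cat("\n")
  invisible(x)
}

#' Omics kind of a matrix
#' @param m an `omics_matrix` (or any matrix with a `kind` attribute).
#' @return character scalar.
#' @export
omics_kind <- function(m) {
  k <- attr(m, "kind")
  if (is.null(k)) stop("matrix has no omics kind")
  k
}

# rebuild after subsetting (base "[" drops attributes)
keep_kind <- function(values, template) {
  omics_matrix(values, omics_kind(template))
}

sample_ids <- function(m) rownames(m)
feature_ids <- function(m) colnames(m)

as_bare_matrix <- function(m) {
  attr(m, "kind") <- NULL
  class(m) <- "matrix"
  unclass(m)
}

#' Stack omics layers into one feature matrix
#'
#' Inner-joins the layers on sample identifiers (ordered as in the first
#' layer, restricted to the common samples) and concatenates their features.
#' Feature identifiers are prefixed with the layer kind so downstream steps
#' can recover per-omics blocks; the block structure is retained in the
#' `"blocks"` attribute (a named list of column index vectors).
#'
#' @param ms list of `omics_matrix` objects with overlapping samples.
#' @return an `omics_matrix` of kind `"latent"`-agnostic stacked values with
#'   a `blocks` attribute.
#' @export
stack_omics <- function(ms) {
  if (!length(ms)) stop("need at least one omics matrix")
  ids <- Reduce(intersect, lapply(ms, sample_ids))
  if (!length(ids)) stop("no samples shared across omics layers")
  ids <- sample_ids(ms[[1]])[sample_ids(ms[[1]]) %in% ids]
  blocks <- list()
  out <- NULL
  at <- 0L
  for (m in ms) {
    k <- omics_kind(m)
    v <- as_bare_matrix(m)[ids, , drop = FALSE]
    colnames(v) <- paste(k, colnames(v), sep = "|")
    nm <- k
    while (nm %in% names(blocks)) nm <- paste0(nm, "+")
    blocks[[nm]] <- at + seq_len(ncol(v))
    at <- at + ncol(v)
    out <- if (is.null(out)) v else cbind(out, v)
  }
  res <- omics_matrix(out, "latent")
  attr(res, "blocks") <- blocks
  res
}

#' Per-omics blocks of a stacked matrix
#' @param m a matrix produced by [stack_omics()].
#' @return named list of column indices.
#' @export
omics_blocks <- function(m) {
  b <- attr(m, "blocks")
  if (is.null(b)) stop("matrix has no omics block structure")
  b
}
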