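#' Median-of-ratios size factors
#'
#' Per-sample normalization factors for count matrices: each sample's
#' factor is the median across genes of the ratio of its count to the
#' gene's geometric mean, computed over genes with positive counts in all
#' samples.
#'
#' @param counts an `omics_matrix` of counts (samples x genes) or bare
#'   matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  v <- if (inherits(counts, "omics_matrix")) as_bare_matrix(counts) else
    counts
  if (any(v < 0)) stop("counts must be nonnegative")
  allpos <- colSums(v == 0) == 0
  if (!any(allpos))
    stop(paste("no gene has positive counts in all samples;",
               "consider a pseudo-reference"))
  lv <- log(v[, allpos, drop = FALSE])
  ref <- colMeans(lv)                  # log of the gene-wise geometric mean
  # median of ratios, taken on the log scale (the reference semantics)
  sf <- exp(apply(sweep(lv, 2, ref), 1, stats::median))
  names(sf) <- rownames(v)
  sf
}

#' Two-group differential analysis of counts
#'
#' Size-factor-normalized counts are log2(x + 1) transformed; each gene
#' gets a Welch t-test between the two groups, a log2 fold change equal
#' to the difference of group means on that scale, BH-adjusted p-values,
#' and a significance call at |log2FC| > `lfc_threshold` and FDR <
#' `fdr_threshold`.
#'
#' @param counts an `omics_matrix` of counts (samples x genes).
#' @param labels two-group labels named by (or ordered as) the samples.
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @param fdr_threshold BH FDR cutoff (default 0.05).
#' @return data frame with columns `feature`, `log2fc`, `stat`, `p`,
#'   `fdr`, `significant`.
#' @export
de_counts <- function(counts, labels, lfc_threshold = 1,
                      fdr_threshold = 0.05) {
  v <- if (inherits(counts, "omics_matrix")) as_bare_matrix(counts) else
    counts
  f <- droplevels(factor(labels))
  if (nlevels(f) != 2) stop("de_counts needs exactly two groups")
  if (any(table(f) < 2)) stop("each group needs at least two samples")
  sf <- size_factors(v)
  lv <- log2(sweep(v, 1, sf, "/") + 1)
  i1 <- f == levels(f)[1]
  i2 <- f == levels(f)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- colMeans(lv[i1, , drop = FALSE])
  m2 <- colMeans(lv[i2, , drop = FALSE])
  v1 <- apply(lv[i1, , drop = FALSE], 2, stats::var)
  v2 <- apply(lv[i2, , drop = FALSE], 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  stat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * stats::pt(-abs(stat), df = df)
  p[se2 == 0] <- 1
  fdr <- bh_fdr(p)
  log2fc <- m2 - m1
  data.frame(feature = colnames(v), log2fc = log2fc, stat = stat, p = p,
             fdr = fdr,
             significant = abs(log2fc) > lfc_threshold &
               fdr < fdr_threshold,
             row.names = NULL)
}

#' Convert methylation beta values to M values
#'
#' M = log2(beta / (1 - beta)); betas are clipped to
#' \[eps, 1 - eps\] first so boundary values stay finite.
#'
#' @param beta numeric vector/matrix of beta values.
#' @param eps clipping bound (default 1e-6).
#' @return M values with the same shape.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

# Newton inversion of the trigamma function (for the EB prior df fit)
trigamma_inverse <- function(x) {
  vapply(x, function(xx) {
    if (!is.finite(xx) || xx <= 0) return(Inf)
    y <- 0.5 + 1 / xx
    for (it in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xx) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderated t-test for two groups
#'
#' Per-feature two-group comparison with variance shrinkage: the residual
#' variances s^2 (pooled, d = n - 2 df) are modeled as scaled-F draws
#' around a prior variance s0^2 with d0 prior df, estimated by moment
#' matching on log s^2 (mean and variance of log s^2 against the
#' digamma/trigamma moments of the scaled-F). Posterior variances
#' s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d) give moderated t statistics
#' on d0 + d degrees of freedom. `prior_df` overrides the estimate:
#' 0 recovers the ordinary t-test, `Inf` fully pools to s0^2.
#'
#' @param m_values an `omics_matrix` or matrix (samples x features), e.g.
#'   M values from [beta_to_m()].
#' @param labels two-group labels.
#' @param prior_df optional fixed prior degrees of freedom.
#' @param diff_threshold absolute group-difference cutoff for the
#'   significance call (default 1, i.e. |M difference| > 1).
#' @param fdr_threshold BH FDR cutoff (default 0.05).
#' @return data frame with `feature`, `m_diff`, `stat`, `df`, `p`, `fdr`,
#'   `significant`, plus `d0` and `s0_sq` as attributes.
#' @export
moderated_t <- function(m_values, labels, prior_df = NULL,
                        diff_threshold = 1, fdr_threshold = 0.05) {
  v <- if (inherits(m_values, "omics_matrix")) as_bare_matrix(m_values)
  else m_values
  f <- droplevels(factor(labels))
  if (nlevels(f) != 2) stop("moderated_t needs exactly two groups")
  n1 <- sum(f == levels(f)[1]); n2 <- sum(f == levels(f)[2])
  if (min(n1, n2) < 2) stop("each group needs at least two samples")
  d <- n1 + n2 - 2
  if (d < 1) stop("zero residual degrees of freedom")
  i1 <- f == levels(f)[1]
  m1 <- colMeans(v[i1, , drop = FALSE])
  m2 <- colMeans(v[!i1, , drop = FALSE])
  ss1 <- colSums(sweep(v[i1, , drop = FALSE], 2, m1)^2)
  ss2 <- colSums(sweep(v[!i1, , drop = FALSE], 2, m2)^2)
  s2 <- (ss1 + ss2) / d
  s2_pos <- pmax(s2, 1e-12)
  if (is.null(prior_df)) {
    # moment matching of log s^2 ~ log(s0^2 F(d, d0))
    z <- log(s2_pos)
    e <- z - digamma(d / 2) + log(d / 2)
    ev <- mean(e)
    vz <- stats::var(z)
    excess <- vz - trigamma(d / 2)
    if (is.finite(excess) && excess > 0) {
      d0 <- 2 * trigamma_inverse(excess)
      s0_sq <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(ev)
    }
  } else {
    d0 <- prior_df
    s0_sq <- exp(mean(log(s2_pos)))
  }
  if (is.infinite(d0)) {
    s_tilde2 <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s_tilde2 <- s2
    df_total <- rep(d, length(s2))
  } else {
    s_tilde2 <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- rep(d0 + d, length(s2))
  }
  sed <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  m_diff <- m2 - m1
  stat <- ifelse(sed > 0, m_diff / sed, 0)
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(stat)),
              2 * stats::pt(-abs(stat), df = df_total))
  p[sed == 0] <- 1
  fdr <- bh_fdr(p)
  out <- data.frame(feature = colnames(v), m_diff = m_diff, stat = stat,
                    df = df_total, p = p, fdr = fdr,
                    significant = abs(m_diff) > diff_threshold &
                      fdr < fdr_threshold,
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
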