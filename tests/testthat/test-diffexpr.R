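count_matrix <- function(v) {
  dimnames(v) <- list(sprintf("s%02d", seq_len(nrow(v))),
                      sprintf("g%03d", seq_len(ncol(v))))
  omics_matrix(v, "mrna_counts")
}

test_that("size factors are median-of-ratios and absorb library scaling", {
  set.seed(61)
  # odd gene count: the ratio-scale and log-scale medians coincide exactly
  v <- matrix(rnbinom(10 * 21, mu = 50, size = 5) + 1, 10, 21)
  m <- count_matrix(v)
  sf <- size_factors(m)
  # a sample with exactly doubled counts gets exactly double the factor
  v2 <- rbind(v, v[1, ] * 2)
  sf2 <- size_factors(count_matrix(v2))
  expect_equal(unname(sf2[11] / sf2[1]), 2, tolerance = 1e-12)
  # identical samples get identical factors
  v3 <- matrix(rep(v[1, ], each = 4), 4, 21)
  sf3 <- unname(size_factors(count_matrix(v3)))
  expect_true(all(sf3 == sf3[1]))
  # direct-formula oracle: median of count/reference ratios per sample
  ref <- exp(colMeans(log(v)))
  oracle <- apply(sweep(v, 2, ref, "/"), 1, median)
  expect_equal(unname(sf), unname(oracle))
  # cross-check against the reference implementation
  ext <- DESeq2::estimateSizeFactorsForMatrix(t(v))
  expect_equal(unname(sf), unname(ext), tolerance = 1e-8)
  # all-zero-containing genes only: error
  vz <- v
  vz[cbind(rep(1:10, length.out = 21), 1:21)] <- 0  # a zero in every gene
  expect_error(size_factors(count_matrix(vz)), "positive")
})

test_that("count DE finds true fold changes and respects the null", {
  set.seed(62)
  n <- 40
  lab <- rep(c("a", "b"), each = n / 2)
  mu <- exp(rnorm(100, 4, 1))
  delta <- c(rep(2, 10), rep(0, 90))  # 10 genes at 4-fold
  mumat <- exp(log(matrix(mu, n, 100, byrow = TRUE)) +
                 outer(as.integer(lab == "b"), delta))
  v <- matrix(rnbinom(n * 100, mu = mumat, size = 10), n, 100)
  de <- de_counts(count_matrix(v), lab)
  expect_true(all(c("feature", "log2fc", "stat", "p", "fdr",
                    "significant") %in% names(de)))
  # most of the true 4-fold genes are called
  expect_gte(mean(de$significant[1:10]), 0.8)
  # significance is invariant to rescaling one sample's library
  v2 <- v
  v2[5, ] <- v2[5, ] * 3
  de2 <- de_counts(count_matrix(v2), lab)
  expect_equal(de$significant, de2$significant)
  # identical groups: nothing significant for a flat gene
  vflat <- v
  vflat[, 50] <- rep(c(30, 40), n / 2)
  deflat <- de_counts(count_matrix(vflat), lab)
  expect_equal(deflat$log2fc[50], 0, tolerance = 0.2)
  expect_false(deflat$significant[50])
  expect_error(de_counts(count_matrix(v), rep("a", n)), "two groups")
})

test_that("null labels keep the FDR in check", {
  set.seed(63)
  calls <- vapply(1:20, function(r) {
    v <- matrix(rnbinom(30 * 80, mu = 60, size = 8), 30, 80)
    lab <- sample(rep(c("a", "b"), 15))
    mean(de_counts(count_matrix(v), lab)$fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(calls), 0.05)
})

test_that("beta/M transform matches its closed form and inverts", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  set.seed(64)
  b <- runif(200, 0.01, 0.99)
  m <- beta_to_m(b)
  back <- 2^m / (1 + 2^m)
  expect_lt(max(abs(back - b)), 1e-9)
  # boundary values are clipped, not infinite
  expect_true(is.finite(beta_to_m(0)))
  expect_true(is.finite(beta_to_m(1)))
})

test_that("moderated t has the right limits and matches limma", {
  set.seed(65)
  n <- 12
  lab <- rep(c("a", "b"), each = n / 2)
  v <- matrix(rnorm(n * 150), n, 150,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%03d", 1:150)))
  v[lab == "b", 1:10] <- v[lab == "b", 1:10] + 2
  # d0 = 0: exactly the ordinary pooled t statistic
  raw <- moderated_t(v, lab, prior_df = 0)
  ordinary <- vapply(seq_len(ncol(v)), function(j) {
    unname(t.test(v[lab == "b", j], v[lab == "a", j],
                  var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_lt(max(abs(raw$stat - ordinary)), 1e-10)
  # d0 = Inf: every feature shares the pooled prior variance
  full <- moderated_t(v, lab, prior_df = Inf)
  sed <- full$m_diff / full$stat
  expect_lt(diff(range(sed[is.finite(sed)])), 1e-10)
  # EB fit agrees with limma's moderated statistics
  mod <- moderated_t(v, lab)
  design <- model.matrix(~ factor(lab))
  lf <- limma::eBayes(limma::lmFit(t(v), design))
  expect_gt(cor(mod$stat, lf$t[, 2]), 0.999)
  expect_gt(cor(-log10(mod$p), -log10(lf$p.value[, 2])), 0.999)
})

test_that("the EB prior df estimate recovers a known variance prior", {
  set.seed(66)
  n <- 10
  d0_true <- 8
  s0 <- 1.5
  lab <- rep(c("a", "b"), each = n / 2)
  vars <- s0^2 * d0_true / rchisq(200, df = d0_true)
  v <- sapply(vars, function(s2) rnorm(n, sd = sqrt(s2)))
  dimnames(v) <- list(sprintf("s%02d", 1:n), sprintf("f%03d", 1:200))
  fit <- moderated_t(v, lab)
  d0_hat <- attr(fit, "d0")
  expect_gt(d0_hat, d0_true / 2)
  expect_lt(d0_hat, d0_true * 2)
})

test_that("BH adjustment matches the exhaustive step-up oracle", {
  # single p is unchanged
  expect_equal(bh_fdr(0.031), 0.031)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # step-up oracle over a grid of p-vectors of length <= 5
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    prev <- 1
    for (i in rev(seq_len(n))) {
      val <- min(prev, n * p[o[i]] / i)
      adj[o[i]] <- val
      prev <- val
    }
    adj
  }
  grid <- c(0.001, 0.01, 0.04, 0.2, 0.5, 0.9)
  set.seed(67)
  for (len in 1:5) {
    for (rep in 1:30) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_fdr(p), bh_oracle(p))
    }
  }
  # adjusted values stay in [0, 1] and are monotone in the sorted order
  p <- runif(50)
  a <- bh_fdr(p)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.1, NA)), "finite")
})
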