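make_counts <- function(v, kind = "mrna_counts") {
  omics_matrix(v, kind)
}

test_that("zero-fraction feature filter drops exactly the right features", {
  # 6 samples x 6 features with per-feature zero counts 0,1,1,2,3,4
  set.seed(1)
  v <- matrix(rpois(36, 10) + 1, 6, 6,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:6)))
  zeros <- c(0, 1, 1, 2, 3, 4)
  for (j in 1:6) if (zeros[j] > 0) v[seq_len(zeros[j]), j] <- 0
  m <- make_counts(v)
  out <- filter_zero_features(m, 0.2)
  expect_identical(colnames(out), c("f1", "f2", "f3"))
  # threshold 1 is vacuous
  expect_identical(dim(filter_zero_features(m, 1)), dim(m))
  # removing everything errors with the threshold named
  allz <- make_counts(matrix(0, 3, 2, dimnames = list(letters[1:3], c("x", "y"))))
  expect_error(filter_zero_features(allz, 0.2), "20%")
})

test_that("zero-fraction sample filter follows the feature filter contract", {
  set.seed(2)
  v <- matrix(rpois(60, 10) + 1, 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  zeros <- c(0, 1, 2, 3, 0, 5)
  for (i in 1:6) if (zeros[i] > 0) v[i, seq_len(zeros[i])] <- 0
  out <- filter_zero_samples(make_counts(v), 0.2)
  expect_identical(rownames(out), c("s1", "s2", "s3", "s5"))
  # all-zero sample goes, clean matrix unchanged
  v2 <- v; v2[2, ] <- 0
  expect_false("s2" %in% rownames(filter_zero_samples(make_counts(v2), 0.2)))
  clean <- make_counts(matrix(1:12, 3, 4, dimnames = list(letters[1:3],
                                                          LETTERS[1:4])))
  expect_identical(dim(filter_zero_samples(clean, 0.2)), c(3L, 4L))
})

test_that("missing-value filter removes features then samples", {
  set.seed(3)
  v <- matrix(runif(25), 5, 5,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:5)))
  miss <- c(0, 1, 1, 2, 3)
  for (j in 1:5) if (miss[j] > 0) v[seq_len(miss[j]), j] <- NA
  m <- omics_matrix(v, "methylation_promoter")
  out <- filter_missing(m, 0.2)
  expect_identical(colnames(out), c("g1", "g2", "g3"))
  # no missing -> unchanged
  full <- omics_matrix(matrix(runif(20), 4, 5,
                              dimnames = list(paste0("s", 1:4),
                                              paste0("g", 1:5))),
                       "methylation_promoter")
  expect_identical(dim(filter_missing(full, 0.2)), c(4L, 5L))
})

test_that("filters are idempotent", {
  co <- small_cohort
  once <- filter_zero_samples(filter_zero_features(co$mrna, 0.2), 0.2)
  twice <- filter_zero_samples(filter_zero_features(once, 0.2), 0.2)
  expect_identical(unclass(once), unclass(twice))
})

test_that("promoter aggregation is strand-aware and averages in-window CpGs", {
  betas <- matrix(c(0.2, 0.4, 0.9, 0.1,
                    0.6, 0.8, 0.5, 0.3), 2, 4, byrow = TRUE,
                  dimnames = list(c("s1", "s2"),
                                  c("cgA", "cgB", "cgC", "cgD")))
  cpg_ann <- data.frame(probe_id = c("cgA", "cgB", "cgC", "cgD"),
                        chromosome = "chr1",
                        position = c(8700, 9900, 11400, 20000))
  gene_ann <- data.frame(gene_id = c("gPlus", "gMinus"),
                         chromosome = "chr1", tss = c(10000, 10000),
                         strand = c("+", "-"))
  out <- aggregate_promoter_methylation(
    omics_matrix(betas, "methylation_beta"), cpg_ann, gene_ann)
  # + strand window [8500, 10000]: cgA and cgB -> mean(0.2, 0.4) = 0.3
  expect_equal(out["s1", "gPlus"], 0.3)
  # - strand window [10000, 11500]: cgC only; cgA/cgB excluded
  expect_equal(out["s1", "gMinus"], 0.9)
  expect_equal(out["s2", "gMinus"], 0.5)
  expect_false("cgD" %in% colnames(out))
  expect_error(aggregate_promoter_methylation(
    omics_matrix(betas, "methylation_beta"), cpg_ann[0, ], gene_ann),
    "empty")
})

test_that("promoter aggregation matches a brute-force position scan", {
  co <- small_cohort
  out <- aggregate_promoter_methylation(co$methylation_cpg,
                                        co$cpg_annotation,
                                        co$gene_annotation)
  # independent oracle: scan every CpG position per gene
  v <- unclass(co$methylation_cpg)
  for (g in sample(colnames(out), 25)) {
    ga <- co$gene_annotation[co$gene_annotation$gene_id == g, ]
    lo <- if (ga$strand == "+") ga$tss - 1500 else ga$tss
    hi <- if (ga$strand == "+") ga$tss else ga$tss + 1500
    inwin <- co$cpg_annotation$chromosome == ga$chromosome &
      co$cpg_annotation$position >= lo & co$cpg_annotation$position <= hi
    probes <- co$cpg_annotation$probe_id[inwin]
    oracle <- rowMeans(v[, probes, drop = FALSE], na.rm = TRUE)
    oracle[is.nan(oracle)] <- NA_real_
    expect_equal(unname(out[, g]), unname(oracle))
  }
})

test_that("knn imputation fills cells sensibly", {
  set.seed(4)
  base <- matrix(runif(100, 0.2, 0.8), 10, 10,
                 dimnames = list(paste0("s", 1:10), paste0("g", 1:10)))
  m <- omics_matrix(base, "methylation_promoter")
  expect_identical(unclass(knn_impute(m)), unclass(m))  # nothing to do
  # a perfect duplicate feature is the nearest neighbour at k = 1
  v <- base
  v[, 2] <- v[, 1]
  v[3, 1] <- NA
  imp <- knn_impute(omics_matrix(v, "methylation_promoter"), k = 1)
  expect_equal(imp[3, 1], v[3, 2])
  expect_false(anyNA(imp))
})

test_that("knn imputation beats column-mean imputation on correlated data", {
  set.seed(5)
  n <- 60; p <- 40
  latent <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(rnorm(3 * p), 3, p)
  x <- plogis(latent %*% load + rnorm(n * p, sd = 0.3))
  dimnames(x) <- list(paste0("s", 1:n), paste0("g", 1:p))
  mask <- matrix(runif(n * p) < 0.05, n, p)
  xm <- x; xm[mask] <- NA
  imp <- knn_impute(omics_matrix(xm, "methylation_promoter"), k = 10)
  colmean <- xm
  for (j in seq_len(p)) colmean[is.na(xm[, j]), j] <- mean(xm[, j], na.rm = TRUE)
  rmse <- function(a) sqrt(mean((a[mask] - x[mask])^2))
  expect_lt(rmse(imp), rmse(colmean))
})

test_that("sample unit scaling produces unit rows (and the printed variant)", {
  v <- matrix(c(3, 4, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("f1", "f2")))
  m <- omics_matrix(v, "mrna_counts")
  out <- unit_scale_samples(m)
  expect_equal(unname(out["a", ]), c(0.6, 0.8))
  expect_equal(unname(out["b", ]), c(0, 1))
  # already unit-norm row is unchanged
  expect_equal(unclass(unit_scale_samples(out)), unclass(out))
  # squared-norm variant
  sq <- unit_scale_samples(m, norm = "l2sq")
  expect_equal(unname(sq["a", ]), c(3, 4) / 25)
  # random rows end up with l2 norm 1 to near machine precision
  set.seed(6)
  r <- omics_matrix(matrix(rnorm(50), 5, 10,
                           dimnames = list(paste0("s", 1:5),
                                           paste0("f", 1:10))),
                    "latent")
  expect_lt(max(abs(sqrt(rowSums(unit_scale_samples(r)^2)) - 1)), 1e-12)
  zr <- omics_matrix(matrix(0, 1, 3, dimnames = list("z", letters[1:3])),
                     "mrna_counts")
  expect_warning(unit_scale_samples(zr), "zero")
})

test_that("median scaling centers at median 0 and mad 1", {
  v <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
              dimnames = list(paste0("s", 1:3), c("f", "const")))
  out <- median_scale(v)
  expect_equal(unname(out$matrix[, "f"]), c(-1, 0, 1))
  expect_equal(unname(out$matrix[, "const"]), c(0, 0, 0))
  expect_true(out$params$flat[out$params$feature == "const"])
  set.seed(7)
  r <- matrix(rnorm(200, 5, 3), 50, 4,
              dimnames = list(paste0("s", 1:50), paste0("f", 1:4)))
  sc <- median_scale(r)$matrix
  expect_lt(max(abs(apply(sc, 2, median))), 1e-12)
  expect_lt(max(abs(apply(sc, 2, function(z)
    median(abs(z - median(z)))) - 1)), 1e-12)
})

test_that("robust scaling matches brute-force trimmed statistics", {
  v <- matrix(c(1, 2, 3, 4, 100), 5, 1,
              dimnames = list(paste0("s", 1:5), "f"))
  out <- robust_scale(v)$matrix
  # trimmed set excludes the outlier; it maps far into the positive tail
  expect_equal(unname(out[1:4, 1]), c(-2, -1, 0, 1))
  expect_gt(out[5, 1], 10)
  set.seed(8)
  r <- matrix(rnorm(300, 2, 4), 60, 5,
              dimnames = list(paste0("s", 1:60), paste0("f", 1:5)))
  got <- robust_scale(r)$matrix
  for (j in 1:5) {
    q <- quantile(r[, j], c(0.25, 0.75), names = FALSE)
    tr <- r[r[, j] >= q[1] & r[, j] <= q[2], j]
    expect_equal(unname(got[, j]), unname((r[, j] - mean(tr)) / sd(tr)))
  }
})

test_that("scalers are invariant to positive rescaling of the input", {
  set.seed(9)
  r <- matrix(rexp(120), 30, 4,
              dimnames = list(paste0("s", 1:30), paste0("f", 1:4)))
  expect_equal(median_scale(r * 7)$matrix, median_scale(r)$matrix)
  expect_equal(robust_scale(r * 7)$matrix, robust_scale(r)$matrix)
})

test_that("probe collapse averages probes per gene symbol", {
  v <- matrix(c(2, 4, 10, 1, 3, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
  m <- omics_matrix(v, "expression_intensity")
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  out <- collapse_probes_to_genes(m, map)
  expect_equal(out["s1", "gA"], 3)
  expect_equal(out["s2", "gA"], 2)
  expect_equal(out["s1", "gB"], 10)
  # one-to-one mapping renames only
  one <- collapse_probes_to_genes(m, c(p1 = "x", p2 = "y", p3 = "z"))
  expect_equal(unname(unclass(one)), unname(v), ignore_attr = TRUE)
  expect_error(collapse_probes_to_genes(m, character(0)), "empty")
  # many-to-one equals a group-by-mean oracle
  set.seed(10)
  big <- omics_matrix(matrix(rnorm(80), 4, 20,
                             dimnames = list(paste0("s", 1:4),
                                             paste0("p", 1:20))),
                      "expression_intensity")
  map2 <- setNames(paste0("g", sample(1:6, 20, TRUE)), paste0("p", 1:20))
  out2 <- collapse_probes_to_genes(big, map2)
  for (g in unique(map2)) {
    probes <- names(map2)[map2 == g]
    expect_equal(unname(out2[, g]),
                 unname(rowMeans(unclass(big)[, probes, drop = FALSE])))
  }
})

test_that("stacking joins on sample ids and keeps block provenance", {
  a <- omics_matrix(matrix(1:6, 2, 3,
                           dimnames = list(c("s1", "s2"),
                                           paste0("a", 1:3))),
                    "mrna_counts")
  b <- omics_matrix(matrix(7:10, 2, 2,
                           dimnames = list(c("s2", "s1"),
                                           paste0("b", 1:2))),
                    "mirna_counts")
  st <- stack_omics(list(a, b))
  expect_equal(ncol(st), 5)
  expect_identical(rownames(st), c("s1", "s2"))
  # rows align by id even though b's order differed
  expect_equal(unname(st["s1", 4:5]), unname(unclass(b)["s1", ]))
  expect_equal(unname(st["s2", 4:5]), unname(unclass(b)["s2", ]))
  blocks <- omics_blocks(st)
  expect_identical(names(blocks), c("mrna_counts", "mirna_counts"))
  disj <- omics_matrix(matrix(1:4, 2, 2,
                              dimnames = list(c("x1", "x2"), c("c1", "c2"))),
                       "mrna_counts")
  expect_error(stack_omics(list(a, disj)), "shared")
})
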