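surv_df <- function(time, event, ids = sprintf("s%02d", seq_along(time))) {
  data.frame(sample_id = ids, time = time, event = event)
}

test_that("Kaplan-Meier matches closed forms and hand computation", {
  # no events: flat at 1
  s0 <- surv_df(c(5, 6, 7), c(0, 0, 0))
  km0 <- kaplan_meier(s0, setNames(rep("g", 3), s0$sample_id))
  expect_true(all(km0$g$surv == 1))
  # four uncensored events: steps 0.75, 0.5, 0.25, 0
  s1 <- surv_df(1:4, rep(1, 4))
  km1 <- kaplan_meier(s1, setNames(rep("g", 4), s1$sample_id))$g
  expect_equal(km1$surv[km1$time %in% 1:4], c(0.75, 0.5, 0.25, 0))
  expect_equal(km1$surv[km1$time == 0], 1)
  # censored 6-subject product-limit hand computation:
  # times 1+, 2, 3, 3+, 5, 6 -> S(2)=4/5, S(3)=3/5, S(5)=3/10, S(6)=0
  s2 <- surv_df(c(1, 2, 3, 3, 5, 6), c(0, 1, 1, 0, 1, 1))
  km2 <- kaplan_meier(s2, setNames(rep("g", 6), s2$sample_id))$g
  expect_equal(km2$surv[km2$time == 2], 0.8)
  expect_equal(km2$surv[km2$time == 3], 0.6)
  expect_equal(km2$surv[km2$time == 5], 0.3)
  expect_equal(km2$surv[km2$time == 6], 0)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(31)
  t <- round(rexp(40, 0.01)) + 1
  s <- surv_df(t, rep(1, 40))
  km <- kaplan_meier(s, setNames(rep("g", 40), s$sample_id))$g
  for (i in seq_len(nrow(km)))
    expect_equal(km$surv[i], mean(t > km$time[i]))
})

test_that("log-rank agrees with direct O-E/V summation", {
  # identical groups: chi2 exactly 0, p = 1
  t <- c(3, 5, 8, 11, 3, 5, 8, 11)
  e <- c(1, 0, 1, 1, 1, 0, 1, 1)
  g <- setNames(rep(c("a", "b"), each = 4), sprintf("s%02d", 1:8))
  lr0 <- logrank_test(surv_df(t, e), g)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # separated groups: matches the hand-summed hypergeometric statistic
  t2 <- c(1, 2, 3, 4, 5, 6)
  e2 <- rep(1, 6)
  g2 <- setNames(rep(c("a", "b"), each = 3), sprintf("s%02d", 1:6))
  lr <- logrank_test(surv_df(t2, e2), g2)
  expect_equal(lr$chi2, logrank_bruteforce(t2, e2, rep(c("a", "b"), each = 3)),
               tolerance = 1e-10)
  # and on a censored random dataset
  set.seed(32)
  t3 <- rexp(30, 0.02)
  e3 <- rbinom(30, 1, 0.7)
  grp <- rep(c("a", "b"), 15)
  lr3 <- logrank_test(surv_df(t3, e3), setNames(grp, sprintf("s%02d", 1:30)))
  expect_equal(lr3$chi2, logrank_bruteforce(t3, e3, grp), tolerance = 1e-8)
  # invariant under group relabeling
  lr3b <- logrank_test(surv_df(t3, e3),
                       setNames(ifelse(grp == "a", "z", "y"),
                                sprintf("s%02d", 1:30)))
  expect_equal(lr3$chi2, lr3b$chi2)
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(33)
  t <- rexp(40, 0.01)
  e <- rbinom(40, 1, 0.8)
  s <- surv_df(t, e)
  ps <- replicate(500, {
    g <- setNames(sample(rep(c("a", "b"), 20)), s$sample_id)
    logrank_test(s, g)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cox fit reports HR, CI and tests coherently", {
  # identical survival in both covariate levels: HR ~ 1, p ~ 1
  t <- c(2, 4, 6, 8, 2, 4, 6, 8)
  e <- rep(1, 8)
  x <- rep(0:1, each = 4)
  r0 <- cox_fit(surv_df(t, e), data.frame(group = x))
  expect_equal(r0$table$hr, 1, tolerance = 1e-6)
  expect_gt(r0$table$p, 0.99)
  # Wald CI identity: exp(log HR +/- 1.96 se) reproduces the CI columns
  set.seed(34)
  z <- rnorm(60)
  sv <- surv_df(rexp(60, 0.02 * exp(0.7 * z)), rbinom(60, 1, 0.8))
  r <- cox_fit(sv, data.frame(z = z))
  se <- log(r$table$hr) / r$table$z
  expect_equal(r$table$ci_lower, exp(log(r$table$hr) - qnorm(0.975) * se),
               tolerance = 1e-6)
  expect_equal(r$table$ci_upper, exp(log(r$table$hr) + qnorm(0.975) * se),
               tolerance = 1e-6)
  expect_true(r$score_p > 0 && r$score_p <= 1)
})

test_that("concordance index equals the brute-force pair enumeration", {
  # all scores tied: exactly 1/2
  s <- surv_df(c(1, 2, 3, 4), rep(1, 4))
  expect_equal(concordance_index(setNames(rep(2, 4), s$sample_id), s), 0.5)
  # perfect anti-ordering of survival times: 1
  t <- c(10, 20, 30, 40, 50)
  sc <- setNames(c(5, 4, 3, 2, 1), sprintf("s%02d", 1:5))
  expect_equal(concordance_index(sc, surv_df(t, rep(1, 5))), 1)
  # random datasets match the exhaustive oracle exactly, both conventions
  for (rep in 1:10) {
    set.seed(500 + rep)
    n <- sample(10:30, 1)
    t <- rexp(n, 0.05)
    e <- rbinom(n, 1, 0.6)
    sc <- sample(1:4, n, TRUE)  # coarse scores force ties
    names(sc) <- sprintf("s%02d", 1:n)
    sv <- surv_df(t, e)
    expect_equal(concordance_index(sc, sv),
                 cindex_bruteforce(sc, t, e, ties = "half"))
    expect_equal(concordance_index(sc, sv, ties = "exclude"),
                 cindex_bruteforce(sc, t, e, ties = "exclude"))
  }
})

test_that("C-index of a score and its negation are complementary", {
  set.seed(35)
  n <- 25
  sc <- setNames(rnorm(n), sprintf("s%02d", 1:n))  # continuous: no ties
  sv <- surv_df(rexp(n, 0.05), rbinom(n, 1, 0.7))
  expect_equal(concordance_index(sc, sv),
               1 - concordance_index(-sc, sv))
})

test_that("Brier score handles exact predictions and censoring weights", {
  # no censoring, predictions equal outcomes: score 0
  t <- c(1, 2, 8, 9)
  s <- surv_df(t, rep(1, 4))
  pred <- setNames(as.numeric(t > 5), s$sample_id)
  expect_equal(brier_score(pred, s, t = 5), 0)
  # constant 1/2 prediction, no censoring: 0.25
  expect_equal(brier_score(setNames(rep(0.5, 4), s$sample_id), s, t = 5),
               0.25)
  # censored 8-subject fixture equals an independently coded IPCW sum
  t8 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e8 <- c(1, 0, 1, 0, 1, 1, 0, 1)
  s8 <- surv_df(t8, e8)
  p8 <- setNames(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2), s8$sample_id)
  horizon <- 4.5
  # oracle: KM of censoring computed by explicit risk-set counting
  cens_km <- function(tt) {
    g <- 1
    for (u in sort(unique(t8[e8 == 0]))) {
      if (u > tt) break
      g <- g * (1 - sum(t8 == u & e8 == 0) / sum(t8 >= u))
    }
    g
  }
  contrib <- vapply(1:8, function(i) {
    if (t8[i] <= horizon && e8[i] == 1)
      (0 - p8[i])^2 / cens_km(t8[i] - 1e-9)
    else if (t8[i] > horizon)
      (1 - p8[i])^2 / cens_km(horizon)
    else 0
  }, numeric(1))
  expect_equal(brier_score(p8, s8, t = horizon), mean(contrib))
  # horizon outside follow-up is rejected
  expect_error(brier_score(p8, s8, t = 100), "follow-up")
})

test_that("survival evaluation bundles coherent statistics", {
  co <- small_cohort
  truth <- setNames(co$true_labels, co$survival$sample_id)
  ev <- evaluate_survival(truth, co$survival)
  expect_lt(ev$logrank_p, 0.01)
  expect_true(ev$c_index > 0.5 && ev$c_index <= 1)
  expect_true(ev$brier_score >= 0 && ev$brier_score <= 1)
  expect_length(ev$km_curves, 2)
})

test_that("Cox CI covers the true log hazard ratio at the nominal rate", {
  hits <- vapply(1:200, function(rep) {
    set.seed(600 + rep)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    sv <- surv_df(rexp(n, 0.01 * exp(log(2) * x)), rbinom(n, 1, 1) * 1)
    r <- cox_fit(sv, data.frame(x = x))
    r$table$ci_lower <= 2 && 2 <= r$table$ci_upper
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  expect_lt(mean(hits), 0.99)
})
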