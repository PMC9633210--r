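# Shared fixtures: one small strong-signal cohort and its discovery fit,
# built once per test run. Sizes are kept small so the whole suite stays
# fast; the acceptance tests build their own cohorts at the scales they
# state.

small_cfg <- sim_config(n_samples = 120, n_mrna = 300, n_mirna = 60,
                        n_cpg = 500, n_genes_annotated = 120,
                        signal_fraction = 0.1, effect_size = 1.5,
                        true_log_hr = log(3), censor_rate = 0.5,
                        seed = 42)
small_cohort <- simulate_cohort(small_cfg)
small_pp <- preprocess_cohort(small_cohort)
small_ae <- ae_spec(c(64, 16, 64), epochs = 16, seed = 42)
small_fit <- suppressWarnings(
  subtype_fit(small_cohort, ae = small_ae, seed = 42,
              preprocessed = small_pp))

# chance-corrected agreement between two partitions (Hubert-Arabie ARI),
# written out from the contingency-table formula
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(0)
  (sij - expected) / (maxidx - expected)
}

# brute-force Harrell C: explicit double loop over all ordered pairs
cindex_bruteforce <- function(score, time, event, ties = "half") {
  num <- 0
  den <- 0
  n <- length(score)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        if (ties == "exclude" && score[i] == score[j]) next
        den <- den + 1
        if (score[i] > score[j]) num <- num + 1
        else if (score[i] == score[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# direct O-E / V summation for the two-group log-rank statistic
logrank_bruteforce <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
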