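#' Kaplan-Meier curves per group
#'
#' Product-limit estimate of the survival function for each group, as
#' right-continuous step functions starting at S(0) = 1.
#'
#' @param surv survival data frame (`sample_id`, `time`, `event`).
#' @param labels group labels named by sample (or in `surv` order).
#' @return a named list of data frames, one per group, with columns
#'   `time`, `n_risk`, `n_event`, `surv`.
#' @export
kaplan_meier <- function(surv, labels) {
  surv <- align_survival(surv, names(labels))
  groups <- if (is.factor(labels)) levels(droplevels(labels)) else
    sort(unique(labels))
  out <- lapply(groups, function(g) {
    idx <- labels == g
    fit <- survival::survfit(
      survival::Surv(surv$time[idx], surv$event[idx]) ~ 1)
    data.frame(time = c(0, fit$time), n_risk = c(sum(idx), fit$n.risk),
               n_event = c(0, fit$n.event), surv = c(1, fit$surv))
  })
  names(out) <- as.character(groups)
  out
}

#' Log-rank test between groups
#'
#' Standard (unweighted) log-rank chi-square with K - 1 degrees of
#' freedom.
#'
#' @inheritParams kaplan_meier
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(surv, labels) {
  surv <- align_survival(surv, names(labels))
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) stop("need at least two non-empty groups")
  if (sum(surv$event) < 1) stop("need at least one event")
  sd0 <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ labels)
  df <- nlevels(labels) - 1L
  p <- stats::pchisq(sd0$chisq, df = df, lower.tail = FALSE)
  list(chi2 = unname(sd0$chisq), df = df, p = p)
}

#' Cox proportional-hazards fit with tidy per-covariate output
#'
#' Partial-likelihood Newton fit with Efron tie handling (the survival
#' package). Returns hazard ratios with 95% Wald confidence intervals, z
#' statistics, per-coefficient Wald p-values and the model-level score and
#' likelihood-ratio test p-values. Categorical covariates use their first
#' factor level as the reference.
#'
#' @param surv survival data frame (`sample_id`, `time`, `event`).
#' @param covariates data frame of covariates (rows aligned to
#'   `surv$sample_id` via a `sample_id` column, or in the same order), or
#'   a numeric vector/matrix.
#' @return a list of class `cox_result` with a `table` data frame
#'   (term, hr, ci_lower, ci_upper, z, p), `score_p`, `lr_p`, `n`,
#'   `events`, and the underlying `fit`.
#' @export
cox_fit <- function(surv, covariates) {
  if (is.vector(covariates) && is.null(dim(covariates)))
    covariates <- data.frame(x = covariates)
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    surv <- align_survival(surv, covariates$sample_id)
    covariates <- covariates[, setdiff(names(covariates), "sample_id"),
                             drop = FALSE]
  } else {
    if (nrow(covariates) != nrow(surv))
      stop("covariates and survival table have different sizes")
    surv <- align_survival(surv, NULL)
  }
  dat <- cbind(surv[, c("time", "event")], covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!fit$iter || any(!is.finite(fit$coefficients)))
    stop("Cox model did not converge")
  sm <- summary(fit)
  co <- sm$coefficients
  big <- abs(co[, "coef"]) > 10
  if (any(big))
    warning("very large coefficients; possible complete separation")
  tab <- data.frame(term = rownames(co),
                    hr = unname(co[, "exp(coef)"]),
                    ci_lower = unname(sm$conf.int[, "lower .95"]),
                    ci_upper = unname(sm$conf.int[, "upper .95"]),
                    z = unname(co[, "z"]),
                    p = unname(co[, "Pr(>|z|)"]),
                    row.names = NULL)
  structure(list(table = tab,
                 score_p = unname(sm$sctest["pvalue"]),
                 lr_p = unname(sm$logtest["pvalue"]),
                 n = sm$n, events = sm$nevent, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox-PH fit: n = %d, events = %d (score test p = %.3g)\n",
              x$n, x$events, x$score_p))
  print(transform(x$table, hr = signif(hr, 4), ci_lower = signif(ci_lower, 4),
                  ci_upper = signif(ci_upper, 4), z = signif(z, 4),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Harrell's concordance index
#'
#' Over usable pairs — pairs in which the member with the shorter observed
#' time experienced the event (ties in time are not usable) — the fraction
#' in which that shorter-surviving member also has the higher risk score;
#' score ties count 1/2.
#'
#' @param risk_score numeric vector, higher = higher predicted risk.
#' @param surv survival data frame (`sample_id`, `time`, `event`), in the
#'   same order (or matched by names on `risk_score`).
#' @param ties how score-tied pairs are handled: `"half"` (default)
#'   counts them 1/2; `"exclude"` drops them from the usable pairs, the
#'   convention commonly applied when the score is a discrete group label
#'   (within-group pairs then carry no information instead of dragging
#'   the index toward 1/2).
#' @return concordance index in \[0, 1\].
#' @export
concordance_index <- function(risk_score, surv,
                              ties = c("half", "exclude")) {
  ties <- match.arg(ties)
  surv <- align_survival(surv, names(risk_score))
  if (length(risk_score) != nrow(surv))
    stop("risk_score and survival table differ in length")
  t <- surv$time; d <- surv$event; s <- as.numeric(risk_score)
  # usable: t_i < t_j and event_i == 1
  shorter <- outer(t, t, "<") & (d == 1)
  if (ties == "exclude") shorter <- shorter & outer(s, s, "!=")
  n_usable <- sum(shorter)
  if (n_usable == 0) stop("no usable pairs for the concordance index")
  sgn <- outer(s, s, ">") + 0.5 * outer(s, s, "==")
  sum(sgn[shorter]) / n_usable
}

# Kaplan-Meier estimate of the censoring distribution G(t) = P(C > t),
# with a left-limit lookup G(t-).
censoring_km <- function(surv) {
  fit <- survival::survfit(
    survival::Surv(surv$time, 1 - surv$event) ~ 1)
  times <- fit$time
  sv <- fit$surv
  function(t, left = FALSE) {
    vapply(t, function(tt) {
      idx <- if (left) which(times < tt) else which(times <= tt)
      if (!length(idx)) 1 else sv[max(idx)]
    }, numeric(1))
  }
}

#' Inverse-probability-of-censoring-weighted Brier score
#'
#' Squared error between the predicted survival probability at horizon `t`
#' and the observed status at `t`, weighted by the inverse of the
#' Kaplan-Meier censoring survival: subjects with an event before `t` get
#' weight 1/G(T-), subjects still at risk at `t` get 1/G(t), and subjects
#' censored before `t` get weight 0.
#'
#' @param pred_survival_prob numeric vector of predicted probabilities of
#'   surviving beyond `t`, one per subject.
#' @param surv survival data frame (`sample_id`, `time`, `event`).
#' @param t evaluation horizon; default the median observed follow-up.
#' @return the Brier score at `t`.
#' @export
brier_score <- function(pred_survival_prob, surv, t = NULL) {
  surv <- align_survival(surv, names(pred_survival_prob))
  p <- as.numeric(pred_survival_prob)
  if (any(p < 0 | p > 1)) stop("predictions must lie in [0, 1]")
  if (is.null(t)) t <- stats::median(surv$time)
  if (t <= 0 || t > max(surv$time))
    stop("horizon t must lie within the observed follow-up range")
  G <- censoring_km(surv)
  if (G(t) <= 0)
    stop("censoring survival is zero at t; choose a smaller horizon")
  tt <- surv$time; d <- surv$event
  w <- numeric(length(p))
  died <- tt <= t & d == 1
  atrisk <- tt > t
  w[died] <- 1 / G(tt[died], left = TRUE)
  w[atrisk] <- 1 / G(t)
  err <- numeric(length(p))
  err[died] <- (0 - p[died])^2
  err[atrisk] <- (1 - p[atrisk])^2
  mean(w * err)
}

#' Integrated Brier score
#'
#' Trapezoidal integral of [brier_score()] over a time grid, divided by
#' the grid span.
#'
#' @inheritParams brier_score
#' @param times evaluation grid; default the event times up to the 90th
#'   percentile of follow-up.
#' @return the integrated Brier score.
#' @export
integrated_brier_score <- function(pred_survival_prob, surv, times = NULL) {
  surv0 <- align_survival(surv, names(pred_survival_prob))
  if (is.null(times)) {
    ev <- sort(unique(surv0$time[surv0$event == 1]))
    times <- ev[ev <= stats::quantile(surv0$time, 0.9)]
  }
  if (length(times) < 2) stop("need at least two evaluation times")
  bs <- vapply(times, function(tt)
    brier_score(pred_survival_prob, surv, t = tt), numeric(1))
  sum(diff(times) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) /
    (max(times) - min(times))
}

#' Evaluate the survival separation of a subgroup assignment
#'
#' Bundles the evaluation statistics used throughout the pipeline: the
#' log-rank test between groups, Harrell's C-index of the group risk
#' score (the Cox linear predictor of the group indicator, with
#' score-tied pairs excluded — the group label is discrete, so
#' within-group pairs carry no ordering information), the IPCW Brier
#' score at the median follow-up using group-wise Kaplan-Meier survival
#' as the prediction, and the per-group KM curves.
#'
#' @param labels group labels named by sample (factor or vector).
#' @param surv survival data frame (`sample_id`, `time`, `event`).
#' @param brier_time Brier horizon; default median observed follow-up.
#' @return a list of class `survival_evaluation` with `logrank_chi2`,
#'   `logrank_p`, `c_index`, `brier_score`, `brier_time`, `km_curves`,
#'   `n`, `events`.
#' @export
evaluate_survival <- function(labels, surv, brier_time = NULL) {
  surv <- align_survival(surv, names(labels))
  lab <- droplevels(factor(labels))
  if (nlevels(lab) < 2) {
    # a single-group assignment separates nothing: log-rank p 1,
    # chance-level concordance, Brier from the pooled KM curve
    warning("single-group labels: reporting the no-separation evaluation")
    if (is.null(brier_time)) brier_time <- stats::median(surv$time)
    km <- kaplan_meier(surv, stats::setNames(lab, surv$sample_id))
    cur <- km[[1]]
    pred <- rep(cur$surv[max(which(cur$time <= brier_time))],
                nrow(surv))
    names(pred) <- surv$sample_id
    return(structure(list(logrank_chi2 = 0, logrank_p = 1, c_index = 0.5,
                          brier_score = brier_score(pred, surv,
                                                    t = brier_time),
                          brier_time = brier_time, km_curves = km,
                          n = nrow(surv), events = sum(surv$event)),
                     class = "survival_evaluation"))
  }
  lr <- logrank_test(surv, stats::setNames(lab, surv$sample_id))
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ lab,
                         ties = "efron")
  score <- stats::setNames(
    as.numeric(stats::model.matrix(~lab)[, -1, drop = FALSE] %*%
                 stats::coef(fit)),
    surv$sample_id)
  ci <- concordance_index(score, surv, ties = "exclude")
  if (is.null(brier_time)) brier_time <- stats::median(surv$time)
  km <- kaplan_meier(surv, stats::setNames(lab, surv$sample_id))
  pred <- vapply(seq_along(lab), function(i) {
    cur <- km[[as.character(lab[i])]]
    idx <- which(cur$time <= brier_time)
    if (!length(idx)) 1 else cur$surv[max(idx)]
  }, numeric(1))
  names(pred) <- surv$sample_id
  bs <- brier_score(pred, surv, t = brier_time)
  structure(list(logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 c_index = ci, brier_score = bs, brier_time = brier_time,
                 km_curves = km, n = nrow(surv), events = sum(surv$event)),
            class = "survival_evaluation")
}

#' @export
print.survival_evaluation <- function(x, ...) {
  cat(sprintf(paste0("survival evaluation (n = %d, events = %d):\n",
                     "  log-rank p = %.3g (chi2 = %.3f)\n",
                     "  C-index    = %.3f\n",
                     "  Brier(%.0f) = %.3f\n"),
              x$n, x$events, x$logrank_p, x$logrank_chi2, x$c_index,
              x$brier_time, x$brier_score))
  invisible(x)
}
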