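# Align a survival table to a vector of sample ids (order and subset);
# errors on samples without survival records.
align_survival <- function(surv, ids) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(surv)))
  if (any(surv$time <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  if (anyDuplicated(surv$sample_id)) stop("duplicate sample ids in survival")
  if (is.null(ids)) {
    if (nrow(surv) == 0) stop("empty survival table")
    return(surv)
  }
  idx <- match(ids, surv$sample_id)
  if (anyNA(idx))
    stop(sprintf("no survival record for samples: %s",
                 paste(utils::head(ids[is.na(idx)], 5), collapse = ", ")))
  surv[idx, , drop = FALSE]
}

# geometric mean of p-values: exp(mean(log p))
geometric_mean_p <- function(p) exp(mean(log(p)))
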