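# Balanced stratified k-fold splitting of survival cohorts, with a
# standardized-mean-difference covariate balance report.

#' Assign half-year survival strata
#'
#' Each patient gets a stratum defined by the half-year bin of their
#' observed time (`floor(2 * t)` with `t` in years; half-open bins, so
#' `t = 0.5` falls in bin 1) crossed with the event indicator, so folds
#' preserve both the survival-duration distribution and the event rate.
#'
#' @param times positive observed times in years.
#' @param events 0/1 event indicators.
#' @return data.frame with columns `half_year_bin`, `event`, `stratum`
#'   (string label).
#' @export
assign_strata <- function(times, events) {
  if (any(times <= 0)) stop("times must be positive")
  if (any(!events %in% c(0, 1))) stop("events must be 0/1")
  bin <- floor(2 * times)
  data.frame(half_year_bin = bin, event = events,
             stratum = sprintf("b%d_e%d", bin, events))
}

#' Stratified k-fold splits
#'
#' Within each (half-year bin, event) stratum, patients are shuffled with
#' the given seed and dealt round-robin to the k folds, so per-stratum test
#' counts differ by at most one across folds. Every patient appears in
#' exactly one test fold.
#'
#' @param ids patient identifiers.
#' @param times,events survival data (years, 0/1).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` fold splits, each a list with `fold_index`,
#'   `train_ids`, `test_ids`.
#' @export
make_folds <- function(ids, times, events, k = 5, seed = 1L) {
  n <- length(ids)
  stopifnot(length(times) == n, length(events) == n)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than patients")
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  strata <- assign_strata(times, events)$stratum
  fold_of <- integer(n)
  with_seed(seed, {
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- (seq_along(idx) - 1L) %% k + 1L
    }
  })
  lapply(seq_len(k), function(f)
    list(fold_index = f, train_ids = ids[fold_of != f],
         test_ids = ids[fold_of == f]))
}

#' Covariate balance report for one fold split
#'
#' Standardized mean difference (SMD) of each covariate between the train
#' and test sets: difference in means over the pooled standard deviation
#' `sqrt((v_train + v_test) / 2)`. Factor/character covariates are expanded
#' into level indicators. Missing values are dropped per covariate
#' (complete-case), with the used counts reported. `|SMD| > 0.1` is
#' flagged as imbalanced.
#'
#' @param split one element of [make_folds()]'s result.
#' @param covariates data.frame keyed by a `patient_id` column.
#' @return data.frame with columns `covariate`, `smd`, `n_train`, `n_test`,
#'   `flagged`.
#' @export
balance_report <- function(split, covariates) {
  stopifnot("patient_id" %in% names(covariates))
  num_cols <- list()
  for (nm in setdiff(names(covariates), "patient_id")) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      num_cols[[nm]] <- v
    } else {
      v <- as.factor(v)
      for (lv in levels(v))
        num_cols[[paste0(nm, "=", lv)]] <- as.numeric(v == lv)
    }
  }
  tr <- covariates$patient_id %in% split$train_ids
  te <- covariates$patient_id %in% split$test_ids
  rows <- lapply(names(num_cols), function(nm) {
    v <- num_cols[[nm]]
    a <- v[tr & !is.na(v)]; b <- v[te & !is.na(v)]
    sp <- sqrt((var(a) + var(b)) / 2)
    smd <- if (!is.finite(sp) || sp == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 0 else Inf
    } else (mean(a) - mean(b)) / sp
    data.frame(covariate = nm, smd = smd, n_train = length(a),
               n_test = length(b), flagged = abs(smd) > 0.1)
  })
  do.call(rbind, rows)
}

#' Persist fold splits as CSV
#'
#' One row per (patient, fold) pair with the patient's role in that fold.
#'
#' @param folds result of [make_folds()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_folds_csv <- function(folds, path) {
  out <- do.call(rbind, lapply(folds, function(f)
    data.frame(patient_id = c(f$train_ids, f$test_ids),
               fold = f$fold_index,
               role = rep(c("train", "test"),
                          c(length(f$train_ids), length(f$test_ids))))))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
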