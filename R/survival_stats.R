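# Survival machinery: negative Cox log partial likelihood (the training
# loss) and its gradient, concordance index, Kaplan-Meier curves, log-rank
# tests and quantile-scheme risk stratification.

check_surv_args <- function(risks, times, events) {
  if (length(risks) != length(times) || length(times) != length(events))
    stop("risks, times and events must have equal length")
  if (length(times) < 1) stop("empty survival data")
  if (any(!events %in% c(0, 1))) stop("events must be 0/1")
  if (any(times <= 0)) stop("times must be positive")
  invisible(TRUE)
}

#' Negative Cox log partial likelihood
#'
#' The training loss: `sum_i mu_i * (-r_i + log sum_{j: t_j >= t_i} exp(r_j))`,
#' i.e. the negative log partial likelihood of the Cox proportional-hazards
#' model with the risk score `r` as linear predictor. Tied event times share
#' a risk set (Breslow's convention), and the inner log-sum is computed with
#' log-sum-exp stabilization. With all risks equal the loss reduces to
#' `sum over events of log |risk set|`, which is non-negative.
#'
#' @param risks numeric vector of risk scores (linear-predictor scale).
#' @param times positive observed times.
#' @param events 0/1 event indicators (1 = death).
#' @return Scalar loss. With zero events a warning is raised and 0 returned
#'   (no informative terms).
#' @seealso [cox_loss_grad()] for the analytic gradient.
#' @export
cox_loss <- function(risks, times, events) {
  check_surv_args(risks, times, events)
  if (sum(events) == 0) {
    warning("no events: Cox partial likelihood has no informative terms")
    return(0)
  }
  loss <- 0
  for (i in which(events == 1)) {
    rs <- risks[times >= times[i]]
    m <- max(rs)
    loss <- loss - risks[i] + m + log(sum(exp(rs - m)))
  }
  loss
}

#' Gradient of the negative Cox log partial likelihood
#'
#' `d loss / d r_k = -mu_k + sum over events i with t_k >= t_i of
#' exp(r_k) / sum_{j in riskset(i)} exp(r_j)`.
#'
#' @inheritParams cox_loss
#' @return Numeric vector of the same length as `risks` (zero when there
#'   are no events).
#' @export
cox_loss_grad <- function(risks, times, events) {
  check_surv_args(risks, times, events)
  g <- -as.numeric(events)
  if (sum(events) == 0) return(g * 0)
  m <- max(risks)
  er <- exp(risks - m)
  for (i in which(events == 1)) {
    in_rs <- times >= times[i]
    g[in_rs] <- g[in_rs] + er[in_rs] / sum(er[in_rs])
  }
  g
}

#' Concordance index for scalar risk scores
#'
#' Fraction of comparable patient pairs (`t_i < t_j` with `mu_i = 1`) in
#' which the patient with the earlier event received the higher risk; tied
#' risks score 1/2. For a time-constant scalar risk per patient this
#' pairwise form coincides with Antolini's time-dependent concordance.
#'
#' @inheritParams cox_loss
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risks, times, events) {
  check_surv_args(risks, times, events)
  num <- 0; den <- 0
  for (i in which(events == 1)) {
    later <- times > times[i]
    den <- den + sum(later)
    num <- num + sum(risks[i] > risks[later]) + 0.5 * sum(risks[i] == risks[later])
  }
  if (den == 0) stop("no comparable pairs: concordance undefined")
  num / den
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator (via [survival::survfit]) evaluated at the
#' distinct event times.
#'
#' @param times positive observed times.
#' @param events 0/1 event indicators.
#' @return A `km_curve`: list with `event_times`, `survival_probs`
#'   (non-increasing step heights at those times), `n_risk` and `n_event`.
#' @export
km_estimate <- function(times, events) {
  check_surv_args(numeric(length(times)), times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 survival_probs = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep]),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a `km_curve`.
#' @param t times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    k <- which(curve$event_times <= ti)
    if (length(k) == 0) 1 else curve$survival_probs[max(k)]
  }, numeric(1))
}

#' Two-sided log-rank test between two groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' (via [survival::survdiff]), referred to a chi-squared distribution with
#' one degree of freedom.
#'
#' @param times_a,events_a survival data of group A.
#' @param times_b,events_b survival data of group B.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0)
    stop("both groups must be nonempty")
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events in either group: log-rank statistic undefined")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Optimal risk cutoff over a quantile grid
#'
#' Evaluates the log-rank statistic of the high/low split induced by each
#' candidate risk quantile and returns the risk value at the quantile with
#' the largest statistic; ties are broken toward the grid point closest to
#' the median. Candidates that leave a group empty (or with no events
#' overall) are infeasible. Intended to be computed on training data only
#' (see the cutoff-source discussion in the package vignette).
#'
#' @inheritParams cox_loss
#' @param quantile_grid candidate quantiles in (0, 1); default
#'   `seq(0.25, 0.75, by = 0.05)`.
#' @return list with `cutoff`, `quantile`, `chi2`.
#' @export
optimal_quantile_cutoff <- function(risks, times, events,
                                    quantile_grid = seq(0.25, 0.75, by = 0.05)) {
  check_surv_args(risks, times, events)
  if (length(quantile_grid) == 0 || any(quantile_grid <= 0) ||
      any(quantile_grid >= 1))
    stop("quantile_grid must lie strictly inside (0, 1)")
  best <- NULL
  for (q in quantile_grid) {
    cut <- unname(quantile(risks, q))
    hi <- risks > cut
    if (!any(hi) || all(hi)) next
    lr <- tryCatch(
      logrank_test(times[!hi], events[!hi], times[hi], events[hi]),
      error = function(e) NULL)
    if (is.null(lr)) next
    better <- is.null(best) || lr$chi2 > best$chi2 + 1e-12 ||
      (abs(lr$chi2 - best$chi2) <= 1e-12 &&
         abs(q - 0.5) < abs(best$quantile - 0.5))
    if (better) best <- list(cutoff = cut, quantile = q, chi2 = lr$chi2)
  }
  if (is.null(best))
    stop("no feasible cutoff candidate in the quantile grid")
  best
}

#' Stratify patients into low/high-risk groups at a cutoff
#'
#' `risk > cutoff` is high risk; boundary ties go to the low-risk group.
#' The log-rank chi-squared and p-value of the induced split are attached;
#' if one group is empty a warning is raised and `p = 1` reported as a
#' sentinel.
#'
#' @inheritParams cox_loss
#' @param cutoff finite risk cutoff.
#' @return A `stratification_result`: list with `cutoff`, `group` (factor
#'   low/high per patient), `logrank_chi2`, `p_value`.
#' @export
stratify <- function(risks, times, events, cutoff) {
  check_surv_args(risks, times, events)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  group <- factor(ifelse(risks > cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (length(unique(group)) < 2) {
    warning("one risk group is empty; p-value set to 1")
    chi2 <- 0; p <- 1
  } else {
    lr <- tryCatch(
      logrank_test(times[group == "low"], events[group == "low"],
                   times[group == "high"], events[group == "high"]),
      error = function(e) list(chi2 = 0, p = 1))
    chi2 <- lr$chi2; p <- lr$p
  }
  structure(list(cutoff = cutoff, group = group, logrank_chi2 = chi2,
                 p_value = p), class = "stratification_result")
}

#' Read / write a patient survival table
#'
#' CSV with columns `patient_id`, `time`, `event`; the time unit (years or
#' days) is the caller's, tracked in configuration, not the file.
#'
#' @param path CSV path.
#' @return data.frame with the three columns.
#' @export
read_survival_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  check_surv_args(numeric(nrow(df)), df$time, df$event)
  df[need]
}

#' Export Kaplan-Meier curves per risk group as CSV (and optionally PNG)
#'
#' @param strat a `stratification_result`.
#' @param times,events the cohort's survival data (same order as the risks
#'   given to [stratify()]).
#' @param csv_path output CSV path (columns group, time, survival).
#' @param png_path optional PNG path for a base-graphics step plot.
#' @return The exported data.frame, invisibly.
#' @export
export_km <- function(strat, times, events, csv_path, png_path = NULL) {
  stopifnot(inherits(strat, "stratification_result"))
  out <- do.call(rbind, lapply(levels(strat$group), function(g) {
    sel <- strat$group == g
    if (!any(sel)) return(NULL)
    cv <- km_estimate(times[sel], events[sel])
    data.frame(group = g, time = c(0, cv$event_times),
               survival = c(1, cv$survival_probs))
  }))
  write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    png(png_path, width = 640, height = 480)
    plot(NA, xlim = c(0, max(times)), ylim = c(0, 1),
         xlab = "time", ylab = "survival probability",
         main = sprintf("log-rank p = %.3g", strat$p_value))
    cols <- c(low = "blue", high = "red")
    for (g in unique(out$group)) {
      d <- out[out$group == g, ]
      lines(stats::stepfun(d$time[-1], d$survival), col = cols[[g]],
            do.points = FALSE)
    }
    legend("topright", legend = unique(out$group),
           col = cols[unique(out$group)], lty = 1)
    dev.off()
  }
  invisible(out)
}
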