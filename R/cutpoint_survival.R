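# Maximally selected log-rank cutpoint, Kaplan-Meier estimation, and a
# permutation correction for the selection bias of the "best cutoff"
# p-value. The log-rank statistic uses the standard aggregated risk-set
# formulation with the hypergeometric variance at each distinct event time,
# so tied event times are handled exactly.

check_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || !all(c("time", "event", "marker") %in% names(cohort)))
    stop_input("cohort must be a data.frame with columns time, event, marker")
  if (any(cohort$time < 0) || anyNA(cohort$time))
    stop_input("times must be non-negative and observed")
  if (!all(cohort$event %in% c(0L, 1L)))
    stop_input("event must be 0 (censored) or 1 (death observed)")
  if (anyNA(cohort$marker))
    stop_input("missing markers must be filtered before analysis")
  cohort
}

# One-time sort/aggregation reused across all candidate cutpoints.
logrank_prep <- function(time, event) {
  ord <- order(time)
  time_s <- time[ord]
  event_s <- as.integer(event[ord])
  ut <- unique(time_s)
  idx <- match(time_s, ut)
  nb <- length(ut)
  cnt <- tabulate(idx, nb)
  before <- c(0L, cumsum(cnt))[seq_len(nb)]
  list(ord = ord, idx = idx, nb = nb, n = length(time_s),
       d = tabulate(idx[event_s == 1L], nb),
       nrisk = length(time_s) - before,
       before = before, event = event_s)
}

# g: logical membership of group 1, already in sorted-by-time order.
# Returns c(stat, O - E, V); stat is 0 when the variance degenerates.
logrank_core <- function(prep, g) {
  n1 <- sum(g)
  cg <- c(0L, cumsum(g))
  n1risk <- n1 - cg[prep$before + 1L]
  d1 <- tabulate(prep$idx[g & prep$event == 1L], prep$nb)
  oe <- sum(d1) - sum(prep$d * n1risk / prep$nrisk)
  ok <- prep$nrisk > 1L
  v <- sum((prep$d * (n1risk / prep$nrisk) * (1 - n1risk / prep$nrisk) *
              (prep$nrisk - prep$d) / (prep$nrisk - 1))[ok])
  stat <- if (v > 0) oe^2 / v else 0
  c(stat = stat, oe = oe, v = v)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom: at each distinct
#' event time the observed number of events in the high group is compared
#' with its hypergeometric expectation given the risk sets, and the
#' standardized squared sum of the differences is referred to the
#' chi-square upper tail.
#'
#' @param cohort data.frame with columns `time`, `event` (1 = death
#'   observed, 0 = censored) and `marker` (see [simulate_survival_cohort()]).
#' @param high_mask logical vector assigning each patient to the high
#'   group; both groups must be non-empty.
#' @return list: `statistic` (chi-square, 1 df), `p_value`,
#'   `observed_minus_expected` and `variance` for the high group.
#' @export
logrank_statistic <- function(cohort, high_mask) {
  cohort <- check_cohort(cohort)
  high_mask <- as.logical(high_mask)
  if (length(high_mask) != nrow(cohort) || anyNA(high_mask))
    stop_input("high_mask must be a complete logical vector over the cohort")
  if (!any(high_mask) || all(high_mask))
    stop_input("both groups must be non-empty")
  prep <- logrank_prep(cohort$time, cohort$event)
  if (sum(prep$d) == 0L) {
    warning("no events in cohort: p = 1")
    return(list(statistic = 0, p_value = 1,
                observed_minus_expected = 0, variance = 0))
  }
  res <- logrank_core(prep, high_mask[prep$ord])
  list(statistic = unname(res["stat"]),
       p_value = pchisq(unname(res["stat"]), df = 1, lower.tail = FALSE),
       observed_minus_expected = unname(res["oe"]),
       variance = unname(res["v"]))
}

candidate_cutoffs <- function(marker, min_prop, n) {
  um <- sort(unique(marker))
  if (length(um) < 2L)
    stop_input("no candidate cutpoints: marker is constant")
  mid <- (um[-length(um)] + um[-1L]) / 2
  n_high <- vapply(mid, function(c) sum(marker > c), integer(1))
  feas <- n_high / n >= min_prop & n_high / n <= 1 - min_prop
  if (!any(feas))
    stop_input("no candidate cutpoints satisfy the group-proportion constraint")
  mid[feas]
}

#' Maximally selected log-rank cutpoint
#'
#' Scans candidate marker cutpoints — the midpoints between consecutive
#' distinct marker values whose induced split keeps both groups at a
#' fraction of at least `min_prop` of the cohort — and returns the cutoff
#' maximizing the log-rank chi-square. Ties are broken toward the candidate
#' nearest the marker median. The returned p-value is the naive chi-square
#' tail at the selected cutoff and is selection-biased (anti-conservative)
#' by construction; see [corrected_cutpoint_p()] for a calibrated version.
#'
#' @inheritParams logrank_statistic
#' @param min_prop minimum fraction of patients per group (default 0.1,
#'   the common default for maximally selected statistics).
#' @return list of class `cutpoint_result`: `cutoff`, `logrank_stat`,
#'   `p_value` (naive), `n_high`, `n_low`, and `selection_trace`
#'   (data.frame `candidate`, `stat`).
#' @export
best_cutpoint <- function(cohort, min_prop = 0.1) {
  cohort <- check_cohort(cohort)
  min_prop <- check_fraction(min_prop, "min_prop", lo = 0, hi = 0.5, hi_open = TRUE)
  n <- nrow(cohort)
  cand <- candidate_cutoffs(cohort$marker, min_prop, n)
  prep <- logrank_prep(cohort$time, cohort$event)
  marker_s <- cohort$marker[prep$ord]
  stats <- vapply(cand, function(c) logrank_core(prep, marker_s > c)["stat"],
                  numeric(1))
  best <- max(stats)
  ties <- which(stats >= best - 1e-9 * max(1, best))
  med <- median(cohort$marker)
  pick <- ties[which.min(abs(cand[ties] - med))]
  cutoff <- cand[pick]
  n_high <- sum(cohort$marker > cutoff)
  structure(list(cutoff = cutoff,
                 logrank_stat = stats[pick],
                 p_value = pchisq(stats[pick], df = 1, lower.tail = FALSE),
                 n_high = n_high, n_low = n - n_high,
                 selection_trace = data.frame(candidate = cand, stat = stats)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Best cutpoint: %.4g (high n = %d, low n = %d)\n",
              x$cutoff, x$n_high, x$n_low))
  cat(sprintf("  log-rank chi-square = %.3f, naive p = %.3g\n",
              x$logrank_stat, x$p_value))
  cat("  note: the naive p is selection-biased; use corrected_cutpoint_p()\n")
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' @inheritParams logrank_statistic
#' @param mask optional logical vector selecting the subgroup (default: the
#'   whole cohort).
#' @return data.frame of class `km_curve`: one row per distinct observed
#'   time with `time`, `n_risk`, `n_event`, `n_censor` and the survival
#'   probability `survival` just after that time. S(0) = 1 is implicit;
#'   the curve is a non-increasing right-continuous step function dropping
#'   only at event times.
#' @export
km_estimate <- function(cohort, mask = NULL) {
  cohort <- check_cohort(cohort)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != nrow(cohort) || anyNA(mask))
      stop_input("mask must be a complete logical vector over the cohort")
    cohort <- cohort[mask, , drop = FALSE]
  }
  if (!nrow(cohort)) stop_input("empty group")
  ord <- order(cohort$time)
  time <- cohort$time[ord]; event <- cohort$event[ord]
  ut <- unique(time)
  idx <- match(time, ut)
  d <- tabulate(idx[event == 1L], length(ut))
  cens <- tabulate(idx[event == 0L], length(ut))
  cnt <- tabulate(idx, length(ut))
  nrisk <- length(time) - c(0L, cumsum(cnt))[seq_along(ut)]
  surv <- cumprod(1 - d / nrisk)
  out <- data.frame(time = ut, n_risk = nrisk, n_event = d,
                    n_censor = cens, survival = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Permutation-corrected p-value for the best cutpoint
#'
#' The naive p-value of a maximally selected statistic ignores that the
#' cutoff was chosen to maximize it. This correction permutes the marker
#' against the (time, event) pairs, re-runs the full cutpoint search on
#' each permutation, and reports the rank-based p-value of the observed
#' maximal statistic among the permuted maxima:
#' `(1 + #\{max_perm >= max_obs\}) / (n_permutations + 1)`.
#'
#' @inheritParams best_cutpoint
#' @param n_permutations number of marker permutations (a warning is
#'   issued below 100).
#' @param seed integer seed for the permutation stream.
#' @return list: `p_adjusted`, `p_naive`, `observed_stat`,
#'   `n_permutations`, and the selected `cutoff`.
#' @export
corrected_cutpoint_p <- function(cohort, min_prop = 0.1,
                                 n_permutations = 1000L, seed = 1L) {
  n_permutations <- check_count(n_permutations, "n_permutations")
  if (n_permutations < 100L)
    warning("fewer than 100 permutations: adjusted p will be coarse")
  obs <- best_cutpoint(cohort, min_prop)
  cohort <- check_cohort(cohort)
  n <- nrow(cohort)
  cand <- candidate_cutoffs(cohort$marker, min_prop, n)
  prep <- logrank_prep(cohort$time, cohort$event)
  set.seed(seed)
  perm_max <- vapply(seq_len(n_permutations), function(b) {
    m <- sample(cohort$marker)[prep$ord]
    max(vapply(cand, function(c) logrank_core(prep, m > c)["stat"], numeric(1)))
  }, numeric(1))
  p_adj <- (1 + sum(perm_max >= obs$logrank_stat)) / (n_permutations + 1)
  list(p_adjusted = p_adj, p_naive = obs$p_value,
       observed_stat = obs$logrank_stat, n_permutations = n_permutations,
       cutoff = obs$cutoff)
}
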