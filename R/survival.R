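#' Partition a cohort's DFS times by gene mutation status
#'
#' Patients carrying at least one deleterious variant in `gene` within the
#' chosen tumor group form the mutant stratum; everyone else in the
#' clinical table is wild type. Every verdict patient must appear in the
#' clinical table.
#'
#' @param clinical Clinical table from [read_clinical_table()].
#' @param verdicts Verdict table from [classify_variants()].
#' @param gene Gene symbol to stratify on.
#' @param group Tumor group: "primary" or "metastatic".
#' @return List with numeric vectors `mutant` and `wildtype` of DFS months,
#'   named by patient id; the two partitions cover the cohort exactly.
#' @export
stratify_by_mutation <- function(clinical, verdicts, gene,
                                 group = c("primary", "metastatic")) {
  group <- match.arg(group)
  missing_pat <- setdiff(unique(verdicts$patient_id), clinical$patient_id)
  if (length(missing_pat) > 0) {
    stop("patient(s) in variant verdicts absent from clinical table: ",
         paste(missing_pat, collapse = ", "))
  }
  mut_ids <- unique(verdicts$patient_id[
    verdicts$deleterious &
      !is.na(verdicts$gene) & verdicts$gene == gene &
      !is.na(verdicts$tumor_group) & verdicts$tumor_group == group
  ])
  dfs <- stats::setNames(clinical$dfs_months, clinical$patient_id)
  list(mutant = dfs[clinical$patient_id %in% mut_ids],
       wildtype = dfs[!clinical$patient_id %in% mut_ids])
}

# exact null distribution of the Mann-Whitney U statistic for group sizes
# n and m by full enumeration of all choose(n+m, n) rank assignments
enumerate_u_distribution <- function(n, m) {
  combos <- utils::combn(n + m, n)
  u <- colSums(combos) - n * (n + 1) / 2
  table(factor(u, levels = 0:(n * m))) / ncol(combos)
}

#' Two-tailed unpaired Wilcoxon rank-sum (Mann-Whitney) test
#'
#' For small tie-free samples (`n + m <= exact_limit`) the p-value is exact:
#' the null distribution of U is built by full enumeration of all
#' `choose(n+m, n)` rank assignments and the two-tailed p is
#' `2 * min(P(U <= u), P(U >= u))` capped at 1. Ties or larger samples fall
#' back to the mid-rank normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Non-empty numeric vectors (e.g. DFS months of the mutant and
#'   wild-type strata).
#' @param exact_limit Largest pooled size for which enumeration is used.
#' @return Object of class `rank_sum_test`: `u_statistic`
#'   (`min(U_x, U_y)`), `p_two_tailed`, `method` ("exact_enumeration" or
#'   "normal_approximation"), group sizes `n`, `m`, and the group means
#'   `mean_x`, `mean_y`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0 || anyNA(x) || anyNA(y)) {
    stop("degenerate stratification: both groups must be non-empty ",
         "and free of missing values")
  }
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0

  r <- rank(pooled)
  u_x <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u_y <- n * m - u_x

  if (!has_ties && n + m <= exact_limit) {
    dist <- enumerate_u_distribution(n, m)
    lo <- sum(dist[as.integer(names(dist)) <= u_x])
    hi <- sum(dist[as.integer(names(dist)) >= u_x])
    p <- min(1, 2 * min(lo, hi))
    method <- "exact_enumeration"
  } else {
    mu <- n * m / 2
    tie_tab <- table(pooled)
    big_n <- n + m
    sigma2 <- n * m / 12 *
      (big_n + 1 - sum(tie_tab^3 - tie_tab) / (big_n * (big_n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_x - mu - sign(u_x - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  structure(list(u_statistic = min(u_x, u_y), p_two_tailed = p,
                 method = method, n = n, m = m,
                 mean_x = mean(x), mean_y = mean(y)),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("Two-tailed unpaired Wilcoxon rank-sum test (",
      x$method, ")\n", sep = "")
  cat(sprintf("  n = %d (mean %.4g)  vs  m = %d (mean %.4g)\n",
              x$n, x$mean_x, x$m, x$mean_y))
  cat(sprintf("  U = %g, p = %.6g\n", x$u_statistic, x$p_two_tailed))
  invisible(x)
}

#' Group means and their ratio
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `mean_x`, `mean_y`, `ratio` (= mean_x / mean_y).
#' @export
group_means <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  list(mean_x = mean(x), mean_y = mean(y), ratio = mean(x) / mean(y))
}

#' Kaplan-Meier product-limit estimate
#'
#' Censored subjects remain in the risk set through their censoring time
#' and leave it afterwards; the survival curve steps only at event times.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1) event indicators aligned with `times`;
#'   default all events.
#' @return Object of class `km_curve`: `event_times` (increasing distinct
#'   times with >= 1 event), `survival_prob`, `at_risk` and `n_events` at
#'   each event time, `censored_times`, `n`, `max_time`.
#' @export
km_estimate <- function(times, events = rep(TRUE, length(times))) {
  times <- as.numeric(times)
  events <- as.logical(events)
  if (length(times) == 0) stop("empty input: no subjects")
  stopifnot(length(events) == length(times), all(times >= 0), !anyNA(times),
            !anyNA(events))
  ev_times <- sort(unique(times[events]))
  at_risk <- vapply(ev_times, function(t) sum(times >= t), integer(1))
  n_events <- vapply(ev_times, function(t) sum(times == t & events),
                     integer(1))
  surv <- cumprod(1 - n_events / at_risk)
  structure(list(event_times = ev_times, survival_prob = surv,
                 at_risk = at_risk, n_events = n_events,
                 censored_times = sort(times[!events]),
                 n = length(times), max_time = max(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' @param curve A [km_estimate()] object.
#' @param t Non-negative time.
#' @return S(t): the step-function value at the latest event time <= t
#'   (1 before the first event).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  idx <- which(curve$event_times <= t)
  if (length(idx) == 0) 1 else curve$survival_prob[max(idx)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", x$n, " subjects, ",
      length(x$event_times), " event times, ",
      length(x$censored_times), " censored\n", sep = "")
  invisible(x)
}

#' Plot a Kaplan-Meier curve
#'
#' @param x A `km_curve`.
#' @param add Add to an existing plot?
#' @param xlab,ylab,col Usual graphical parameters.
#' @param ... Passed to [graphics::lines()].
#' @export
plot.km_curve <- function(x, add = FALSE, xlab = "Months",
                          ylab = "Survival probability", col = 1, ...) {
  tt <- c(0, rep(x$event_times, each = 2), x$max_time)
  ss <- c(1, 1, rep(x$survival_prob, each = 2))
  ss <- ss[seq_along(tt)]
  if (!add) {
    graphics::plot(tt, ss, type = "n", ylim = c(0, 1), xlab = xlab,
                   ylab = ylab)
  }
  graphics::lines(tt, ss, col = col, ...)
  invisible(x)
}

#' One-degree-of-freedom log-rank test
#'
#' Compares the survival experience of two groups by the usual
#' observed-minus-expected decomposition over the pooled event times.
#'
#' @param times_a,events_a Follow-up times and event indicators, group A.
#' @param times_b,events_b Same for group B.
#' @return List with `statistic` (chi-square, 1 df), `p_value`,
#'   `observed` and `expected` event counts for group A.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  times_a <- as.numeric(times_a); times_b <- as.numeric(times_b)
  events_a <- as.logical(events_a); events_b <- as.logical(events_b)
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (!any(events_a) && !any(events_b)) stop("no events in either group")
  all_times <- c(times_a, times_b)
  all_events <- c(events_a, events_b)
  in_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  ev_times <- sort(unique(all_times[all_events]))
  o_a <- e_a <- v <- 0
  for (t in ev_times) {
    at_risk <- all_times >= t
    n_tot <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d_tot <- sum(all_times == t & all_events)
    d_a <- sum(all_times == t & all_events & in_a)
    o_a <- o_a + d_a
    e_a <- e_a + d_tot * n_a / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  stat <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = o_a, expected = e_a)
}

#' Difference in survival probability at a time point
#'
#' @param curve_a,curve_b [km_estimate()] objects.
#' @param t Non-negative time (months).
#' @return `S_a(t) - S_b(t)`, with a truncation warning when `t` lies
#'   beyond both curves' follow-up.
#' @export
survival_gain_at <- function(curve_a, curve_b, t) {
  stopifnot(t >= 0)
  if (t > curve_a$max_time && t > curve_b$max_time) {
    warning("t = ", t, " exceeds follow-up of both curves; ",
            "values are carried forward from the last event time")
  }
  km_survival_at(curve_a, t) - km_survival_at(curve_b, t)
}
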