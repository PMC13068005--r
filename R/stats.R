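#' Two-group rank-sum comparison (Wilcoxon--Mann--Whitney)
#'
#' Two-sided Mann--Whitney U comparison via [stats::wilcox.test()]: exact
#' enumeration for combined n of 10 or fewer without ties, otherwise the
#' normal approximation with midrank tie correction.
#'
#' @param group_a,group_b Numeric vectors (both nonempty).
#' @return A `group_comparison` list: `statistic` (U for `group_a`),
#'   `p_value`, `group_sizes`, `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value   # exact: 0.1
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- n <= 10L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 group_sizes = c(length(group_a), length(group_b)),
                 method = if (exact) "Mann-Whitney U (exact)"
                          else "Mann-Whitney U (normal approximation, tie-corrected)"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = " vs ")))
  invisible(x)
}

#' Rank-based ROC area under the curve
#'
#' AUC = P(score of a positive > score of a negative) + 1/2 P(tie), computed
#' from midranks (the Mann--Whitney scaling).
#'
#' @param scores Numeric predictor values.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return The AUC (scalar in `[0, 1]`).
#' @export
#' @examples
#' roc_auc(c(1, 1, 2), c(0, 1, 1))   # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)   # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Complete/near-complete separation diagnostic
#'
#' A predictor that (almost) perfectly splits the outcome classes makes
#' logistic-regression likelihoods diverge; this diagnostic surfaces the
#' condition explicitly instead of fitting a divergent model.  The overlap
#' measure is the fraction of all subjects whose score lies in the closed
#' intersection of the two class ranges; the flag is `TRUE` for disjoint
#' ranges (complete separation) or when the overlap fraction is below
#' `near_cutoff` (near-complete).
#'
#' @param scores Numeric predictor values.
#' @param labels Binary labels, both classes present.
#' @param near_cutoff Overlap fraction below which separation is called
#'   near-complete (default 0.05).
#' @return List with `flag` (logical) and `overlap` (fraction).
#' @export
#' @examples
#' detect_complete_separation(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
detect_complete_separation <- function(scores, labels, near_cutoff = 0.05) {
  labels <- as.integer(as.logical(labels))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present", call. = FALSE)
  a <- range(scores[labels == 1L])
  b <- range(scores[labels == 0L])
  lo <- max(a[1L], b[1L])
  hi <- min(a[2L], b[2L])
  overlap <- if (lo > hi) 0 else mean(scores >= lo & scores <= hi)
  list(flag = overlap < near_cutoff, overlap = overlap)
}

#' Kaplan--Meier product-limit survival curve
#'
#' Thin wrapper around [survival::survfit()] returning the step function as
#' a plain table.
#'
#' @param event_times Nonnegative follow-up times.
#' @param event_observed Binary flags (1 = event, 0 = censored), aligned with
#'   `event_times`.
#' @return An object of class `"survival_curve"`: data.frame with `time`,
#'   `survival`, `at_risk`, `events` per distinct observed time.
#' @export
#' @examples
#' kaplan_meier(c(1, 2), c(1, 1))   # S(1) = 0.5, S(2) = 0
kaplan_meier <- function(event_times, event_observed) {
  if (any(event_times < 0))
    stop("event times must be nonnegative", call. = FALSE)
  if (length(event_times) != length(event_observed))
    stop("'event_times' and 'event_observed' must be aligned", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(event_times, as.integer(event_observed)) ~ 1,
    conf.type = "none")
  structure(data.frame(time = fit$time, survival = fit$surv,
                       at_risk = fit$n.risk, events = fit$n.event),
            class = c("survival_curve", "data.frame"))
}

#' Log-rank comparison of survival between groups
#'
#' Standard log-rank chi-square (via [survival::survdiff()]) with k - 1
#' degrees of freedom from observed-vs-expected event counts at the pooled
#' event times.
#'
#' @param groups A list of two or more `list(times =, observed =)` elements.
#' @return A `group_comparison` with the chi-square statistic, `df` and
#'   `p_value`.
#' @export
log_rank <- function(groups) {
  if (length(groups) < 2L)
    stop("log-rank needs at least two groups", call. = FALSE)
  times <- unlist(lapply(groups, `[[`, "times"))
  obs <- unlist(lapply(groups, `[[`, "observed"))
  g <- rep(seq_along(groups), vapply(groups, function(x) length(x$times),
                                     integer(1)))
  if (sum(obs) == 0L)
    stop("degenerate log-rank test: no events in any group", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, as.integer(obs)) ~ g)
  df <- length(groups) - 1L
  structure(list(statistic = unname(sd$chisq),
                 df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 group_sizes = as.integer(table(g)),
                 method = "log-rank"),
            class = "group_comparison")
}

#' Empirical tertile assignment
#'
#' Boundaries at the empirical 1/3 and 2/3 quantiles; values equal to a
#' boundary go to the lower tertile.  If all values are identical every
#' subject lands in tertile 1 and a warning is emitted.
#'
#' @param values Nonempty numeric vector.
#' @return Integer vector of tertile labels (1, 2, 3) aligned with `values`.
#' @export
#' @examples
#' tertile_split(1:9)
tertile_split <- function(values) {
  if (length(values) == 0L) stop("'values' must be nonempty", call. = FALSE)
  q <- stats::quantile(values, c(1, 2) / 3, names = FALSE)
  out <- 1L + (values > q[1L]) + (values > q[2L])
  if (length(unique(values)) == 1L)
    warning("all values identical: every subject assigned to tertile 1")
  as.integer(out)
}

#' Kaplan--Meier curves by time-to-peak tertile
#'
#' The virtual analogue of delay-tertile survival stratification: subjects
#' are split by empirical tertiles of time-to-peak Y; for event-positive
#' subjects the event time is the time at which Y first reaches its maximum,
#' and event-free subjects are censored at the end of the simulation window.
#'
#' @param cohort A labelled `cascade_cohort`.
#' @return List with `curves` (three `survival_curve` tables, named T1-T3),
#'   `tertile` (per-subject assignment), `event_fraction` (per tertile) and
#'   `comparison` (the log-rank test, `NULL` when no events occurred).
#' @export
km_by_delay_tertiles <- function(cohort) {
  stopifnot(inherits(cohort, "cascade_cohort"))
  m <- cohort$metrics
  if (anyNA(m$event_cv)) stop("cohort must be labelled", call. = FALSE)
  if (length(unique(m$time_to_peak_y)) < 3L)
    stop("stratification needs at least 3 distinct time-to-peak values",
         call. = FALSE)
  tert <- tertile_split(m$time_to_peak_y)
  t_end <- cohort$model$grid$t_end
  time <- ifelse(m$event_cv == 1L, m$time_to_peak_y, t_end)
  groups <- lapply(1:3, function(k)
    list(times = time[tert == k], observed = m$event_cv[tert == k]))
  curves <- lapply(groups, function(gr)
    kaplan_meier(gr$times, gr$observed))
  names(curves) <- paste0("T", 1:3)
  cmp <- if (sum(m$event_cv) > 0L) log_rank(groups)
  list(curves = curves, tertile = tert,
       event_fraction = vapply(groups, function(gr) mean(gr$observed),
                               numeric(1)),
       comparison = cmp)
}

#' Plot a set of survival curves
#'
#' @param curves Named list of `survival_curve` tables.
#' @param main Plot title.
#' @param ... Passed to [plot()].
#' @export
plot_survival_curves <- function(curves, main = "Survival curves", ...) {
  t_max <- max(unlist(lapply(curves, function(cv) max(cv$time))))
  plot(NULL, xlim = c(0, t_max), ylim = c(0, 1),
       xlab = "time (abstract units)", ylab = "event-free survival",
       main = main, ...)
  cols <- c("steelblue", "darkorange", "firebrick")
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$survival)),
                    col = cols[(i - 1L) %% 3L + 1L], do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = names(curves),
                   col = cols[seq_along(curves)], lty = 1, bty = "n")
  invisible(curves)
}
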