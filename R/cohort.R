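#' Simulate a cohort of virtual subjects
#'
#' Integrates the cascade for `n_subjects` independent virtual subjects, all
#' exposed to the same stressor.  Per-subject seeds are spawned
#' deterministically from `master_seed` (one `sample.int` draw without
#' replacement), so the cohort is a pure function of
#' `(parameters, n_subjects, master_seed)` and any single subject can be
#' re-integrated in isolation from its stored seed.
#'
#' @param params A [cascade_model()], or a list of `n_subjects` of them for
#'   heterogeneous cohorts (see [draw_heterogeneous_parameters()]).
#' @param n_subjects Number of virtual subjects (default 100).
#' @param master_seed Integer master seed.
#' @param keep_paths Keep the full trajectories (default `TRUE`); with
#'   `FALSE` only per-subject metrics are retained, which is cheaper for
#'   multi-seed sweeps.
#' @param engine `"compiled"` (default) uses the cascade-specialised
#'   Euler--Maruyama stepper; `"generic"` routes through [integrate_sdde()]
#'   on [build_cascade_system()].  Both produce identical trajectories.
#'
#' @return A list with `trajectories` (possibly `NULL`) and `metrics`
#'   (data.frame: `subject_id`, `max_y`, `time_to_peak_y`, `seed`).
#' @seealso [simulate.cascade_model()] for the labelled-cohort front end.
#' @export
simulate_cohort <- function(params, n_subjects = 100, master_seed = 1,
                            keep_paths = TRUE,
                            engine = c("compiled", "generic")) {
  engine <- match.arg(engine)
  if (n_subjects < 1) stop("'n_subjects' must be >= 1", call. = FALSE)
  per_subject <- is.list(params) && !inherits(params, "cascade_model")
  if (per_subject && length(params) != n_subjects)
    stop("per-subject parameter list must have length n_subjects",
         call. = FALSE)
  seeds <- spawn_seeds(master_seed, n_subjects)

  trajectories <- if (keep_paths) vector("list", n_subjects)
  metrics <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- if (per_subject) params[[i]] else params
    tr <- tryCatch(
      integrate_cascade(p, seed = seeds[i], subject_id = i, engine = engine),
      error = function(e)
        stop(sprintf("subject %d: %s", i, conditionMessage(e)),
             call. = FALSE))
    metrics[[i]] <- extract_metrics(tr)
    if (keep_paths) trajectories[[i]] <- tr
  }
  metrics <- do.call(rbind, metrics)
  metrics$seed <- seeds
  list(trajectories = trajectories, metrics = metrics)
}

# Integrate one subject of the cascade; the compiled and generic engines are
# step-for-step identical (tested).
integrate_cascade <- function(p, seed, subject_id = 1L,
                              engine = c("compiled", "generic")) {
  engine <- match.arg(engine)
  stopifnot(inherits(p, "cascade_model"))
  grid <- p$grid
  pre <- cascade_pre_history(p)
  if (engine == "generic") {
    tr <- integrate_sdde(build_cascade_system(p), pre, grid, seed,
                         subject_id = subject_id)
  } else {
    n <- grid$n_steps
    dW <- with_seed(seed, matrix(stats::rnorm(n * 4L), nrow = n, ncol = 4L)) *
      sqrt(grid$dt)
    taus <- unlist(p[.cascade_tau_names])
    states <- .cascade_em_cpp(
      rates = unlist(p[.cascade_rate_names]),
      lag_steps = delay_steps(taus, grid$dt),
      sigma = unlist(p[.cascade_sigma_names]),
      pre_history = pre,
      stressor = c(p$stressor$amplitude, p$stressor$onset,
                   p$stressor$duration, p$tau1),
      t0 = grid$t0, dt = grid$dt, n_steps = n, dW = dW)
    tr <- structure(
      list(grid = grid, times = grid$times, states = states,
           seed = as.integer(seed), subject_id = as.integer(subject_id),
           clipped = NA_integer_,
           clipping = "componentwise at 0 after each step"),
      class = "sdde_trajectory")
  }
  colnames(tr$states) <- c("B1", "B2", "B3", "Y")
  tr
}

#' Per-subject trajectory metrics
#'
#' The peak of the latent output Y and the time at which it is first
#' attained (first-occurrence tie-break); the event label is added later by
#' [label_events()].
#'
#' @param traj An `sdde_trajectory` whose last state column is Y (or a
#'   one-column path).
#' @return One-row data.frame: `subject_id`, `max_y`, `time_to_peak_y`,
#'   `event_cv` (`NA` until labelled).
#' @export
extract_metrics <- function(traj) {
  stopifnot(inherits(traj, "sdde_trajectory"))
  y <- traj$states[, ncol(traj$states)]
  if (length(y) == 0L) stop("empty trajectory", call. = FALSE)
  peak <- which.max(y)   # first index attaining the maximum
  data.frame(subject_id = traj$subject_id,
             max_y = y[peak],
             time_to_peak_y = traj$times[peak],
             event_cv = NA_integer_)
}

#' Calibrate the event threshold to a target prevalence
#'
#' Returns the `ceiling(n * (1 - prevalence))`-th order statistic of the
#' per-subject peak values.  With the strict-exceedance labelling rule of
#' [label_events()] and distinct values this yields exactly
#' `round(n * prevalence)` events.
#'
#' @param max_y_values Numeric vector of per-subject peaks.
#' @param prevalence Target event fraction in `[0, 1]`.
#' @return The threshold (scalar).  `prevalence = 0` gives the maximum
#'   (zero events); `prevalence = 1` gives `-Inf` (all events).
#' @export
#' @examples
#' calibrate_threshold(1:5, 0.2)   # 4: only the subject at 5 is an event
calibrate_threshold <- function(max_y_values, prevalence) {
  if (length(max_y_values) == 0L)
    stop("'max_y_values' must be nonempty", call. = FALSE)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence < 0 || prevalence > 1)
    stop("'prevalence' must be a single number in [0, 1]", call. = FALSE)
  n <- length(max_y_values)
  k <- ceiling(n * (1 - prevalence))
  if (k == 0L) -Inf else sort(max_y_values)[k]
}

#' Label cardiovascular events by threshold exceedance
#'
#' `event_cv = 1` iff `max_y` strictly exceeds the threshold.  If ties at the
#' threshold leave fewer than `round(n * prevalence)` events, tied subjects
#' are promoted in subject-index order to preserve the exact prevalence
#' (reported via a message); this cannot occur with continuous noise.
#'
#' @param metrics Metrics data.frame with `max_y` (and `subject_id`).
#' @param threshold Finite (or `-Inf`) event cutoff on the raw max-Y scale.
#' @param prevalence Optional target prevalence enabling tie promotion.
#' @return `metrics` with `event_cv` filled in.
#' @export
label_events <- function(metrics, threshold, prevalence = NULL) {
  if (length(threshold) != 1L || is.na(threshold) || threshold == Inf)
    stop("'threshold' must be a single finite (or -Inf) value",
         call. = FALSE)
  metrics$event_cv <- as.integer(metrics$max_y > threshold)
  if (!is.null(prevalence)) {
    want <- round(nrow(metrics) * prevalence)
    short <- want - sum(metrics$event_cv)
    if (short > 0L) {
      tied <- which(metrics$max_y == threshold)
      tied <- tied[order(metrics$subject_id[tied])]
      promote <- utils::head(tied, short)
      if (length(promote)) {
        metrics$event_cv[promote] <- 1L
        message(sprintf("tie at threshold: promoted %d subject(s) by index to preserve prevalence",
                        length(promote)))
      }
    }
  }
  metrics
}

#' Simulate, label and normalise a virtual cohort
#'
#' The front end of the simulator: integrates `nsim` virtual subjects from a
#' [cascade_model()], extracts per-subject metrics, calibrates the event
#' threshold so that the target prevalence of subjects exceed it, labels
#' events, and attaches the normalisation mapping the calibrated cutoff to
#' the nominal value 1.5.
#'
#' @param object A [cascade_model()].
#' @param nsim Number of virtual subjects (default 100).
#' @param seed Master seed (default 1).
#' @param prevalence Target event prevalence (default 0.2).
#' @param keep_paths,engine Passed to [simulate_cohort()].
#' @param ... Unused.
#'
#' @return An object of class `"cascade_cohort"`: list with `model`,
#'   `trajectories`, `metrics` (with `max_y_normalized` and `event_cv`),
#'   `threshold`, `normalization_factor`, `prevalence`, `master_seed`.
#' @export
#' @examples
#' \donttest{
#' m <- cascade_model("paper2026")
#' co <- simulate(m, nsim = 20, seed = 1)
#' summary(co)
#' }
simulate.cascade_model <- function(object, nsim = 100, seed = 1,
                                   prevalence = 0.2, keep_paths = TRUE,
                                   engine = "compiled", ...) {
  sim <- simulate_cohort(object, n_subjects = nsim, master_seed = seed,
                         keep_paths = keep_paths, engine = engine)
  threshold <- calibrate_threshold(sim$metrics$max_y, prevalence)
  metrics <- label_events(sim$metrics, threshold, prevalence)
  cohort <- structure(
    list(model = object, trajectories = sim$trajectories, metrics = metrics,
         threshold = threshold, normalization_factor = NA_real_,
         prevalence = prevalence, master_seed = as.integer(seed)),
    class = "cascade_cohort")
  normalize_output(cohort)
}

#' Attach the normalised-Y view of a cohort
#'
#' The calibrated raw threshold is mapped to the nominal cutoff 1.5 on a
#' normalised Y scale: `normalization_factor = 1.5 / threshold`, and
#' `max_y_normalized = max_y * normalization_factor`.  Raw paths are left
#' untouched; an event on the raw scale is exactly an event on the
#' normalised scale.
#'
#' @param cohort A `cascade_cohort` with a calibrated threshold.
#' @return The cohort with `normalization_factor` and the
#'   `max_y_normalized` metrics column set.
#' @export
normalize_output <- function(cohort) {
  stopifnot(inherits(cohort, "cascade_cohort"))
  if (!is.finite(cohort$threshold) || cohort$threshold <= 0)
    stop("normalization requires a positive finite threshold", call. = FALSE)
  cohort$normalization_factor <- 1.5 / cohort$threshold
  cohort$metrics$max_y_normalized <-
    cohort$metrics$max_y * cohort$normalization_factor
  cohort$metrics <- cohort$metrics[, c("subject_id", "max_y",
                                       "max_y_normalized", "time_to_peak_y",
                                       "event_cv", "seed")]
  cohort
}

#' @export
print.cascade_cohort <- function(x, ...) {
  n <- nrow(x$metrics)
  cat(sprintf("Virtual cohort: %d subjects (preset \"%s\", master seed %d)\n",
              n, x$model$preset, x$master_seed))
  cat(sprintf("  events: %d (target prevalence %.0f%%), raw threshold %.4g (normalised 1.5)\n",
              sum(x$metrics$event_cv), 100 * x$prevalence, x$threshold))
  invisible(x)
}

#' Summarise a simulated cohort
#'
#' Group means of time-to-peak Y by event status, the two-sided rank-sum
#' comparison, the rank-based AUC of time-to-peak against the event label,
#' and the complete-separation diagnostic.
#'
#' @param object A `cascade_cohort`.
#' @param ... Unused.
#' @return An object of class `"summary.cascade_cohort"`.
#' @export
summary.cascade_cohort <- function(object, ...) {
  m <- object$metrics
  ev <- m$event_cv == 1L
  cmp <- if (any(ev) && any(!ev))
    rank_sum_test(m$time_to_peak_y[ev], m$time_to_peak_y[!ev])
  auc <- if (any(ev) && any(!ev)) roc_auc(m$time_to_peak_y, m$event_cv)
  sep <- if (any(ev) && any(!ev))
    detect_complete_separation(m$time_to_peak_y, m$event_cv)
  out <- list(
    n = nrow(m), n_events = sum(ev),
    threshold = object$threshold,
    normalization_factor = object$normalization_factor,
    mean_ttp_event = mean(m$time_to_peak_y[ev]),
    mean_ttp_nonevent = mean(m$time_to_peak_y[!ev]),
    rank_test = cmp, auc = auc, separation = sep)
  class(out) <- "summary.cascade_cohort"
  out
}

#' @export
print.summary.cascade_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d subjects, %d events\n", x$n, x$n_events))
  cat(sprintf("  raw threshold %.4g (x %.4g -> nominal 1.5)\n",
              x$threshold, x$normalization_factor))
  cat(sprintf("  mean time-to-peak Y: %.1f (events) vs %.1f (non-events)\n",
              x$mean_ttp_event, x$mean_ttp_nonevent))
  if (!is.null(x$rank_test))
    cat(sprintf("  rank-sum test: U = %g, p = %.3g\n",
                x$rank_test$statistic, x$rank_test$p_value))
  if (!is.null(x$auc))
    cat(sprintf("  AUC of time-to-peak vs event: %.3f\n", x$auc))
  if (!is.null(x$sep <- x$separation))
    cat(sprintf("  %s separation (overlap fraction %.3f)\n",
                if (x$sep$flag) "near-complete" else "no near-complete",
                x$sep$overlap))
  invisible(x)
}

#' @export
as.data.frame.cascade_cohort <- function(x, ..., what = c("metrics", "paths")) {
  what <- match.arg(what)
  if (what == "metrics") return(x$metrics)
  if (is.null(x$trajectories))
    stop("trajectories were not kept (keep_paths = FALSE)", call. = FALSE)
  do.call(rbind, lapply(x$trajectories, as.data.frame))
}

#' Plot a simulated cohort
#'
#' Latent-output trajectories coloured by event status (requires kept
#' paths), or the Kaplan--Meier curves by time-to-peak tertile.
#'
#' @param x A `cascade_cohort`.
#' @param type `"paths"` or `"km"`.
#' @param ... Passed to the underlying plot.
#' @export
plot.cascade_cohort <- function(x, type = c("paths", "km"), ...) {
  type <- match.arg(type)
  if (type == "paths") {
    if (is.null(x$trajectories))
      stop("trajectories were not kept (keep_paths = FALSE)", call. = FALSE)
    ev <- x$metrics$event_cv == 1L
    ylim <- range(vapply(x$trajectories, function(tr) max(tr$states[, 4L]),
                         numeric(1)))
    plot(NULL, xlim = range(x$trajectories[[1L]]$times), ylim = c(0, ylim[2L]),
         xlab = "time (abstract units)", ylab = "Y(t)",
         main = "Latent output trajectories by event status", ...)
    for (i in seq_along(x$trajectories))
      graphics::lines(x$trajectories[[i]]$times,
                      x$trajectories[[i]]$states[, 4L],
                      col = if (ev[i]) grDevices::adjustcolor("firebrick", 0.5)
                            else grDevices::adjustcolor("grey40", 0.3))
    graphics::legend("topright", legend = c("event", "no event"),
                     col = c("firebrick", "grey40"), lty = 1, bty = "n")
  } else {
    km <- km_by_delay_tertiles(x)
    plot_survival_curves(km$curves,
                         main = "Event-free survival by time-to-peak tertile",
                         ...)
  }
  invisible(x)
}
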