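#' Relabel events at an alternative prevalence
#'
#' Recalibrates the event threshold at the requested prevalence, relabels
#' events, and summarises the association between time-to-peak Y and the new
#' labels.
#'
#' @param metrics Cohort metrics data.frame (from [simulate.cascade_model()]
#'   or [simulate_cohort()]).
#' @param prevalence Target event fraction.
#' @param score_column Column used for relabelling (default `"max_y"`;
#'   `"max_y_obs"` after [add_outcome_noise()]).
#' @return List with `threshold`, `metrics` (relabelled), and `summary`
#'   (event count, group means of time-to-peak, rank-test p, AUC, and a
#'   `degenerate` flag when one group is empty).
#' @export
relabel_at_prevalence <- function(metrics, prevalence,
                                  score_column = "max_y") {
  if (nrow(metrics) == 0L) stop("'metrics' must be nonempty", call. = FALSE)
  threshold <- calibrate_threshold(metrics[[score_column]], prevalence)
  lab <- metrics
  lab$max_y <- metrics[[score_column]]   # label on the chosen score
  lab <- label_events(lab, threshold, prevalence)
  metrics$event_cv <- lab$event_cv
  ev <- metrics$event_cv == 1L
  degenerate <- !any(ev) || all(ev)
  summ <- list(
    n_events = sum(ev),
    mean_ttp_event = if (any(ev)) mean(metrics$time_to_peak_y[ev]) else NA_real_,
    mean_ttp_nonevent = if (any(!ev)) mean(metrics$time_to_peak_y[!ev]) else NA_real_,
    p_value = if (!degenerate)
      rank_sum_test(metrics$time_to_peak_y[ev],
                    metrics$time_to_peak_y[!ev])$p_value else NA_real_,
    auc = if (!degenerate) roc_auc(metrics$time_to_peak_y, metrics$event_cv)
          else NA_real_,
    degenerate = degenerate)
  list(threshold = threshold, metrics = metrics, summary = summ)
}

#' Add independent outcome noise at the event-definition stage
#'
#' Observed peaks are `max_y_obs = max_y + eps` with independent Gaussian
#' `eps` of mean 0 and SD equal to `sd_fraction` times the cohort SD of
#' `max_y`.  Trajectories and the stored `max_y` are untouched; event
#' relabelling then uses `max_y_obs`.
#'
#' @param metrics Cohort metrics data.frame with at least 2 rows.
#' @param sd_fraction Noise scale as a fraction of the cohort SD of max Y
#'   (default 0.15, the midpoint of the 10--20% band).
#' @param seed Integer seed for the noise draws.
#' @return `metrics` with a `max_y_obs` column appended.
#' @export
add_outcome_noise <- function(metrics, sd_fraction = 0.15, seed = 1) {
  if (sd_fraction < 0 || sd_fraction > 1)
    stop("'sd_fraction' must be in [0, 1]", call. = FALSE)
  if (nrow(metrics) < 2L)
    stop("outcome noise needs >= 2 subjects (SD undefined otherwise)",
         call. = FALSE)
  sd_noise <- sd_fraction * stats::sd(metrics$max_y)
  eps <- with_seed(seed, stats::rnorm(nrow(metrics), 0, sd_noise))
  metrics$max_y_obs <- metrics$max_y + eps
  metrics
}

#' Draw heterogeneous per-subject parameter sets
#'
#' Inter-individual heterogeneity: each listed parameter is drawn
#' independently per subject from a normal distribution centred on its
#' nominal value with coefficient of variation `cv`; non-positive draws are
#' rejected and redrawn (preserving the distribution shape); delays are
#' snapped to the nearest positive grid multiple.  By default the delay and
#' gain terms linking CRP and albumin to the output are perturbed
#' (`tau7`, `tau8`, `beta1`, `beta2`); the minimal CRP-arm-only choice is
#' `parameters = c("tau7", "beta1")`.
#'
#' @param nominal A [cascade_model()].
#' @param n_subjects Number of parameter sets to draw.
#' @param cv Coefficient of variation (default 0.10).
#' @param parameters Character vector of parameter names to perturb.
#' @param seed Integer seed.
#' @return List of `n_subjects` `cascade_model` objects; attribute
#'   `"rejections"` counts redrawn non-positive values.
#' @export
draw_heterogeneous_parameters <- function(nominal, n_subjects, cv = 0.10,
                                          parameters = c("tau7", "tau8",
                                                         "beta1", "beta2"),
                                          seed = 1) {
  stopifnot(inherits(nominal, "cascade_model"))
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  bad <- setdiff(parameters, .cascade_param_names)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dt <- nominal$grid$dt
  rejections <- 0L
  draws <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      vals <- vapply(parameters, function(nm) {
        mu <- nominal[[nm]]
        if (cv == 0 || mu == 0) return(mu)
        repeat {
          v <- stats::rnorm(1L, mu, cv * mu)
          if (v > 0) return(v)
          rejections <<- rejections + 1L
        }
      }, numeric(1))
      vals
    })
  })
  nominal_values <- nominal[c(delaytwin_param_names(),
                              delaytwin_baseline_names())]
  out <- lapply(draws, function(vals) {
    is_tau <- grepl("^tau", names(vals))
    vals[is_tau] <- pmax(round(vals[is_tau] / dt), 1) * dt
    full <- utils::modifyList(nominal_values, as.list(vals))
    do.call(cascade_model,
            c(list(preset = nominal$preset, grid = nominal$grid,
                   stressor = nominal$stressor), full))
  })
  attr(out, "rejections") <- rejections
  out
}

#' Simulate one perturbed cohort and score its discrimination
#'
#' The combined perturbation used to probe robustness: 10%-CV (by default)
#' parameter heterogeneity across subjects plus independent outcome noise at
#' the event-definition stage, followed by relabelling at the target
#' prevalence.  Returns the AUC of time-to-peak Y against the noisy labels
#' and the separation diagnostic.
#'
#' @param model A [cascade_model()].
#' @param n_subjects Cohort size (default 100).
#' @param master_seed Integer seed driving heterogeneity draws, trajectories
#'   and outcome noise.
#' @param sd_fraction Outcome-noise scale (default 0.15).
#' @param cv Heterogeneity coefficient of variation (default 0.10).
#' @param parameters Parameters perturbed across subjects.
#' @param prevalence Event prevalence for relabelling (default 0.2).
#' @return List with `auc`, `separation`, `summary` (from
#'   [relabel_at_prevalence()]) and `metrics`.
#' @export
perturbed_discrimination <- function(model, n_subjects = 100, master_seed = 1,
                                     sd_fraction = 0.15, cv = 0.10,
                                     parameters = c("tau7", "tau8",
                                                    "beta1", "beta2"),
                                     prevalence = 0.2) {
  subseeds <- with_seed(master_seed, sample.int(2147483646L, 3L))
  het <- draw_heterogeneous_parameters(model, n_subjects, cv = cv,
                                       parameters = parameters,
                                       seed = subseeds[1L])
  sim <- simulate_cohort(het, n_subjects, master_seed = subseeds[2L],
                         keep_paths = FALSE)
  noisy <- if (sd_fraction > 0) {
    add_outcome_noise(sim$metrics, sd_fraction, seed = subseeds[3L])
  } else {
    m <- sim$metrics
    m$max_y_obs <- m$max_y
    m
  }
  rel <- relabel_at_prevalence(noisy, prevalence, score_column = "max_y_obs")
  sep <- if (!rel$summary$degenerate)
    detect_complete_separation(rel$metrics$time_to_peak_y,
                               rel$metrics$event_cv)
  list(auc = rel$summary$auc, separation = sep, summary = rel$summary,
       metrics = rel$metrics)
}

#' Run the full sensitivity suite
#'
#' The three robustness analyses on a common base cohort:
#' \enumerate{
#'   \item event-prevalence variation (thresholds recalibrated at 15%, 20%
#'     and 30% prevalence);
#'   \item independent outcome noise at the event-definition stage;
#'   \item inter-individual parameter heterogeneity (combined with the
#'     outcome noise for the perturbed-discrimination readout).
#' }
#'
#' @param preset Preset name or a [cascade_model()].
#' @param master_seed Integer master seed; the whole report is a pure
#'   function of `(preset, master_seed)`.
#' @param n_subjects Cohort size (default 100).
#' @param prevalences Prevalences for analysis 1.
#' @param sd_fraction Outcome-noise scale for analyses 2-3.
#' @param cv Heterogeneity CV for analysis 3.
#' @param parameters Parameters perturbed in analysis 3.
#' @return An object of class `"sensitivity_report"` with elements `base`
#'   (the unperturbed cohort summary incl. separation flag), `prevalence`,
#'   `outcome_noise` and `heterogeneity` analysis blocks.
#' @export
run_sensitivity_suite <- function(preset = "paper2026", master_seed = 1,
                                  n_subjects = 100,
                                  prevalences = c(0.15, 0.20, 0.30),
                                  sd_fraction = 0.15, cv = 0.10,
                                  parameters = c("tau7", "tau8",
                                                 "beta1", "beta2")) {
  model <- if (inherits(preset, "cascade_model")) preset
           else cascade_model(preset)
  base <- simulate(model, nsim = n_subjects, seed = master_seed,
                   keep_paths = FALSE)
  base_sum <- summary(base)

  prev_block <- lapply(prevalences, function(p) {
    rel <- relabel_at_prevalence(base$metrics, p)
    c(list(prevalence = p, threshold = rel$threshold), rel$summary)
  })

  noise_seed <- (master_seed + 499979L) %% 2147483647L
  noisy <- add_outcome_noise(base$metrics, sd_fraction, seed = noise_seed)
  noise_rel <- relabel_at_prevalence(noisy, base$prevalence,
                                     score_column = "max_y_obs")
  noise_block <- c(list(sd_fraction = sd_fraction,
                        threshold = noise_rel$threshold,
                        separation = if (!noise_rel$summary$degenerate)
                          detect_complete_separation(
                            noise_rel$metrics$time_to_peak_y,
                            noise_rel$metrics$event_cv)),
                   noise_rel$summary)

  het <- perturbed_discrimination(model, n_subjects,
                                  master_seed = master_seed + 1L,
                                  sd_fraction = sd_fraction, cv = cv,
                                  parameters = parameters,
                                  prevalence = base$prevalence)
  het_block <- c(list(cv = cv, parameters = parameters,
                      separation = het$separation), het$summary)

  structure(list(preset = model$preset, master_seed = master_seed,
                 n_subjects = n_subjects,
                 base = list(summary = base_sum,
                             separation = base_sum$separation),
                 prevalence = prev_block,
                 outcome_noise = noise_block,
                 heterogeneity = het_block),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity suite (preset \"%s\", master seed %d, n = %d)\n",
              x$preset, x$master_seed, x$n_subjects))
  bs <- x$base$summary
  cat(sprintf("Base cohort: mean time-to-peak %.1f (events) vs %.1f (non-events), AUC %.3f, %snear-complete separation\n",
              bs$mean_ttp_event, bs$mean_ttp_nonevent, bs$auc,
              if (bs$separation$flag) "" else "no "))
  cat("1. Prevalence variation:\n")
  for (b in x$prevalence)
    cat(sprintf("   prevalence %.0f%%: %d events, group means %.1f vs %.1f, p = %.3g, AUC %.3f\n",
                100 * b$prevalence, b$n_events, b$mean_ttp_event,
                b$mean_ttp_nonevent, b$p_value, b$auc))
  nb <- x$outcome_noise
  cat(sprintf("2. Outcome noise (sd_fraction %.2f): %d events, AUC %.3f, %snear-complete separation\n",
              nb$sd_fraction, nb$n_events, nb$auc,
              if (isTRUE(nb$separation$flag)) "" else "no "))
  hb <- x$heterogeneity
  cat(sprintf("3. Heterogeneity (cv %.2f on %s) + outcome noise: %d events, AUC %.3f, %snear-complete separation\n",
              hb$cv, paste(hb$parameters, collapse = ", "), hb$n_events,
              hb$auc, if (isTRUE(hb$separation$flag)) "" else "no "))
  invisible(x)
}
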