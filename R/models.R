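# Parameter names of the four-variable cascade, one per model symbol:
# gains/clearances (alpha, gamma, theta, beta), noise intensities (sigma),
# lags (tau).
.cascade_rate_names <- c("alpha1", "alpha2", "gamma1", "gamma2",
                         "theta1", "theta2", "theta3",
                         "beta1", "beta2", "beta3")
.cascade_sigma_names <- paste0("sigma", 1:4)
.cascade_tau_names <- paste0("tau", 1:9)
.cascade_param_names <- c(.cascade_rate_names, .cascade_sigma_names,
                          .cascade_tau_names)
.cascade_baseline_names <- c("baseline_b1", "baseline_b2", "baseline_b3",
                             "baseline_y")

delaytwin_param_names <- function() .cascade_param_names
delaytwin_baseline_names <- function() .cascade_baseline_names

preset_dir <- function() {
  system.file("extdata", "presets", package = "delaytwin", mustWork = TRUE)
}

#' List shipped parameter presets
#'
#' @return Character vector of preset names available to [cascade_model()].
#' @export
list_presets <- function() {
  sub("\\.yaml$", "", list.files(preset_dir(), pattern = "\\.yaml$"))
}

#' Delayed inflammatory cascade model
#'
#' Constructs the four-variable stochastic delay model of an inflammatory
#' biomarker cascade: a stressor pulse S(t) drives neutrophils (B1), which
#' induce C-reactive protein (B2), which suppresses albumin (B3); a latent
#' cardio-inflammatory output Y is driven positively by CRP and negatively by
#' albumin.  The dynamics are
#' \deqn{dB_1 = [\alpha_1 S(t-\tau_1) - \alpha_2 B_1(t-\tau_2)]dt +
#'       \sigma_1 B_1(t-\tau_2)dW_1}
#' \deqn{dB_2 = [\gamma_1 B_1(t-\tau_3) - \gamma_2 B_2(t-\tau_4)]dt +
#'       \sigma_2 B_2(t-\tau_4)dW_2}
#' \deqn{dB_3 = [\theta_1 - \theta_2 B_2(t-\tau_5) - \theta_3 B_3(t-\tau_6)]dt +
#'       \sigma_3 B_3(t-\tau_6)dW_3}
#' \deqn{dY = [\beta_1 B_2(t-\tau_7) - \beta_2 B_3(t-\tau_8) -
#'       \beta_3 Y(t-\tau_9)]dt + \sigma_4 Y(t-\tau_9)dW_4}
#' with independent Wiener processes \eqn{W_1,\ldots,W_4}.  Time is in
#' abstract units; delays respect the fast (neutrophil), intermediate (CRP),
#' slow (albumin) ordering of the cascade.
#'
#' Parameter values come from a named preset shipped with the package (a
#' plain YAML file, version-pinned by MD5 hash) and can be overridden
#' individually through `...`.
#'
#' @param preset Name of a shipped preset; see [list_presets()].  The default
#'   `"paper2026"` is the package's calibrated reference parameterisation.
#' @param ... Named overrides for individual parameters (e.g. `sigma4 = 0`,
#'   `tau7 = 2`) or baselines (`baseline_y = 0`).
#' @param grid Optional [time_grid()] replacing the preset's grid.
#' @param stressor Optional [stressor_spec()] replacing the preset's input.
#'
#' @return An object of class `"cascade_model"`: parameter list plus grid,
#'   stressor, preset name and preset file hash.
#' @seealso [simulate.cascade_model()], [build_cascade_system()],
#'   [coef.cascade_model()]
#' @export
#' @examples
#' m <- cascade_model("paper2026")
#' coef(m)[c("alpha1", "tau7", "sigma4")]
cascade_model <- function(preset = "paper2026", ..., grid = NULL,
                          stressor = NULL) {
  path <- file.path(preset_dir(), paste0(preset, ".yaml"))
  if (!file.exists(path))
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(list_presets(), collapse = ", ")), call. = FALSE)
  raw <- yaml::read_yaml(path)

  p <- raw[c(.cascade_param_names, .cascade_baseline_names)]
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides),
                   c(.cascade_param_names, .cascade_baseline_names))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    p[names(overrides)] <- overrides
  }
  if (is.null(grid))
    grid <- time_grid(raw$grid$t0, raw$grid$t_end, raw$grid$dt)
  if (is.null(stressor))
    stressor <- stressor_spec(raw$stressor$amplitude, raw$stressor$onset,
                              raw$stressor$duration)

  model <- structure(
    c(p, list(stressor = stressor, grid = grid, preset = preset,
              preset_hash = unname(tools::md5sum(path)),
              modified = length(overrides) > 0L)),
    class = "cascade_model")
  validate_cascade_model(model)
  model
}

validate_cascade_model <- function(m) {
  num <- unlist(m[c(.cascade_param_names, .cascade_baseline_names)])
  if (length(num) != length(.cascade_param_names) +
      length(.cascade_baseline_names) || anyNA(num))
    stop("incomplete cascade parameter set", call. = FALSE)
  if (any(unlist(m[c(.cascade_rate_names, .cascade_sigma_names)]) < 0))
    stop("rates and noise intensities must be >= 0", call. = FALSE)
  taus <- unlist(m[.cascade_tau_names])
  if (any(taus < 0)) stop("delays must be >= 0", call. = FALSE)
  dt <- m$grid$dt
  if (any(abs(taus / dt - round(taus / dt)) > 1e-8))
    stop("delays must be integer multiples of the grid step", call. = FALSE)
  # fast -> intermediate -> slow ordering of the cascade lags
  if (max(m$tau1, m$tau2) > min(m$tau3, m$tau4) + 1e-12 ||
      max(m$tau3, m$tau4) > min(m$tau5, m$tau6) + 1e-12)
    stop("delay ordering violated: need tau1,tau2 <= tau3,tau4 <= tau5,tau6",
         call. = FALSE)
  invisible(m)
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("Delayed inflammatory cascade model (preset \"%s\"%s)\n",
              x$preset, if (isTRUE(x$modified)) ", modified" else ""))
  cat(sprintf("  states: B1 (neutrophils), B2 (CRP), B3 (albumin), Y (latent output)\n"))
  cat(sprintf("  gains: alpha = (%g, %g)  gamma = (%g, %g)  theta = (%g, %g, %g)  beta = (%g, %g, %g)\n",
              x$alpha1, x$alpha2, x$gamma1, x$gamma2,
              x$theta1, x$theta2, x$theta3, x$beta1, x$beta2, x$beta3))
  cat(sprintf("  noise:  sigma = (%g, %g, %g, %g)\n",
              x$sigma1, x$sigma2, x$sigma3, x$sigma4))
  cat(sprintf("  lags:   tau = (%s)\n",
              paste(unlist(x[.cascade_tau_names]), collapse = ", ")))
  print(x$stressor)
  print(x$grid)
  invisible(x)
}

#' @describeIn cascade_model Named vector of all model parameters
#'   (gains, noise intensities, lags).
#' @param object,x A `cascade_model`.
#' @export
coef.cascade_model <- function(object, ...) {
  unlist(object[.cascade_param_names])
}

#' Default cascade parameters by preset name
#'
#' Convenience lookup returning the fully specified, version-pinned
#' parameter set for a named preset.
#'
#' @param preset_name Preset identifier (default `"paper2026"`).
#' @return A [cascade_model()].
#' @export
default_parameters <- function(preset_name = "paper2026") {
  cascade_model(preset_name)
}

#' Build the generic SDDE system for a cascade model
#'
#' Expresses the four cascade equations as a generic [sdde_system()] so that
#' they can be integrated by [integrate_sdde()].  Cohort simulation normally
#' uses an equivalent compiled fast path; this constructor is the reference
#' definition the fast path is tested against.
#'
#' @param p A [cascade_model()].
#' @return An [sdde_system()] with state `(B1, B2, B3, Y)` and the nine lags
#'   `tau1..tau9`.
#' @export
build_cascade_system <- function(p) {
  stopifnot(inherits(p, "cascade_model"))
  stressor <- p$stressor
  sdde_system(
    state_dim = 4L,
    delays = unlist(p[.cascade_tau_names]),
    drift = function(t, x, xlag) {
      c(p$alpha1 * stressor_value(stressor, t - p$tau1) -
          p$alpha2 * xlag[1L, 2L],
        p$gamma1 * xlag[1L, 3L] - p$gamma2 * xlag[2L, 4L],
        p$theta1 - p$theta2 * xlag[2L, 5L] - p$theta3 * xlag[3L, 6L],
        p$beta1 * xlag[2L, 7L] - p$beta2 * xlag[3L, 8L] -
          p$beta3 * xlag[4L, 9L])
    },
    diffusion = function(t, xlag) {
      c(p$sigma1 * xlag[1L, 2L], p$sigma2 * xlag[2L, 4L],
        p$sigma3 * xlag[3L, 6L], p$sigma4 * xlag[4L, 9L])
    })
}

cascade_pre_history <- function(p) {
  c(p$baseline_b1, p$baseline_b2, p$baseline_b3, p$baseline_y)
}

#' Two-variable stimulus-biomarker-output model
#'
#' The reduced delayed system with a single biomarker B and output Y:
#' \deqn{dB = [\alpha_1 S(t-\tau_1) - \alpha_2 B(t-\tau_2)]dt +
#'       \sigma_1 B(t-\tau_2)dW_1}
#' \deqn{dY = [\beta_1 B(t-\tau_3) - \beta_2 Y(t-\tau_3)]dt +
#'       \sigma_2 Y(t-\tau_3)dW_2.}
#' The clearance term acts on the biomarker B; set
#' `literal_clearance = TRUE` in [build_two_var_system()] for the variant in
#' which it acts on the stimulus S instead.
#'
#' @param alpha1,alpha2 Amplification and clearance rates for the biomarker.
#' @param beta1,beta2 Output sensitivity and decay.
#' @param sigma1,sigma2 Noise intensities.
#' @param tau1,tau2,tau3 Lags (abstract units).
#' @param baseline_b,baseline_y Constant pre-history values.
#' @return An object of class `"two_var_params"`.
#' @export
two_var_params <- function(alpha1, alpha2, beta1, beta2,
                           sigma1 = 0, sigma2 = 0,
                           tau1 = 0, tau2 = 0, tau3 = 0,
                           baseline_b = 0, baseline_y = 0) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
            sigma1 = sigma1, sigma2 = sigma2,
            tau1 = tau1, tau2 = tau2, tau3 = tau3,
            baseline_b = baseline_b, baseline_y = baseline_y)
  if (any(unlist(p[1:6]) < 0))
    stop("rates and noise intensities must be >= 0", call. = FALSE)
  if (any(unlist(p[7:9]) < 0)) stop("delays must be >= 0", call. = FALSE)
  structure(p, class = "two_var_params")
}

#' Build the SDDE system for the two-variable model
#'
#' @param p A [two_var_params()].
#' @param stressor A [stressor_spec()].
#' @param literal_clearance If `TRUE`, the clearance term is
#'   \eqn{\alpha_2 S(t-\tau_2)} (clearance acting on the stimulus) instead of
#'   the default \eqn{\alpha_2 B(t-\tau_2)}.
#' @return An [sdde_system()] with state `(B, Y)`.
#' @export
build_two_var_system <- function(p, stressor, literal_clearance = FALSE) {
  stopifnot(inherits(p, "two_var_params"), inherits(stressor, "stressor_spec"))
  sdde_system(
    state_dim = 2L,
    delays = c(p$tau1, p$tau2, p$tau3),
    drift = function(t, x, xlag) {
      clear <- if (literal_clearance) stressor_value(stressor, t - p$tau2)
               else xlag[1L, 2L]
      c(p$alpha1 * stressor_value(stressor, t - p$tau1) - p$alpha2 * clear,
        p$beta1 * xlag[1L, 3L] - p$beta2 * xlag[2L, 3L])
    },
    diffusion = function(t, xlag) {
      c(p$sigma1 * xlag[1L, 2L], p$sigma2 * xlag[2L, 3L])
    })
}
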