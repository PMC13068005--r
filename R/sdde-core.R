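#' Uniform time grid for delay-equation integration
#'
#' Delays are represented on the grid as integer step counts, so every delay
#' used with a grid must be (close to) an integer multiple of `dt`.
#'
#' @param t0 Start time (abstract time units).
#' @param t_end Horizon (abstract time units); must exceed `t0`.
#' @param dt Step size (abstract time units); must be positive.
#'
#' @return An object of class `"time_grid"`: a list with elements `t0`,
#'   `t_end`, `dt`, `n_steps` and `times` (the `n_steps + 1` grid points).
#' @export
#' @examples
#' g <- time_grid(0, 1, 0.1)
#' g$n_steps
time_grid <- function(t0 = 0, t_end = 100, dt = 0.01) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  if (t_end <= t0)
    stop("'t_end' must exceed 't0'", call. = FALSE)
  n_steps <- as.integer(round((t_end - t0) / dt))
  structure(
    list(t0 = t0, t_end = t_end, dt = dt, n_steps = n_steps,
         times = t0 + dt * (0:n_steps)),
    class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("Time grid: [%g, %g], dt = %g (%d steps)\n",
              x$t0, x$t_end, x$dt, x$n_steps))
  invisible(x)
}

# Delay -> integer step offset, round half away from zero (no interpolation).
delay_steps <- function(tau, dt) {
  if (any(tau < 0)) stop("delays must be nonnegative", call. = FALSE)
  as.integer(floor(tau / dt + 0.5))
}

#' History buffer for delayed-state lookup
#'
#' Stores the state path on a [time_grid()] as it is filled in, together with
#' the constant pre-history vector that defines the state for all times
#' before `t0`.
#'
#' @param grid A [time_grid()].
#' @param pre_history Numeric state vector used for every time before `t0`;
#'   also the initial state at `t0`.
#'
#' @return An object of class `"history_buffer"` (an environment) with the
#'   state matrix, the fill pointer and the pre-history.
#' @seealso [lookup_delayed()]
#' @export
history_buffer <- function(grid, pre_history) {
  stopifnot(inherits(grid, "time_grid"))
  if (!all(is.finite(pre_history)))
    stop("'pre_history' must be finite", call. = FALSE)
  buf <- new.env(parent = emptyenv())
  buf$grid <- grid
  buf$pre_history <- as.numeric(pre_history)
  buf$states <- matrix(NA_real_, nrow = grid$n_steps + 1L,
                       ncol = length(pre_history))
  buf$states[1L, ] <- pre_history
  buf$filled <- 1L            # rows filled so far (row 1 = t0)
  class(buf) <- "history_buffer"
  buf
}

#' @describeIn history_buffer Store `state` at grid index `index` (0-based,
#'   index 0 is `t0`) and advance the fill pointer.
#' @param buffer A `history_buffer`.
#' @param index Integer grid index (0-based).
#' @param state Numeric state vector to store.
#' @export
buffer_set <- function(buffer, index, state) {
  buffer$states[index + 1L, ] <- state
  buffer$filled <- max(buffer$filled, index + 1L)
  invisible(buffer)
}

#' Retrieve a delayed state from a history buffer
#'
#' Delayed values are read by discrete indexing: the lag is converted to an
#' integer number of steps (`round(tau/dt)`, half away from zero) and the
#' stored state at that offset is returned.  Lookups that reach before the
#' grid origin return the constant pre-history vector exactly.
#'
#' @param buffer A [history_buffer()].
#' @param t Grid time at which the delayed value is needed; must lie at or
#'   before the buffer's fill point.
#' @param tau Nonnegative lag (abstract time units).
#'
#' @return The stored numeric state vector at time `t - tau`.
#' @export
#' @examples
#' g <- time_grid(0, 1, 0.1)
#' b <- history_buffer(g, pre_history = c(1, 2))
#' lookup_delayed(b, t = 0, tau = 0.5)   # before t0 -> pre-history
lookup_delayed <- function(buffer, t, tau) {
  stopifnot(inherits(buffer, "history_buffer"))
  if (length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("invalid lag: 'tau' must be a single nonnegative number",
         call. = FALSE)
  g <- buffer$grid
  i_t <- as.integer(round((t - g$t0) / g$dt))
  if (i_t + 1L > buffer$filled)
    stop(sprintf("lookup ahead of fill point: t = %g not yet integrated", t),
         call. = FALSE)
  idx <- i_t - delay_steps(tau, g$dt)
  if (idx < 0L) buffer$pre_history else buffer$states[idx + 1L, ]
}

#' Define a stochastic delay differential equation system
#'
#' The system is written componentwise as
#' \deqn{dX_i = f_i(t, X(t), X(t-\tau_1), \ldots)\,dt +
#'       g_i(t, X(t-\tau_1), \ldots)\,dW_i(t),}
#' with one independent Wiener increment stream per component and a diffusion
#' amplitude that depends on delayed states only.
#'
#' @param state_dim Number of state components.
#' @param delays Numeric vector of lag durations (abstract units).  Each lag
#'   must be zero or at least one grid step when integrated.
#' @param drift Function `(t, state, xlag)` returning the rate vector, where
#'   `xlag` is a `state_dim x length(delays)` matrix whose j-th column is the
#'   full state vector at `t - delays[j]`.
#' @param diffusion Function `(t, xlag)` returning the noise-amplitude vector
#'   (same `xlag` convention).
#'
#' @return An object of class `"sdde_system"`.
#' @seealso [integrate_sdde()]
#' @export
sdde_system <- function(state_dim, delays, drift, diffusion) {
  stopifnot(is.function(drift), is.function(diffusion),
            state_dim >= 1L, all(is.finite(delays)), all(delays >= 0))
  structure(list(state_dim = as.integer(state_dim),
                 delays = as.numeric(delays),
                 drift = drift, diffusion = diffusion),
            class = "sdde_system")
}

#' Integrate an SDDE system by delay-aware Euler--Maruyama
#'
#' One explicit Euler--Maruyama step per grid point:
#' \deqn{X(t+\Delta t) = X(t) + f\,\Delta t + g \odot \Delta W,}
#' with independent Gaussian increments \eqn{\Delta W_i \sim N(0, \Delta t)}
#' per component, delayed states looked up by discrete indexing against the
#' growing history buffer, and the constant pre-history supplying all values
#' before `t0`.  After each step the state is clipped at zero (the
#' multiplicative delayed noise does not guarantee positivity under Euler
#' discretisation); the clipping rule is recorded in the returned object.
#'
#' @param system An [sdde_system()].
#' @param pre_history Numeric vector of length `state_dim`: the constant
#'   history for `t < t0` and the initial state at `t0`.
#' @param grid A [time_grid()].  All nonzero system delays must be at least
#'   one step and (within tolerance) integer multiples of `dt`.
#' @param seed Integer seed for the Wiener increments.  The increments for
#'   component i form the i-th column of one matrix drawn from this seed, so
#'   each component has its own independent stream and a subject is
#'   reproducible in isolation.  The caller's RNG state is restored on exit.
#' @param subject_id Integer identifier stored in the trajectory.
#' @param clip_at_zero Clip state components at 0 after each step
#'   (default `TRUE`).
#'
#' @return An object of class `"sdde_trajectory"`: list with `grid`, `times`,
#'   `states` (matrix, one column per component), `seed`, `subject_id`,
#'   `clipped` (number of clipped entries).
#' @export
#' @examples
#' # pure exponential decay, no delay, no noise
#' sys <- sdde_system(1, delays = 0,
#'                    drift = function(t, x, xl) -0.5 * x,
#'                    diffusion = function(t, xl) 0)
#' tr <- integrate_sdde(sys, pre_history = 1, grid = time_grid(0, 2, 0.01),
#'                      seed = 1)
#' tail(tr$states[, 1], 1)   # ~ exp(-1)
integrate_sdde <- function(system, pre_history, grid, seed,
                           subject_id = 1L, clip_at_zero = TRUE) {
  stopifnot(inherits(system, "sdde_system"), inherits(grid, "time_grid"))
  if (length(pre_history) != system$state_dim || !all(is.finite(pre_history)))
    stop("'pre_history' must be a finite vector of length state_dim",
         call. = FALSE)
  dt <- grid$dt
  bad <- system$delays > 0 & system$delays < dt - 1e-12
  if (any(bad))
    stop("all nonzero delays must be at least one grid step", call. = FALSE)
  off_grid <- abs(system$delays / dt - round(system$delays / dt)) > 1e-8
  if (any(off_grid))
    stop("delays must be integer multiples of dt on this grid",
         call. = FALSE)
  lag_idx <- delay_steps(system$delays, dt)

  d <- system$state_dim
  n <- grid$n_steps
  states <- matrix(NA_real_, nrow = n + 1L, ncol = d)
  states[1L, ] <- pre_history
  dW <- with_seed(seed, matrix(stats::rnorm(n * d), nrow = n, ncol = d)) *
    sqrt(dt)

  xlag <- matrix(0, nrow = d, ncol = length(lag_idx))
  n_clipped <- 0L
  x <- as.numeric(pre_history)
  for (step in seq_len(n)) {
    t <- grid$t0 + (step - 1L) * dt
    for (j in seq_along(lag_idx)) {
      idx <- step - 1L - lag_idx[j]
      xlag[, j] <- if (idx < 0L) pre_history else states[idx + 1L, ]
    }
    f <- system$drift(t, x, xlag)
    g <- system$diffusion(t, xlag)
    if (!all(is.finite(f)) || !all(is.finite(g)))
      stop(sprintf("numerical divergence: non-finite drift/diffusion at step %d (t = %g)",
                   step, t), call. = FALSE)
    x <- x + f * dt + g * dW[step, ]
    if (clip_at_zero) {
      neg <- x < 0
      if (any(neg)) {
        n_clipped <- n_clipped + sum(neg)
        x[neg] <- 0
      }
    }
    states[step + 1L, ] <- x
  }

  structure(list(grid = grid, times = grid$times, states = states,
                 seed = as.integer(seed), subject_id = as.integer(subject_id),
                 clipped = n_clipped,
                 clipping = if (clip_at_zero) "componentwise at 0 after each step" else "none"),
            class = "sdde_trajectory")
}

#' @export
print.sdde_trajectory <- function(x, ...) {
  cat(sprintf("SDDE trajectory: subject %d, %d components, t in [%g, %g], seed %d\n",
              x$subject_id, ncol(x$states), x$grid$t0, x$grid$t_end, x$seed))
  invisible(x)
}

#' @export
as.data.frame.sdde_trajectory <- function(x, ...) {
  d <- as.data.frame(x$states)
  names(d) <- colnames(x$states) %||%
    paste0("X", seq_len(ncol(x$states)))
  cbind(subject_id = x$subject_id, t = x$times, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

# Deterministic per-subject seed spawning from a master seed.
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(2147483646L, n, replace = FALSE))
}
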