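#' Input stressor signal
#'
#' The common external input every virtual subject receives: by default a
#' rectangular pulse of given amplitude, onset and duration.  S(t) equals
#' `amplitude` for `onset <= t < onset + duration` and 0 elsewhere.
#'
#' @param amplitude Nonnegative pulse level (abstract units).
#' @param onset Pulse start time.
#' @param duration Nonnegative pulse length.
#' @param shape Pulse shape identifier; only `"rectangular"` is implemented.
#'
#' @return An object of class `"stressor_spec"`.
#' @export
#' @examples
#' s <- stressor_spec(amplitude = 1, onset = 5, duration = 10)
#' stressor_value(s, c(0, 7, 20))
stressor_spec <- function(amplitude = 1, onset = 5, duration = 10,
                          shape = "rectangular") {
  if (amplitude < 0) stop("'amplitude' must be >= 0", call. = FALSE)
  if (duration < 0) stop("'duration' must be >= 0", call. = FALSE)
  shape <- match.arg(shape, "rectangular")
  structure(list(amplitude = amplitude, onset = onset,
                 duration = duration, shape = shape),
            class = "stressor_spec")
}

#' Evaluate the stressor signal
#'
#' @param spec A [stressor_spec()].
#' @param t Numeric vector of times.
#' @return Numeric vector of stressor levels at `t`.
#' @rdname stressor_spec
#' @export
stressor_value <- function(spec, t) {
  stopifnot(inherits(spec, "stressor_spec"))
  ifelse(t >= spec$onset & t < spec$onset + spec$duration,
         spec$amplitude, 0)
}

#' @export
print.stressor_spec <- function(x, ...) {
  cat(sprintf("Stressor: %s pulse, amplitude %g on [%g, %g)\n",
              x$shape, x$amplitude, x$onset, x$onset + x$duration))
  invisible(x)
}
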