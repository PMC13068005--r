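# Shared, lazily computed cohorts so expensive simulations run once per
# test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Default 100-subject labelled cohort (metrics only) for a given master seed.
base_cohort <- function(seed = 1) {
  cached(paste0("cohort", seed), {
    m <- cascade_model("paper2026")
    simulate(m, nsim = 100, seed = seed, keep_paths = FALSE)
  })
}

# A coarse grid on which the generic R integrator is fast; all preset delays
# are integer multiples of dt = 0.1.
coarse_model <- function(...) {
  cascade_model("paper2026", ..., grid = time_grid(0, 30, 0.1))
}

# Single-subject cascade integration (internal fast/generic dispatcher).
integrate_cascade_test <- function(m, seed = 1, engine = "compiled") {
  delaytwin:::integrate_cascade(m, seed = seed, engine = engine)
}

# Minimal hand-built trajectory for metric extraction tests.
fake_trajectory <- function(y, times = seq_along(y) - 1, subject_id = 1L) {
  structure(list(grid = NULL, times = times,
                 states = matrix(y, ncol = 1, dimnames = list(NULL, "Y")),
                 seed = 0L, subject_id = subject_id),
            class = "sdde_trajectory")
}
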