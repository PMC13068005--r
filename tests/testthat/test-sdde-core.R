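test_that("delayed lookup uses discrete indexing and the constant pre-history", {
  g <- time_grid(0, 1, 0.1)
  b <- history_buffer(g, pre_history = c(5, 7))
  for (i in 1:10) buffer_set(b, i, c(i, 10 + i))

  # tau = 0 is the identity
  expect_identical(lookup_delayed(b, t = 0.4, tau = 0), c(4, 14))
  # offset arithmetic: round(0.3 / 0.1) = 3 steps back
  expect_identical(lookup_delayed(b, t = 1.0, tau = 0.3), c(7, 17))
  # lookups reaching before t0 return the pre-history exactly
  expect_identical(lookup_delayed(b, t = 0.5, tau = 2.0), c(5, 7))

  expect_error(lookup_delayed(b, t = 0.5, tau = -1), "invalid lag")
  g2 <- time_grid(0, 1, 0.1)
  b2 <- history_buffer(g2, pre_history = 1)
  expect_error(lookup_delayed(b2, t = 0.5, tau = 0), "ahead of fill")
})

test_that("pre-history is returned for every time before the minimum delay", {
  g <- time_grid(0, 2, 0.05)
  pre <- c(2.5, -1)  # buffer itself permits any finite pre-history
  b <- history_buffer(g, pre)
  for (i in 1:40) buffer_set(b, i, rnorm(2))
  for (tau in c(0.5, 1, 1.7)) {
    for (t in seq(0, tau - 0.05, by = 0.05)) {
      expect_identical(lookup_delayed(b, t, tau), pre)
    }
  }
})

test_that("Euler-Maruyama reproduces closed forms for linear test systems", {
  # zero drift, zero diffusion: constant path
  sys0 <- sdde_system(2, delays = 0,
                      drift = function(t, x, xl) c(0, 0),
                      diffusion = function(t, xl) c(0, 0))
  tr0 <- integrate_sdde(sys0, c(3, 4), time_grid(0, 1, 0.1), seed = 1)
  expect_true(all(tr0$states[, 1] == 3) && all(tr0$states[, 2] == 4))

  # dX = -0.5 X dt: X(2) = exp(-1) within 1%
  sys1 <- sdde_system(1, delays = 0,
                      drift = function(t, x, xl) -0.5 * x,
                      diffusion = function(t, xl) 0)
  tr1 <- integrate_sdde(sys1, 1, time_grid(0, 2, 0.01), seed = 1)
  xT <- tr1$states[nrow(tr1$states), 1]
  expect_lt(abs(xT - exp(-1)) / exp(-1), 0.01)

  # dX = -X(t - tau) dt with tau > T: drift is the constant -1, Euler exact
  sys2 <- sdde_system(1, delays = 2,
                      drift = function(t, x, xl) -xl[1, 1],
                      diffusion = function(t, xl) 0)
  tr2 <- integrate_sdde(sys2, 1, time_grid(0, 1, 0.01), seed = 1,
                        clip_at_zero = FALSE)
  expect_equal(tr2$states[nrow(tr2$states), 1], 0)
})

test_that("global error of the deterministic scheme halves with the step", {
  err <- vapply(c(0.02, 0.01), function(dt) {
    sys <- sdde_system(1, delays = 0,
                       drift = function(t, x, xl) -0.5 * x,
                       diffusion = function(t, xl) 0)
    tr <- integrate_sdde(sys, 1, time_grid(0, 2, dt), seed = 1)
    max(abs(tr$states[, 1] - exp(-0.5 * tr$times)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.7)
  expect_lt(err[1] / err[2], 2.3)
})

test_that("zero diffusion makes the integrator seed-independent", {
  sys <- sdde_system(1, delays = 0.5,
                     drift = function(t, x, xl) 1 - xl[1, 1],
                     diffusion = function(t, xl) 0)
  g <- time_grid(0, 5, 0.01)
  tr_a <- integrate_sdde(sys, 0.2, g, seed = 1)
  tr_b <- integrate_sdde(sys, 0.2, g, seed = 999)
  expect_identical(tr_a$states, tr_b$states)
})

test_that("a fixed seed gives bitwise-identical stochastic trajectories", {
  sys <- sdde_system(2, delays = c(0, 0.5),
                     drift = function(t, x, xl) c(1 - x[1], x[1] - xl[2, 2]),
                     diffusion = function(t, xl) 0.3 * xl[, 2])
  g <- time_grid(0, 3, 0.01)
  tr_a <- integrate_sdde(sys, c(1, 1), g, seed = 42)
  tr_b <- integrate_sdde(sys, c(1, 1), g, seed = 42)
  expect_identical(tr_a$states, tr_b$states)
  # and the caller's RNG stream is untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(integrate_sdde(sys, c(1, 1), g, seed = 42))
  expect_identical(rnorm(1), before)
})

test_that("non-finite dynamics raise an error naming the failing step", {
  sys <- sdde_system(1, delays = 0,
                     drift = function(t, x, xl) if (t > 0.5) NaN else 0,
                     diffusion = function(t, xl) 0)
  expect_error(integrate_sdde(sys, 1, time_grid(0, 1, 0.1), seed = 1),
               "divergence.*step", perl = TRUE)
  expect_error(time_grid(0, 1, dt = 0), "positive")
})

test_that("states are clipped at zero after each step", {
  sys <- sdde_system(1, delays = 0,
                     drift = function(t, x, xl) -10,
                     diffusion = function(t, xl) 0)
  tr <- integrate_sdde(sys, 0.05, time_grid(0, 2, 0.01), seed = 1)
  expect_true(all(tr$states >= 0))
  expect_gt(tr$clipped, 0)
  expect_match(tr$clipping, "at 0")
})

test_that("delays smaller than one step or off the grid are rejected", {
  sys <- sdde_system(1, delays = 0.004,
                     drift = function(t, x, xl) 0,
                     diffusion = function(t, xl) 0)
  expect_error(integrate_sdde(sys, 1, time_grid(0, 1, 0.01), seed = 1),
               "one grid step")
  sys2 <- sdde_system(1, delays = 0.015,
                      drift = function(t, x, xl) 0,
                      diffusion = function(t, xl) 0)
  expect_error(integrate_sdde(sys2, 1, time_grid(0, 1, 0.01), seed = 1),
               "integer multiples")
})
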