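test_that("the rectangular stressor pulse has the stated support and mass", {
  s <- stressor_spec(amplitude = 1, onset = 5, duration = 10)
  expect_identical(stressor_value(s, 4.999), 0)
  expect_identical(stressor_value(s, 7), 1)
  expect_identical(stressor_value(s, 15), 0)   # right-open interval
  # mass over the horizon equals amplitude x duration
  g <- time_grid(0, 100, 0.01)
  mass <- sum(stressor_value(s, g$times[-1])) * g$dt
  expect_equal(mass, 10, tolerance = 1e-6)
  expect_error(stressor_spec(amplitude = -1), "amplitude")
})

test_that("two-variable model reaches its closed-form equilibria without noise", {
  p <- two_var_params(alpha1 = 0.4, alpha2 = 0.2, beta1 = 0.3, beta2 = 0.15,
                      tau1 = 0, tau2 = 0, tau3 = 0)
  s <- stressor_spec(amplitude = 2, onset = 0, duration = 200)
  tr <- integrate_sdde(build_two_var_system(p, s), c(0, 0),
                       time_grid(0, 150, 0.01), seed = 1)
  final <- tr$states[nrow(tr$states), ]
  b_star <- 0.4 * 2 / 0.2                 # alpha1 s / alpha2
  y_star <- 0.3 * b_star / 0.15           # beta1 B* / beta2
  expect_equal(final[1], b_star, tolerance = 1e-3)
  expect_equal(final[2], y_star, tolerance = 1e-3)
})

test_that("two-variable model with no input and zero baselines stays at zero", {
  p <- two_var_params(alpha1 = 0.4, alpha2 = 0.2, beta1 = 0.3, beta2 = 0.15)
  s <- stressor_spec(amplitude = 0, onset = 0, duration = 0)
  tr <- integrate_sdde(build_two_var_system(p, s), c(0, 0),
                       time_grid(0, 10, 0.01), seed = 1)
  expect_true(all(tr$states == 0))
})

test_that("the literal printed clearance variant acts on S, not B", {
  p <- two_var_params(alpha1 = 0.4, alpha2 = 0.2, beta1 = 0, beta2 = 0,
                      baseline_b = 1)
  s <- stressor_spec(amplitude = 0, onset = 0, duration = 0)  # S identically 0
  g <- time_grid(0, 5, 0.01)
  tr_default <- integrate_sdde(build_two_var_system(p, s), c(1, 0), g, seed = 1)
  tr_literal <- integrate_sdde(
    build_two_var_system(p, s, literal_clearance = TRUE), c(1, 0), g, seed = 1)
  expect_lt(tr_default$states[nrow(tr_default$states), 1], 1)  # B cleared
  expect_equal(tr_literal$states[, 1], rep(1, nrow(tr_literal$states)))
})

test_that("cascade holds the albumin equilibrium theta1/theta3 without noise", {
  m <- coarse_model(sigma1 = 0, sigma2 = 0, sigma3 = 0, sigma4 = 0,
                    theta2 = 0, baseline_b1 = 0, baseline_b2 = 0,
                    baseline_b3 = 1, baseline_y = 0,
                    stressor = stressor_spec(0, 5, 6))
  tr <- integrate_cascade_test(m)
  expect_equal(max(abs(tr$states[, "B3"] - 1)), 0, tolerance = 1e-6)
})

test_that("the deterministic cascade respects the peak ordering B1 <= B2 <= Y", {
  m <- cascade_model("paper2026", sigma1 = 0, sigma2 = 0, sigma3 = 0,
                     sigma4 = 0)
  tr <- integrate_cascade_test(m)
  peak_at <- function(col) tr$times[which.max(tr$states[, col])]
  expect_lte(peak_at("B1"), peak_at("B2"))
  expect_lte(peak_at("B2"), peak_at("Y"))
})

test_that("zero gains and baselines give identically zero paths", {
  m <- coarse_model(alpha1 = 0, gamma1 = 0, theta1 = 0, beta1 = 0,
                    alpha2 = 0, gamma2 = 0, theta2 = 0, theta3 = 0,
                    beta2 = 0, beta3 = 0,
                    sigma1 = 0, sigma2 = 0, sigma3 = 0, sigma4 = 0,
                    baseline_b1 = 0, baseline_b2 = 0, baseline_b3 = 0,
                    baseline_y = 0)
  tr <- integrate_cascade_test(m)
  expect_true(all(tr$states == 0))
})

test_that("every cascade symbol maps to exactly one parameter field", {
  symbols <- c("alpha1", "alpha2",                      # neutrophil arm
               "gamma1", "gamma2",                      # CRP arm
               "theta1", "theta2", "theta3",            # albumin arm
               "beta1", "beta2", "beta3",               # output arm
               paste0("sigma", 1:4), paste0("tau", 1:9))
  expect_setequal(names(coef(cascade_model("paper2026"))), symbols)
})

test_that("the shipped preset is valid, stable without input, and heterogeneous", {
  m <- cascade_model("paper2026")
  expect_s3_class(m, "cascade_model")
  expect_true(all(coef(m) >= 0))
  # fast/intermediate/slow lag ordering
  expect_lte(max(m$tau1, m$tau2), min(m$tau3, m$tau4))
  expect_lte(max(m$tau3, m$tau4), min(m$tau5, m$tau6))

  # without input and noise all components settle (no divergence)
  m0 <- cascade_model("paper2026", sigma1 = 0, sigma2 = 0, sigma3 = 0,
                      sigma4 = 0, stressor = stressor_spec(0, 5, 6))
  tr <- integrate_cascade_test(m0)
  expect_true(all(is.finite(tr$states)))
  final <- tr$states[nrow(tr$states), ]
  expect_lt(final[["B1"]], 1e-3)
  expect_equal(final[["B3"]], m$theta1 / m$theta3, tolerance = 0.01)

  # identical preset, different seeds: distinct peak outputs
  sim <- simulate_cohort(m, n_subjects = 2, master_seed = 1,
                         keep_paths = FALSE)
  expect_false(sim$metrics$max_y[1] == sim$metrics$max_y[2])
})

test_that("trajectories under the default preset stay finite over the horizon", {
  co <- base_cohort(1)
  expect_true(all(is.finite(co$metrics$max_y)))
  tr <- integrate_cascade_test(cascade_model("paper2026"), seed = 123)
  expect_true(all(is.finite(tr$states)))
})

test_that("parameter validation rejects bad values and unknown presets", {
  expect_error(cascade_model("paper2026", alpha1 = -1), ">= 0")
  expect_error(cascade_model("paper2026", tau3 = 0.5), "ordering")
  expect_error(cascade_model("paper2026", tau5 = 0.123), "multiples")
  expect_error(cascade_model("paper2026", foo = 1), "unknown parameter")
  expect_error(cascade_model("nope"), "available.*paper2026")
})

test_that("compiled and generic cascade engines agree bitwise", {
  m <- coarse_model()
  tr_fast <- integrate_cascade_test(m, seed = 11, engine = "compiled")
  tr_gen <- integrate_cascade_test(m, seed = 11, engine = "generic")
  expect_identical(tr_fast$states, tr_gen$states)
})
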