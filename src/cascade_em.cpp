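#include <Rcpp.h>
using namespace Rcpp;

// Delay-aware Euler-Maruyama stepper specialised to the four-variable
// inflammatory cascade.  Must stay step-for-step identical to the generic R
// integrator applied to build_cascade_system(); the equivalence is enforced
// by a test.  Wiener increments are generated in R (so the RNG and the
// seed-spawning scheme live in one place) and passed in as an
// n_steps x 4 matrix already scaled by sqrt(dt).
// [[Rcpp::export(name = ".cascade_em_cpp")]]
NumericMatrix cascade_em_cpp(NumericVector rates, IntegerVector lag_steps,
                             NumericVector sigma, NumericVector pre_history,
                             NumericVector stressor, double t0, double dt,
                             int n_steps, NumericMatrix dW) {
  const double alpha1 = rates[0], alpha2 = rates[1];
  const double gamma1 = rates[2], gamma2 = rates[3];
  const double theta1 = rates[4], theta2 = rates[5], theta3 = rates[6];
  const double beta1 = rates[7], beta2 = rates[8], beta3 = rates[9];
  const double amp = stressor[0], onset = stressor[1], dur = stressor[2];
  const double tau1 = stressor[3];

  NumericMatrix states(n_steps + 1, 4);
  for (int c = 0; c < 4; ++c) states(0, c) = pre_history[c];

  // lagged value of component c at step offset `steps`
  auto lag = [&](int step, int c, int steps) {
    int idx = step - steps;
    return idx < 0 ? pre_history[c] : states(idx, c);
  };

  for (int n = 0; n < n_steps; ++n) {
    double t = t0 + n * dt;
    double ts = t - tau1;  // stressor uses the raw lag, as the R reference does
    double S = (ts >= onset && ts < onset + dur) ? amp : 0.0;

    double b1_t2 = lag(n, 0, lag_steps[1]);
    double b1_t3 = lag(n, 0, lag_steps[2]);
    double b2_t4 = lag(n, 1, lag_steps[3]);
    double b2_t5 = lag(n, 1, lag_steps[4]);
    double b2_t7 = lag(n, 1, lag_steps[6]);
    double b3_t6 = lag(n, 2, lag_steps[5]);
    double b3_t8 = lag(n, 2, lag_steps[7]);
    double y_t9  = lag(n, 3, lag_steps[8]);

    double f0 = alpha1 * S - alpha2 * b1_t2;
    double f1 = gamma1 * b1_t3 - gamma2 * b2_t4;
    double f2 = theta1 - theta2 * b2_t5 - theta3 * b3_t6;
    double f3 = beta1 * b2_t7 - beta2 * b3_t8 - beta3 * y_t9;

    double g0 = sigma[0] * b1_t2;
    double g1 = sigma[1] * b2_t4;
    double g2 = sigma[2] * b3_t6;
    double g3 = sigma[3] * y_t9;

    double x0 = states(n, 0) + f0 * dt + g0 * dW(n, 0);
    double x1 = states(n, 1) + f1 * dt + g1 * dW(n, 1);
    double x2 = states(n, 2) + f2 * dt + g2 * dW(n, 2);
    double x3 = states(n, 3) + f3 * dt + g3 * dW(n, 3);

    if (!(R_finite(x0) && R_finite(x1) && R_finite(x2) && R_finite(x3)))
      stop("numerical divergence: non-finite state at step %d (t = %g)",
           n + 1, t);

    states(n + 1, 0) = x0 < 0 ? 0 : x0;
    states(n + 1, 1) = x1 < 0 ? 0 : x1;
    states(n + 1, 2) = x2 < 0 ? 0 : x2;
    states(n + 1, 3) = x3 < 0 ? 0 : x3;
  }
  return states;
}
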