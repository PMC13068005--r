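# "paper2026" reference preset for the delayed inflammatory cascade.
# Calibrated once with scripts/calibrate.R and then frozen; time is in
# abstract units.  Edit only by re-running the calibration.
#
# Design of the calibrated regime:
#   - the stressor drives a short neutrophil burst (B1) whose multiplicative
#     noise (sigma1) is the dominant source of between-subject variability;
#     the burst dies quickly (alpha2), freezing each subject's "burst scale"
#     early in the run;
#   - CRP (B2) integrates the burst and clears slowly (gamma2), so its
#     post-burst tail is the common dome shape scaled per subject;
#   - albumin (B3) is suppressed in proportion to CRP and relaxes back,
#     setting the moving floor that terminates the latent-output rise;
#   - the latent output Y rises while the CRP drive exceeds the albumin
#     floor; subjects with stronger bursts peak later and higher, which
#     couples time-to-peak tightly to peak height.
alpha1: 2.2     # stress -> neutrophil gain
alpha2: 1.0     # neutrophil clearance (fast burst)
gamma1: 0.15    # neutrophil -> CRP gain
gamma2: 0.04    # CRP clearance (slow tail)
theta1: 0.1     # albumin baseline production
theta2: 0.04    # CRP -> albumin suppression
theta3: 0.1     # albumin relaxation
beta1: 0.15     # CRP -> Y gain
beta2: 0.42     # albumin -> Y suppression
beta3: 0.002    # Y decay
sigma1: 0.2
sigma2: 0.0005
sigma3: 0.0005
sigma4: 0.0005
tau1: 1.0       # stress -> neutrophil activation (fast)
tau2: 1.0       # neutrophil self-clearance lag (fast)
tau3: 3.0       # neutrophil -> CRP induction (intermediate)
tau4: 3.0       # CRP clearance lag (intermediate)
tau5: 4.0       # CRP -> albumin suppression (slow)
tau6: 4.0       # albumin relaxation lag (slow)
tau7: 2.0       # CRP -> Y propagation
tau8: 2.0       # albumin -> Y propagation
tau9: 2.0       # Y self-decay lag
baseline_b1: 0.05
baseline_b2: 0.05
baseline_b3: 1.0
baseline_y: 0.05
stressor:
  amplitude: 1.0
  onset: 5.0
  duration: 6.0
grid:
  t0: 0.0
  t_end: 100.0
  dt: 0.01
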