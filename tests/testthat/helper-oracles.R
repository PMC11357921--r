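# Frozen 50-digit reference values for E_alpha(z), computed once with an
# arbitrary-precision oracle (adaptive-precision Taylor series where feasible,
# cross-validated against the completely monotone spectral representation of
# E_alpha(-x) for 0 < alpha < 1; the two agreed to ~1e-52 wherever both
# converge).
ml_reference_pins <- list(
  list(alpha = 0.1, z = -5, value = 0.15804238235845183),
  list(alpha = 0.1, z = -50, value = 0.018378057012219195),
  list(alpha = 0.2, z = -20, value = 0.04132308263406081),
  list(alpha = 0.25, z = -12.34, value = 0.062571472729790798),
  list(alpha = 0.3, z = -50, value = 0.015228201501814695),
  list(alpha = 0.4, z = -30, value = 0.022135442378833812),
  list(alpha = 0.5, z = -50, value = 0.011281536265323773),
  list(alpha = 0.55, z = -12, value = 0.04283506729085032),
  list(alpha = 0.6, z = -35, value = 0.013016611692177908),
  list(alpha = 0.65, z = -18, value = 0.022520008484244487),
  list(alpha = 0.7, z = -20, value = 0.017395698291603977),
  list(alpha = 0.75, z = -40, value = 0.0070756747558264278),
  list(alpha = 0.783, z = -1.7, value = 0.23357543453953248),
  list(alpha = 0.783, z = -2.6422602616391478, value = 0.13800604230418098),
  list(alpha = 0.8, z = -25, value = 0.0091709970964705318),
  list(alpha = 0.85, z = -45, value = 0.0036930827578439454),
  list(alpha = 0.9, z = -50, value = 0.0021753530768569765),
  list(alpha = 0.95, z = -50, value = 0.001067234039220842),
  list(alpha = 0.999, z = -3.21, value = 0.040728098638587869),
  list(alpha = 1.2, z = -15, value = -0.013455707401708765),
  list(alpha = 1.5, z = -7.5, value = -0.22677465777284576),
  list(alpha = 1.7, z = -30, value = 0.098161164176360319),
  list(alpha = 2.0, z = -49, value = 0.75390225434330464)
)

# 50-digit oracle grid over alpha in {0.1..1.0}, z in {0, -0.5, ..., -5}
ml_reference_grid <- function() {
  utils::read.csv(test_path("ml-oracle-grid.csv"))
}

# E_{1/2}(-1) truncated at 200 terms, summed at 60-digit precision
ML_SERIES_HALF_M1 <- 0.427583576155807

# CTRW signal at the high-grade reference medians, S0 = 1000, b = 3000
# (= 1000 * E_0.783(-(3000 * 1.021e-3)^0.868), 50-digit oracle)
CTRW_HIGH_GRADE_B3000 <- 138.00604230418098

# ICC(2,1) worked example pinned from an independent implementation
# (pingouin ICC(A,1); CI reported there at 2 decimals)
ICC_WORKED <- list(
  r1 = c(1.10, 0.95, 1.42, 1.20, 0.88, 1.31),
  r2 = c(1.05, 1.02, 1.38, 1.25, 0.91, 1.28),
  icc = 0.970706136294,
  ci_2dp = c(0.81, 1.00)
)

# noiseless CTRW signal over a scheme, used throughout the fitting tests
ctrw_truth_signal <- function(D, alpha, beta, S0 = 1000,
                              scheme = default_bvalue_scheme()) {
  ctrw_signal(ctrw_params(D, alpha, beta), S0, scheme$b)
}

# reference medians/IQRs used repeatedly in tests
ref_cell <- function(group, parameter) {
  d <- reference_param_distributions()
  d[d$group == group & d$parameter == parameter, ]
}
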