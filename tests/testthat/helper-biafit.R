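# noise-free first-order transient series from known parameters
exact_series <- function(b, c_amp, a, n = 5, delta_s = 1) {
  t <- delta_s * seq_len(n)
  impedance_series(b + c_amp * exp(-a * t), delta_s = delta_s)
}

# calibration config whose settle threshold never short-circuits the
# extrapolation path, to exercise the log-linear estimator in isolation
extrapolation_config <- function() {
  calibration_config(settle_threshold = 1e-9)
}

# small network spec so unit tests of the training contract stay fast
tiny_mlp <- function(input_dim, seed = 1L, ...) {
  mlp_spec(input_dim, hidden_nodes = c(16, 16), seed = seed, ...)
}

# zero-noise cohort whose PBF rule is affine in the model features: equal
# group means remove the between-group offset that no feature encodes
linear_cohort_config <- function() {
  g <- biafit:::group_stats_table()
  g$pbf_mean <- 20
  default_cohort_config(meas_noise_sd = 0, pbf_noise_sd = 0,
                        r50_noise_sd = 0, nonlinearity_strength = 0,
                        groups = g)
}
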