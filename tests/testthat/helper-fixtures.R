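# Shared fixtures: all synthetic, built in code.

ref <- hnscc_reference_params("discovery")
ref_mean <- stats::setNames(ref$mean, ref$param)
ref_sd <- stats::setNames(ref$sd, ref$param)

# Noiseless model-true curve on the 12-b scheme.
noiseless_curve <- function(model, params, s0 = 1000,
                            scheme = default_b_scheme()) {
  simulate_signal(model, params, scheme = scheme, s0 = s0, noise = "none")
}

max_rel_err <- function(est, truth) {
  max(abs(unlist(est) - unlist(truth)) / abs(unlist(truth)))
}

# Small two-group survival fixture builder.
surv_df <- function(time, event, group) {
  data.frame(time = time, event = event, group = group)
}
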