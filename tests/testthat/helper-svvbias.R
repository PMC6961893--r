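# shared fixtures built in code

# a deterministic, noise-free subject on the published-condition plateaus
noiseless_profile <- function(tau = 11.4) {
  subject_profile(plateau_preset("table1", tau = tau), tau = tau,
                  responsiveness = 1, tracking_sd = 0, intercept = 0)
}

# a small noise-free cohort: reduction should recover the generator exactly
noiseless_cohort <- function(n_subjects = 2) {
  generate_cohort(n_subjects = n_subjects, tracking_sd = 0,
                  responsiveness_sdlog = 0, intercept_sd = 0)
}

# final bias of a long constant-rotation simulation (the asymptote)
asymptotic_bias <- function(velocity, noise = 0, params = model_params(),
                            motion_s = 150) {
  p <- apply_noise_attenuation(params, noise)
  sim <- svv_simulate(roll_protocol(velocity, motion_s = motion_s,
                                    static_pre_s = 2, static_post_s = 0), p)
  sim$bias[length(sim$bias)]
}
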