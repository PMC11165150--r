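# Shared fixtures, built in code.

# A single-trial-gamma subject with known generating parameters.
make_gamma2_subject <- function(seed, upsilon = 4, lambda = 0.93, phi = 0.058,
                                subject = "s1") {
  set.seed(seed)
  gs <- generate_gamma_series(300)
  z <- as.numeric(suppressMessages(zeta_trial(gs)))
  p <- model_params(upsilon, lambda, phi, variant = "gamma2")
  obs <- simulate_session(p, zeta = z, subject = subject)
  list(obs = obs, zeta = z, params = p)
}

# CMF parameter set at the printed weak moderator values.
cmf_printed <- function(s = 0.45) {
  model_params(3.8, 0.98, 0.057, rho = -0.05, kappa = -0.01, s = s,
               variant = "cmf")
}

# CMF parameter set at the 10-minute refitted values.
cmf_refit <- function(s = 0.45) {
  model_params(3.82, 0.88, 0.057, rho = -0.20, kappa = -0.15, s = s,
               variant = "cmf")
}
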