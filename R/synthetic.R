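#' Binned gamma-power trend specification
#'
#' Mean log-power profile across the five 2-minute bins plus multiplicative
#' lognormal trial noise. The default profile is non-monotonic with a dip in
#' the final bin — bins 2 and 4 above bin 5 — the qualitative shape of binned
#' frontal high-gamma power during a brief vigil. An optional end-spurt
#' uplift raises the final bin instead.
#'
#' @param log_profile 5 finite per-bin mean log powers (natural log).
#' @param sigma lognormal trial-noise standard deviation (log scale, >= 0).
#' @param end_spurt additive uplift to the final bin's mean log power.
#' @export
gamma_trend_spec <- function(log_profile = log(c(10, 11.5, 10.5, 11.5, 8.5)),
                             sigma = 0.5, end_spurt = 0) {
  if (length(log_profile) != 5 || any(!is.finite(log_profile))) {
    stop("gamma_trend_spec: `log_profile` must be 5 finite values", call. = FALSE)
  }
  if (sigma < 0) stop("gamma_trend_spec: `sigma` must be >= 0", call. = FALSE)
  lp <- log_profile
  lp[5] <- lp[5] + end_spurt
  structure(list(log_profile = lp, sigma = sigma), class = "gamma_trend_spec")
}

#' Generate a synthetic per-trial gamma power series
#'
#' Trials are assigned to the five bins by trial-time proportion; each
#' trial's power is `exp(profile[bin])` times lognormal noise, so all powers
#' are strictly positive. When a series is generated longer than one session
#' (as overrun protection for an emergent trial count), `n_session` fixes the
#' number of trials that spans the five bins, so the profile unfolds on the
#' session's time scale and surplus trials stay in the final bin.
#'
#' @param n_trials number of trials (>= 1).
#' @param spec a [gamma_trend_spec()].
#' @param subject subject id.
#' @param seed optional seed.
#' @param n_session trials spanning the five bins (default `n_trials`).
#' @return a [gamma_series()] with bin labels.
#' @export
generate_gamma_series <- function(n_trials, spec = gamma_trend_spec(),
                                  subject = "s1", seed = NULL,
                                  n_session = n_trials) {
  stopifnot(inherits(spec, "gamma_trend_spec"))
  if (n_trials < 1) stop("generate_gamma_series: need n_trials >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bin <- pmin(floor((seq_len(n_trials) - 1) / n_session * 5) + 1, 5)
  g <- exp(spec$log_profile[bin] + rnorm(n_trials, 0, spec$sigma))
  gamma_series(g, subject = subject, bin = bin)
}

#' Default per-subject parameter samplers
#'
#' Truncated-normal draws centred on the published cross-subject parameter
#' summaries (mean and between-subject SD reconstructed from the reported
#' standard errors at n = 34), truncated to the fitting bounds.
#'
#' @param variant model variant.
#' @param point optional named list overriding means with fixed values (a
#'   point-mass sampler).
#' @param s,mismatch configuration constants passed through to
#'   [model_params()].
#' @return function(subject_index) returning a [model_params()].
#' @export
param_sampler_default <- function(variant = c("cmf", "gamma1", "gamma2"),
                                  point = NULL, s = 0.45, mismatch = 6.0) {
  variant <- match.arg(variant)
  sumstats <- switch(variant,
    cmf = list(mean = c(upsilon = 3.82, lambda = 0.88, phi = 0.057,
                        rho = -0.20, kappa = -0.15),
               sd = c(upsilon = 0.82, lambda = 0.06, phi = 0.012,
                      rho = 0.06, kappa = 0.06)),
    gamma1 = list(mean = c(upsilon = 6.65, lambda = 0.94, phi = 0.058),
                  sd = c(upsilon = 0.9, lambda = 0.04, phi = 0.012)),
    gamma2 = list(mean = c(upsilon = 4.15, lambda = 0.93, phi = 0.058),
                  sd = c(upsilon = 0.9, lambda = 0.04, phi = 0.012)))
  b <- param_bounds(variant)
  lower <- setNames(b$lower, b$param)
  upper <- setNames(b$upper, b$param)
  function(i) {
    draw <- sumstats$mean
    for (p in names(draw)) {
      if (!is.null(point) && p %in% names(point)) {
        draw[p] <- point[[p]]
        next
      }
      if (sumstats$sd[p] > 0) {
        repeat {
          v <- rnorm(1, sumstats$mean[p], sumstats$sd[p])
          if (v > lower[p] && v <= upper[p]) break
        }
        draw[p] <- v
      }
    }
    if (variant == "cmf") {
      model_params(draw["upsilon"], draw["lambda"], draw["phi"],
                   rho = draw["rho"], kappa = draw["kappa"],
                   s = s, mismatch = mismatch, variant = variant)
    } else {
      model_params(draw["upsilon"], draw["lambda"], draw["phi"],
                   s = s, mismatch = mismatch, variant = variant)
    }
  }
}

#' Generate a coupled synthetic cohort
#'
#' For gamma variants, each subject's gamma series is generated first, its
#' motivation transform computed, and the very same zeta series then
#' moderates that subject's simulated session — the ground-truth coupling
#' needed for parameter- and model-recovery studies. True parameters are
#' returned verbatim alongside the sessions.
#'
#' @param n_subjects cohort size.
#' @param variant model variant.
#' @param param_sampler per-subject sampler, as from [param_sampler_default()].
#' @param trend_spec a [gamma_trend_spec()] (gamma variants).
#' @param task a [task_config()].
#' @param seed root seed; per-subject streams are derived from it.
#' @param zeta_cfg a [zeta_config()] for the trial-mode transform.
#' @return list with `sessions`, `gamma` (list of [gamma_series()] or NULL),
#'   `zeta` (list or NULL), `true_params` (list of [model_params()]).
#' @export
generate_synthetic_cohort <- function(n_subjects,
                                      variant = c("cmf", "gamma1", "gamma2"),
                                      param_sampler = NULL,
                                      trend_spec = gamma_trend_spec(),
                                      task = task_config(), seed = 1,
                                      zeta_cfg = zeta_config("trial")) {
  variant <- match.arg(variant)
  if (is.null(param_sampler)) param_sampler <- param_sampler_default(variant)
  # expected trials per session: mean ISI 6 s plus ~0.25 s of responding;
  # generate half a session extra so an emergent overrun stays covered
  n_session <- round(task$duration_s / 6.25)
  n_max <- ceiling(1.5 * n_session)
  sessions <- vector("list", n_subjects)
  gammas <- vector("list", n_subjects)
  zetas <- vector("list", n_subjects)
  pars <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(child_seed(seed, i))
    pars[[i]] <- param_sampler(i)
    subj <- paste0("s", i)
    if (variant == "cmf") {
      sessions[[i]] <- simulate_session(pars[[i]], task = task, subject = subj)
    } else {
      gs <- generate_gamma_series(n_max, trend_spec, subject = subj,
                                  n_session = n_session)
      z <- if (variant == "gamma1") {
        zeta_binned(bin_aggregate(gs$gamma_power, gs$bin, "mean"))
      } else {
        suppressMessages(zeta_trial(gs, zeta_cfg))
      }
      sessions[[i]] <- simulate_session(pars[[i]], zeta = as.numeric(z),
                                        task = task, subject = subj)
      n_real <- nrow(sessions[[i]]$trials)
      gammas[[i]] <- gamma_series(gs$gamma_power[seq_len(n_real)],
                                  subject = subj,
                                  bin = gs$bin[seq_len(n_real)])
      zetas[[i]] <- as.numeric(z)[seq_len(n_real)]
    }
  }
  list(sessions = sessions,
       gamma = if (variant == "cmf") NULL else gammas,
       zeta = if (variant == "cmf") NULL else zetas,
       true_params = pars)
}

#' Generate synthetic EEG epochs with in-band bursts
#'
#' White noise plus a sinusoidal burst inside the 70-80 Hz band, injected
#' only within the -300..800 ms analysis window, with a per-bin amplitude
#' profile — a fixture with a known ground truth for the spectral pipeline.
#'
#' @param n_trials number of epochs.
#' @param rate_hz sampling rate (> 160 so the band is below Nyquist).
#' @param span_ms epoch span.
#' @param burst_hz burst frequency in Hz.
#' @param amp_profile 5 per-bin burst amplitudes (>= 0).
#' @param noise_sd white-noise standard deviation.
#' @param seed optional seed.
#' @return an [epoch_matrix()] with attribute `bin` (per-trial labels).
#' @export
generate_synthetic_epochs <- function(n_trials, rate_hz = 512,
                                      span_ms = c(-1500, 1500),
                                      burst_hz = 75,
                                      amp_profile = c(1, 1.3, 1.1, 1.3, 0.8),
                                      noise_sd = 1, seed = NULL) {
  if (rate_hz <= 160) stop("generate_synthetic_epochs: rate must exceed 160 Hz",
                           call. = FALSE)
  if (burst_hz >= rate_hz / 2) {
    stop("generate_synthetic_epochs: burst band above Nyquist", call. = FALSE)
  }
  if (any(amp_profile < 0)) {
    stop("generate_synthetic_epochs: amplitudes must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_samp <- floor(diff(span_ms) * rate_hz / 1000)
  t_ms <- span_ms[1] + (seq_len(n_samp) - 1) * 1000 / rate_hz
  in_win <- t_ms >= -300 & t_ms < 800
  bin <- pmin(floor((seq_len(n_trials) - 1) / n_trials * 5) + 1, 5)
  m <- matrix(rnorm(n_trials * n_samp, 0, noise_sd), nrow = n_trials)
  burst <- sin(2 * pi * burst_hz * t_ms / 1000)
  for (i in seq_len(n_trials)) {
    m[i, in_win] <- m[i, in_win] + amp_profile[bin[i]] * burst[in_win]
  }
  out <- epoch_matrix(m, rate_hz, span_ms)
  attr(out, "bin") <- bin
  out
}
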