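#' Simulated-likelihood settings
#'
#' The trial-level likelihood is approximated by forward simulation: a
#' defective mixture of point masses on the false-start and sleep-attack
#' categories plus a density over response RTs, estimated either as a
#' fixed-bin histogram (10-ms bins over 150-1,000 ms plus a lumped tail) or a
#' Gaussian kernel density. Because a trial's outcome distribution depends on
#' its moderator, the mixture is built per stratum — zeta quartiles for the
#' single-trial gamma model, 2-minute time bins otherwise — and each observed
#' trial is scored in its own stratum. All masses are floored at `eps` so an
#' observed outcome never scores -Inf.
#'
#' @param n_sim simulated trials per likelihood evaluation (>= 100).
#' @param estimator `"histogram"` or `"kde"`.
#' @param eps category/density mass floor (> 0).
#' @param bin_ms histogram bin width in ms.
#' @param rt_range histogram support in ms; slower responses fall in the tail
#'   mass.
#' @export
likelihood_config <- function(n_sim = 2000, estimator = c("histogram", "kde"),
                              eps = 1e-6, bin_ms = 10, rt_range = c(150, 1000)) {
  estimator <- match.arg(estimator)
  if (n_sim < 100) stop("likelihood_config: need n_sim >= 100", call. = FALSE)
  if (eps <= 0) stop("likelihood_config: `eps` must be > 0", call. = FALSE)
  structure(list(n_sim = n_sim, estimator = estimator, eps = eps,
                 bin_ms = bin_ms, rt_range = rt_range),
            class = "likelihood_config")
}

# Run a function under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

proposal_seed <- function(root, chain, iter) {
  (as.numeric(root) * 2654435 + chain * 97561 + iter * 3571) %% 2147483629
}

#' Approximate trial-level log-likelihood by forward simulation
#'
#' Simulates sessions at the candidate parameters until at least `n_sim`
#' trials are collected (re-using the observed session's task settings and,
#' for gamma variants, its zeta series), builds the defective outcome mixture
#' of [likelihood_config()], and sums the log mass/density of every observed
#' trial. Deterministic given `seed`; invariant to observed-trial order.
#'
#' @param observed a `session_result` (or a trial data.frame with columns
#'   `rt_ms`, `type`).
#' @param params candidate [model_params()].
#' @param config a [likelihood_config()].
#' @param zeta zeta series for gamma variants; defaults to the observed
#'   session's applied zeta.
#' @param task a [task_config()]; defaults to the observed session's.
#' @param seed simulation seed for this evaluation.
#' @return scalar log-likelihood.
#' @export
approx_loglik <- function(observed, params, config = likelihood_config(),
                          zeta = NULL, task = NULL, seed = 1) {
  trials <- if (inherits(observed, "session_result")) observed$trials else observed
  if (is.null(trials) || nrow(trials) == 0) {
    stop("approx_loglik: empty observation", call. = FALSE)
  }
  if (is.null(task)) {
    task <- if (inherits(observed, "session_result")) observed$task else task_config()
  }
  if (is.null(zeta) && params$variant != "cmf") {
    if (!"zeta" %in% names(trials)) {
      stop("approx_loglik: gamma variants need a zeta series", call. = FALSE)
    }
    zeta <- if (params$variant == "gamma1") {
      bins <- assign_time_bins(trials$onset_s, task$duration_s)
      as.numeric(tapply(trials$zeta, factor(bins, levels = 1:5),
                        function(x) x[1]))
    } else {
      trials$zeta
    }
  }
  n_obs <- nrow(trials)
  n_sessions <- ceiling(config$n_sim / max(n_obs, 1))

  z_sim <- if (params$variant == "cmf") 1 else as.numeric(zeta)
  sim <- with_seed(seed, {
    cpp_simulate_trials(unclass(params), variant_code(params$variant), z_sim,
                        task$duration_s, task$timeout_s, task$isi_choices,
                        n_sessions)
  })
  if (length(sim$type) == 0) return(n_obs * log(config$eps))

  # Conditional strata: the outcome distribution of a trial depends on its
  # moderator, so observed trials are scored against simulated trials from the
  # same stratum — zeta quartiles for the single-trial gamma model, 2-minute
  # time bins otherwise (where zeta/time-on-task is bin-constant).
  if (params$variant == "gamma2") {
    zb <- unique(quantile(trials$zeta, c(0.25, 0.5, 0.75), names = FALSE))
    obs_g <- findInterval(trials$zeta, zb) + 1L
    sim_g <- findInterval(sim$zeta, zb) + 1L
    n_g <- length(zb) + 1L
  } else {
    obs_g <- assign_time_bins(pmin(trials$onset_s, task$duration_s),
                              task$duration_s)
    sim_g <- assign_time_bins(pmin(sim$onset_s, task$duration_s),
                              task$duration_s)
    n_g <- 5L
  }

  lo <- config$rt_range[1]
  hi <- config$rt_range[2]
  breaks <- seq(lo, hi, by = config$bin_ms)
  n_bins <- length(breaks) - 1

  ll <- numeric(n_obs)
  for (g in seq_len(n_g)) {
    og <- which(obs_g == g)
    if (length(og) == 0) next
    sg <- sim_g == g
    n_tot <- sum(sg)
    if (n_tot == 0) {
      ll[og] <- log(config$eps)
      next
    }
    st <- sim$type[sg]
    resp <- sim$rt_ms[sg][st <= 1L]
    p_fs <- mean(st == 2L)
    p_sa <- mean(st == 3L)
    tail_mass <- sum(resp >= hi) / n_tot
    if (config$estimator == "histogram") {
      # bins [lo, lo+w), ..., [hi-w, hi); slower responses fall into
      # log-spaced tail bins (cascade depth carries the microlapse-penalty
      # signal)
      counts <- tabulate(findInterval(resp[resp >= lo & resp < hi], breaks),
                         nbins = n_bins)
      bin_mass <- counts / n_tot
      tail_breaks <- c(hi, 1400, 2000, 3000, 5000, 10000, Inf)
      tail_counts <- tabulate(findInterval(resp[resp >= hi], tail_breaks),
                              nbins = length(tail_breaks) - 1)
      tail_bin_mass <- tail_counts / n_tot
      mass_of_rt <- function(rt) {
        ifelse(rt >= hi,
               tail_bin_mass[pmax(1, findInterval(rt, tail_breaks))],
               bin_mass[pmax(1, pmin(n_bins,
                                     floor((rt - lo) / config$bin_ms) + 1))])
      }
    } else {
      p_resp <- sum(resp < hi) / n_tot
      if (sum(resp < hi) >= 2) {
        kd <- density(resp[resp < hi], bw = "nrd0", from = lo - 50, to = hi + 50)
        mass_of_rt <- function(rt) {
          ifelse(rt >= hi, tail_mass,
                 p_resp * approx(kd$x, kd$y, xout = rt, rule = 2)$y * config$bin_ms)
        }
      } else {
        mass_of_rt <- function(rt) ifelse(rt >= hi, tail_mass, 0)
      }
    }
    obs_rt <- trials$rt_ms[og]
    obs_type <- trials$type[og]
    is_fs <- obs_type == "false_start" | (!is.na(obs_rt) & obs_rt < lo)
    is_sa <- obs_type == "sleep_attack"
    is_resp <- !is_fs & !is_sa
    lg <- numeric(length(og))
    lg[is_fs] <- log(max(p_fs, config$eps))
    lg[is_sa] <- log(max(p_sa, config$eps))
    if (any(is_resp)) {
      lg[is_resp] <- log(pmax(mass_of_rt(obs_rt[is_resp]), config$eps))
    }
    ll[og] <- lg
  }
  sum(ll)
}

#' Differential-evolution MCMC settings
#'
#' @param chains number of chains; default `4 * d` where `d` is the number of
#'   free parameters.
#' @param iterations sampling iterations per chain.
#' @param burn_in iterations discarded before the posterior mode is tracked.
#' @param gamma_de DE step size; default `2.38 / sqrt(2 d)`.
#' @param jitter uniform jitter half-width added to every proposal.
#' @param refresh probability per chain-iteration of re-evaluating the held
#'   (noisy) log-likelihood under a fresh seed, which stops chains sticking
#'   to lucky simulation draws.
#' @export
de_settings <- function(chains = NULL, iterations = 1000, burn_in = 500,
                        gamma_de = NULL, jitter = 1e-4, refresh = 0.2) {
  structure(list(chains = chains, iterations = iterations, burn_in = burn_in,
                 gamma_de = gamma_de, jitter = jitter, refresh = refresh),
            class = "de_settings")
}

reflect_into <- function(x, lower, upper) {
  for (k in seq_along(x)) {
    while (x[k] < lower[k] || x[k] > upper[k]) {
      if (x[k] < lower[k]) x[k] <- 2 * lower[k] - x[k]
      if (x[k] > upper[k]) x[k] <- 2 * upper[k] - x[k]
    }
  }
  x
}

params_from_vector <- function(theta, variant, fixed) {
  if (variant == "cmf") {
    model_params(theta[["upsilon"]], theta[["lambda"]], theta[["phi"]],
                 rho = theta[["rho"]], kappa = theta[["kappa"]],
                 tau = fixed$tau, s = fixed$s,
                 t_microlapse = fixed$t_microlapse, t_motor = fixed$t_motor,
                 mismatch = fixed$mismatch, variant = variant)
  } else {
    model_params(theta[["upsilon"]], theta[["lambda"]], theta[["phi"]],
                 tau = fixed$tau, s = fixed$s,
                 t_microlapse = fixed$t_microlapse, t_motor = fixed$t_motor,
                 mismatch = fixed$mismatch, variant = variant)
  }
}

#' Fit one subject by DE-MCMC over the simulated likelihood
#'
#' Differential-evolution MCMC with uniform priors on the fitting bounds
#' (reflection at the edges), a fresh simulation seed per proposal derived
#' from (`seed`, chain, iteration), and the posterior mode as point estimate —
#' penalised maximum likelihood under the bounded uniform prior. Because the
#' simulated likelihood is noisy, the raw argmax favours lucky simulation
#' draws; the leading post-burn-in states are therefore re-scored under five
#' fresh seeds and the best averaged log-likelihood wins (reported as `-2LL`).
#' AIC is `-2LL + 2p` with `p` free parameters (5 for the CMF, 3 for the
#' gamma variants; the threshold is fixed at 2.0).
#'
#' @param observed a `session_result` (or trial data.frame).
#' @param variant model variant to fit.
#' @param bounds fitting box, as from [param_bounds()].
#' @param de a [de_settings()].
#' @param config a [likelihood_config()].
#' @param fixed named list of configuration constants (`tau`, `s`,
#'   `t_microlapse`, `t_motor`, `mismatch`).
#' @param zeta zeta series for gamma variants (defaults to the observed
#'   session's).
#' @param seed root seed; the fit is fully reproducible given it.
#' @return object of class `fit_result`.
#' @export
fit_subject <- function(observed, variant = c("cmf", "gamma1", "gamma2"),
                        bounds = NULL, de = de_settings(),
                        config = likelihood_config(), fixed = list(),
                        zeta = NULL, seed = 1) {
  variant <- match.arg(variant)
  if (is.null(bounds)) bounds <- param_bounds(variant)
  fixed <- modifyList(list(tau = 2.0, s = 0.45, t_microlapse = 0.05,
                           t_motor = 0.1, mismatch = 6.0), fixed)
  d <- nrow(bounds)
  n_chains <- if (is.null(de$chains)) 4L * d else de$chains
  if (n_chains < 4) stop("fit_subject: need >= 4 chains", call. = FALSE)
  gamma_de <- if (is.null(de$gamma_de)) 2.38 / sqrt(2 * d) else de$gamma_de
  lower <- bounds$lower
  upper <- bounds$upper
  pnames <- bounds$param

  subject <- if (inherits(observed, "session_result")) observed$subject else "s1"

  ll_fun <- function(theta, sd) {
    par <- params_from_vector(setNames(as.list(theta), pnames), variant, fixed)
    approx_loglik(observed, par, config = config, zeta = zeta, seed = sd)
  }

  n_bad <- 0L
  res <- with_seed(seed, {
    theta <- sapply(seq_len(d), function(k) runif(n_chains, lower[k], upper[k]))
    theta <- matrix(theta, nrow = n_chains,
                    dimnames = list(NULL, pnames))
    ll <- vapply(seq_len(n_chains), function(i) {
      ll_fun(theta[i, ], proposal_seed(seed, i, 0))
    }, numeric(1))
    # reservoir of the highest-scoring post-burn-in states, for mode polishing
    n_top <- 15L
    top_theta <- matrix(NA_real_, n_top, d)
    top_ll <- rep(-Inf, n_top)
    n_accept <- 0L
    for (it in seq_len(de$iterations)) {
      for (i in seq_len(n_chains)) {
        # refresh the held noisy log-likelihood occasionally so a chain
        # cannot stay stuck on one lucky simulation draw
        if (runif(1) < de$refresh) {
          ll[i] <- ll_fun(theta[i, ], proposal_seed(seed, i + n_chains, it))
        }
        ab <- sample(setdiff(seq_len(n_chains), i), 2)
        prop <- theta[i, ] + gamma_de * (theta[ab[1], ] - theta[ab[2], ]) +
          runif(d, -de$jitter, de$jitter)
        prop <- reflect_into(prop, lower, upper)
        ll_prop <- ll_fun(prop, proposal_seed(seed, i, it))
        if (!is.finite(ll_prop)) {
          n_bad <- n_bad + 1L
          if (n_bad > n_chains * 10L) {
            stop("fit_subject: non-finite log-likelihood persisted beyond ",
                 n_chains * 10L, " proposals (chain ", i, ", iteration ", it,
                 ")", call. = FALSE)
          }
          next
        }
        n_bad <- 0L
        if (log(runif(1)) < ll_prop - ll[i]) {
          theta[i, ] <- prop
          ll[i] <- ll_prop
          n_accept <- n_accept + 1L
        }
        if (it > de$burn_in && ll[i] > min(top_ll) &&
            !any(top_ll == ll[i])) {
          k <- which.min(top_ll)
          top_ll[k] <- ll[i]
          top_theta[k, ] <- theta[i, ]
        }
      }
    }
    # Mode polishing: the raw argmax over single noisy evaluations favours
    # lucky simulation draws; re-score the leading states under several fresh
    # seeds and keep the best averaged log-likelihood.
    keep <- which(is.finite(top_ll))
    if (length(keep) == 0) {
      keep <- 1L
      top_theta[1, ] <- theta[1, ]
    }
    avg <- vapply(keep, function(j) {
      mean(vapply(1:5, function(r) {
        ll_fun(top_theta[j, ],
               proposal_seed(seed, j, de$iterations + r))
      }, numeric(1)))
    }, numeric(1))
    jbest <- keep[which.max(avg)]
    list(best_theta = top_theta[jbest, ], best_ll = max(avg),
         acceptance = n_accept / (de$iterations * n_chains))
  })

  est <- setNames(as.numeric(res$best_theta), pnames)
  neg2ll <- -2 * res$best_ll
  structure(list(subject = subject, variant = variant,
                 estimates = est, neg2ll = neg2ll,
                 aic = aic(neg2ll, d), n_free = d,
                 chains = n_chains, iterations = de$iterations,
                 burn_in = de$burn_in, acceptance_rate = res$acceptance,
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit (%s, subject %s): -2LL = %.2f, AIC = %.2f (p = %d)\n",
              x$variant, x$subject, x$neg2ll, x$aic, x$n_free))
  print(round(x$estimates, 4))
  cat(sprintf("  %d chains x %d iterations, acceptance %.2f, seed %s\n",
              x$chains, x$iterations, x$acceptance_rate, format(x$seed)))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = -2LL + 2p`.
#'
#' @param neg2ll minimised -2 log-likelihood.
#' @param n_free_params number of free parameters (>= 1).
#' @export
aic <- function(neg2ll, n_free_params) {
  if (any(n_free_params < 1)) stop("aic: need n_free_params >= 1", call. = FALSE)
  neg2ll + 2 * n_free_params
}

#' Compare fitted model variants by AIC
#'
#' Per-subject AIC differences between every pair of variants, with mean and
#' standard error; the winner is the variant with the lowest mean AIC.
#'
#' @param fits named list: one entry per variant, each a list of
#'   `fit_result`s covering the same subjects.
#' @return object of class `model_comparison` with `aic` (subject x variant
#'   data.frame), `delta` (pairwise per-subject differences), `mean_aic`,
#'   `winner`.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2 || is.null(names(fits))) {
    stop("compare_models: need a named list of >= 2 variants", call. = FALSE)
  }
  subj <- lapply(fits, function(f) sort(vapply(f, `[[`, "", "subject")))
  if (!all(vapply(subj, identical, TRUE, subj[[1]]))) {
    stop("compare_models: variants fitted on different subjects", call. = FALSE)
  }
  aic_tab <- data.frame(subject = subj[[1]], stringsAsFactors = FALSE)
  for (v in names(fits)) {
    ord <- order(vapply(fits[[v]], `[[`, "", "subject"))
    aic_tab[[v]] <- vapply(fits[[v]][ord], `[[`, numeric(1), "aic")
  }
  vn <- names(fits)
  deltas <- list()
  for (i in seq_along(vn)) {
    for (j in seq_along(vn)) {
      if (i < j) {
        dd <- aic_tab[[vn[i]]] - aic_tab[[vn[j]]]
        deltas[[paste0(vn[i], "-", vn[j])]] <-
          list(per_subject = dd, mean = mean(dd),
               se = sd(dd) / sqrt(length(dd)))
      }
    }
  }
  mean_aic <- vapply(vn, function(v) mean(aic_tab[[v]]), numeric(1))
  structure(list(aic = aic_tab, delta = deltas, mean_aic = mean_aic,
                 winner = vn[which.min(mean_aic)]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (mean AIC):\n")
  print(round(x$mean_aic, 2))
  cat("winner:", x$winner, "\n")
  invisible(x)
}
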