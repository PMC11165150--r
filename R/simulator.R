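RESPONSE_TYPES <- c("alert", "lapse", "false_start", "sleep_attack")

type_label <- function(code) RESPONSE_TYPES[code + 1L]

#' PVT task configuration
#'
#' A 10-minute session with inter-stimulus intervals drawn uniformly from the
#' whole seconds 2..10 and a 30-second response timeout (a miss is scored as a
#' sleep attack).
#'
#' @param duration_s session duration in seconds.
#' @param isi_choices integer ISI support in seconds, a subset of 2..10.
#' @param timeout_s response timeout in seconds.
#' @export
task_config <- function(duration_s = 600, isi_choices = 2:10, timeout_s = 30) {
  if (duration_s <= 0) stop("task_config: duration must be > 0", call. = FALSE)
  if (!all(isi_choices %in% 2:10)) {
    stop("task_config: ISI support must be whole seconds within 2..10", call. = FALSE)
  }
  if (timeout_s <= 0) stop("task_config: timeout must be > 0", call. = FALSE)
  structure(list(duration_s = duration_s,
                 isi_choices = as.integer(isi_choices),
                 timeout_s = timeout_s),
            class = "task_config")
}

#' Simulate a single PVT trial
#'
#' Runs the production cycle for one trial from the current fatigue state:
#' pre-stimulus cycles (candidates wait / respond, a respond firing is a false
#' start), then post-stimulus cycles (attend competing with wait, then
#' respond). Every cycle in which no candidate's noisy utility clears the
#' threshold after stimulus onset is a microlapse: it consumes
#' `phi + t_microlapse` seconds and increments the session's microlapse
#' count, further lowering utilities. RT is the time from stimulus onset
#' through the respond firing plus `t_motor`. No response within the timeout
#' is a sleep attack.
#'
#' @param params a [model_params()].
#' @param state a [fatigue_state()].
#' @param zeta motivation value applied this trial (1 for the CMF).
#' @param task a [task_config()].
#' @param isi inter-stimulus interval for this trial (seconds); drawn from
#'   `task$isi_choices` when `NULL`.
#' @return list with `outcome` (one-row data.frame: `onset_s`, `isi_s`,
#'   `rt_ms`, `type`, `n_ml_trial`, `zeta`) and `state` (updated
#'   [fatigue_state()]).
#' @export
simulate_trial <- function(params, state, zeta = 1, task = task_config(),
                           isi = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(state, "fatigue_state"))
  if (params$variant == "cmf" && zeta != 1) {
    stop("simulate_trial: zeta must be 1 for the CMF variant", call. = FALSE)
  }
  if (is.null(isi)) {
    isi <- sample(task$isi_choices, 1)
  }
  res <- cpp_simulate_trial(unclass(params), variant_code(params$variant),
                            zeta, state$n_ml, state$t_minutes * 60,
                            isi, task$timeout_s)
  outcome <- data.frame(
    onset_s = res$onset_s,
    isi_s = isi,
    rt_ms = res$rt_ms,
    type = type_label(res$type),
    n_ml_trial = res$n_ml_trial,
    zeta = res$zeta,
    stringsAsFactors = FALSE)
  list(outcome = outcome,
       state = fatigue_state(res$n_ml, res$elapsed_end / 60))
}

#' Simulate a full PVT session
#'
#' Chains trials with fresh ISI draws until the session duration elapses.
#' The CMF variant moderates utility and threshold by time-on-task each
#' cycle; the gamma variants hold the threshold at `tau` and moderate utility
#' by the supplied zeta series (per 2-minute bin for `"gamma1"`, per trial
#' for `"gamma2"`; a series shorter than the realised trial count is extended
#' by its last value with a warning).
#'
#' @param params a [model_params()].
#' @param zeta zeta series (`"gamma1"`: 5 per-bin values; `"gamma2"`: per
#'   trial). Must be `NULL` for the CMF.
#' @param task a [task_config()].
#' @param subject subject identifier.
#' @param seed optional seed applied before simulation.
#' @return a `session_result`: list with `subject`, `variant`, `params`,
#'   `trials` (data.frame), `final_state`.
#' @examples
#' p <- model_params(3.8, 0.98, 0.057, rho = -0.05, kappa = -0.01, variant = "cmf")
#' s <- simulate_session(p, seed = 1)
#' table(s$trials$type)
#' @export
simulate_session <- function(params, zeta = NULL, task = task_config(),
                             subject = "s1", seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(seed)
  if (params$variant == "cmf") {
    if (!is.null(zeta)) {
      stop("simulate_session: the CMF takes no zeta series", call. = FALSE)
    }
    zeta <- 1
  } else {
    if (is.null(zeta)) {
      stop("simulate_session: variant '", params$variant,
           "' requires a zeta series", call. = FALSE)
    }
    if (any(zeta < 0)) stop("simulate_session: zeta cannot go below zero", call. = FALSE)
    if (params$variant == "gamma1" && length(zeta) != 5) {
      stop("simulate_session: gamma1 takes one zeta per 2-minute bin (5 values)",
           call. = FALSE)
    }
  }
  res <- cpp_simulate_session(unclass(params), variant_code(params$variant),
                              as.numeric(zeta), task$duration_s,
                              task$timeout_s, task$isi_choices)
  n <- length(res$onset_s)
  # a scalar zeta means constant motivation and recycles silently
  if (params$variant == "gamma2" && length(zeta) > 1 && n > length(zeta)) {
    warning("simulate_session: zeta series shorter than realised trial count (",
            length(zeta), " < ", n, "); extended by its last value")
  }
  trials <- data.frame(
    subject = rep(subject, n),
    trial = seq_len(n),
    onset_s = res$onset_s,
    isi_s = res$isi_s,
    rt_ms = res$rt_ms,
    type = type_label(res$type),
    n_ml_trial = res$n_ml_trial,
    zeta = res$zeta,
    stringsAsFactors = FALSE)
  structure(list(subject = subject,
                 variant = params$variant,
                 params = params,
                 task = task,
                 trials = trials,
                 final_state = fatigue_state(res$final_n_ml,
                                             res$final_elapsed / 60)),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  tab <- table(factor(x$trials$type, levels = RESPONSE_TYPES))
  cat(sprintf("PVT session (%s, subject %s): %d trials, %d microlapses\n",
              x$variant, x$subject, nrow(x$trials), x$final_state$n_ml))
  print(tab)
  invisible(x)
}

#' Simulate a cohort of independent subjects
#'
#' Draws per-subject parameters from `param_sampler` and simulates one session
#' each. Per-subject seeds are derived from `seed` by fixed offsets so a
#' cohort is reproducible and insensitive to evaluation order.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param param_sampler function(subject_index) returning a [model_params()];
#'   called under the subject's derived seed.
#' @param zeta_fn optional function(subject_index) returning the subject's
#'   zeta series (required for gamma variants).
#' @param task a [task_config()].
#' @param seed root seed.
#' @return list of `session_result` objects with subjects `"s1".."sN"`.
#' @export
simulate_cohort <- function(n_subjects, param_sampler, zeta_fn = NULL,
                            task = task_config(), seed = 1) {
  if (n_subjects < 1) stop("simulate_cohort: need n_subjects >= 1", call. = FALSE)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(child_seed(seed, i))
    p <- param_sampler(i)
    z <- if (is.null(zeta_fn)) NULL else zeta_fn(i)
    simulate_session(p, zeta = z, task = task,
                     subject = paste0("s", i))
  })
}

# Derived child seed: deterministic, order-independent, < 2^31.
child_seed <- function(root, i) {
  (as.numeric(root) * 48271 + as.numeric(i) * 9973) %% 2147483629
}

#' Write / read simulated sessions
#'
#' The trial table goes to CSV (columns `subject`, `trial`, `onset_s`,
#' `isi_s`, `rt_ms`, `type`, `n_ml_trial`, `zeta`); the parameters, variant
#' and any seed go to a JSON sidecar `<path>.json`.
#'
#' @param x a `session_result` or list of them.
#' @param path CSV output path.
#' @param seed optional seed echoed into the sidecar.
#' @export
write_session_csv <- function(x, path, seed = NULL) {
  sessions <- if (inherits(x, "session_result")) list(x) else x
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  write.csv(trials, path, row.names = FALSE)
  meta <- lapply(sessions, function(s) {
    c(list(subject = s$subject, variant = s$variant),
      unclass(s$params)[setdiff(names(unclass(s$params)), "variant")])
  })
  jsonlite::write_json(list(seed = seed, sessions = meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_csv
#' @return `read_session_csv`: the trial data.frame (all subjects).
#' @export
read_session_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "onset_s", "rt_ms", "type")
  if (!all(need %in% names(d))) {
    stop("read_session_csv: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}
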