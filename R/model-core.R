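#' Time-on-task and microlapse moderated utility (CMF)
#'
#' `U = upsilon * lambda^n_ml * (1 + t)^rho`, the perceived value of firing a
#' production after `n_ml` accumulated microlapses and `t` minutes on task.
#' With `lambda <= 1` and `rho <= 0` the utility can never exceed `upsilon`.
#'
#' @param upsilon initial utility (> 0).
#' @param lambda microlapse penalty in (0, 1].
#' @param n_ml cumulative microlapse count (non-negative integer, vectorised).
#' @param t_minutes time-on-task in minutes (>= 0, vectorised).
#' @param rho time-on-task exponent in (-1, 0].
#' @return utility value(s).
#' @examples
#' cmf_utility(3.82, 0.88, 0, 0, -0.20)   # = upsilon at task onset
#' cmf_utility(1, 0.98, 0, 10, -0.05)     # pure time-on-task decay
#' @export
cmf_utility <- function(upsilon, lambda, n_ml, t_minutes, rho) {
  if (any(upsilon <= 0)) stop("cmf_utility: `upsilon` must be > 0", call. = FALSE)
  if (any(lambda <= 0 | lambda > 1)) {
    stop("cmf_utility: `lambda` must lie in (0, 1]", call. = FALSE)
  }
  if (any(n_ml < 0) || any(n_ml != round(n_ml))) {
    stop("cmf_utility: `n_ml` must be a non-negative integer", call. = FALSE)
  }
  if (any(t_minutes < 0)) stop("cmf_utility: `t_minutes` must be >= 0", call. = FALSE)
  upsilon * lambda^n_ml * (1 + t_minutes)^rho
}

#' Time-on-task moderated utility threshold (CMF)
#'
#' `UT = tau * (1 + t)^kappa`. With `kappa < 0` the threshold declines with
#' time-on-task, a compensatory mechanism that keeps weakened productions
#' firing at the price of more inappropriate firings.
#'
#' @param tau initial threshold (> 0).
#' @param t_minutes time-on-task in minutes (>= 0, vectorised).
#' @param kappa threshold exponent in (-1, 0].
#' @return threshold value(s); equals `tau` at `t_minutes = 0`.
#' @export
cmf_threshold <- function(tau, t_minutes, kappa) {
  if (any(tau <= 0)) stop("cmf_threshold: `tau` must be > 0", call. = FALSE)
  if (any(t_minutes < 0)) stop("cmf_threshold: `t_minutes` must be >= 0", call. = FALSE)
  tau * (1 + t_minutes)^kappa
}

#' Gamma-motivation moderated utility
#'
#' `U = upsilon * lambda^n_ml * zeta`, linear in the motivation parameter
#' `zeta` (1 = baseline effort, > 1 compensatory effort, 0 = absolute
#' fatigue). Reduces to `cmf_utility(..., t_minutes = 0)` at `zeta = 1`.
#'
#' @inheritParams cmf_utility
#' @param zeta motivation parameter (>= 0, vectorised).
#' @export
gamma_utility <- function(upsilon, lambda, n_ml, zeta) {
  if (any(upsilon <= 0)) stop("gamma_utility: `upsilon` must be > 0", call. = FALSE)
  if (any(lambda <= 0 | lambda > 1)) {
    stop("gamma_utility: `lambda` must lie in (0, 1]", call. = FALSE)
  }
  if (any(n_ml < 0) || any(n_ml != round(n_ml))) {
    stop("gamma_utility: `n_ml` must be a non-negative integer", call. = FALSE)
  }
  if (any(zeta < 0)) {
    stop("gamma_utility: `zeta` cannot go below zero", call. = FALSE)
  }
  upsilon * lambda^n_ml * zeta
}

#' Draw production-utility noise
#'
#' Logistic noise with mean 0 and scale `s`, hence variance `pi^2/3 * s^2`.
#' `s = 0` degenerates to all zeros.
#'
#' @param s noise scale (>= 0).
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
sample_utility_noise <- function(s, n) {
  if (length(s) != 1 || s < 0) stop("sample_utility_noise: `s` must be >= 0", call. = FALSE)
  if (n < 1) stop("sample_utility_noise: `n` must be >= 1", call. = FALSE)
  if (s == 0) return(numeric(n))
  rlogis(n, location = 0, scale = s)
}

#' Conflict-resolution context
#'
#' The candidate productions competing in one conflict-resolution cycle, their
#' current (moderated) utilities, the utility threshold and the noise scale.
#' The above-threshold subset is derived, never stored.
#'
#' @param utilities named numeric vector of candidate utilities (non-empty).
#' @param threshold current utility threshold.
#' @param s noise scale (>= 0).
#' @export
selection_context <- function(utilities, threshold, s) {
  if (length(utilities) == 0) {
    stop("selection_context: candidate set must be non-empty", call. = FALSE)
  }
  if (is.null(names(utilities))) {
    names(utilities) <- paste0("p", seq_along(utilities))
  }
  if (s < 0) stop("selection_context: `s` must be >= 0", call. = FALSE)
  structure(list(utilities = utilities, threshold = threshold, s = s),
            class = "selection_context")
}

#' Closed-form selection and microlapse probabilities
#'
#' Over the above-threshold set J, the probability of selecting production i is
#' the soft-max `exp(U_i/2s) / sum_J exp(U_j/2s)` (Luce choice; the
#' conventional closed-form description of noisy-utility competition, exact
#' under extreme-value noise and an approximation under logistic noise). The
#' microlapse probability is the product of logistic CDFs
#' `prod_i F((UT - U_i)/s)`, i.e. the chance that every candidate's noisy
#' utility falls below threshold. An empty J gives microlapse probability 1.
#'
#' @param context a [selection_context()].
#' @return list with `p_select` (named, over all candidates; zero for
#'   sub-threshold ones), `p_microlapse`, and `tie` (TRUE when `s = 0` had to
#'   break a tie deterministically).
#' @export
selection_probabilities <- function(context) {
  stopifnot(inherits(context, "selection_context"))
  u <- context$utilities
  ut <- context$threshold
  s <- context$s
  above <- u >= ut
  p <- setNames(numeric(length(u)), names(u))
  tie <- FALSE
  if (!any(above)) {
    return(list(p_select = p, p_microlapse = 1, tie = FALSE))
  }
  if (s == 0) {
    ua <- u[above]
    win <- names(ua)[which.max(ua)]  # which.max: first index wins ties
    tie <- sum(ua == max(ua)) > 1
    p[win] <- 1
    return(list(p_select = p, p_microlapse = 0, tie = tie))
  }
  e <- exp((u[above] - max(u[above])) / (2 * s))
  p[above] <- e / sum(e)
  p_ml <- prod(plogis((ut - u) / s))
  list(p_select = p, p_microlapse = p_ml, tie = FALSE)
}

#' Resolve one conflict-resolution cycle operationally
#'
#' Adds an independent logistic noise draw to every candidate utility and
#' fires the noisy-max candidate if its noisy utility clears the threshold;
#' otherwise the cycle is a microlapse. With `s = 0` ties are broken in favour
#' of the lowest candidate index.
#'
#' @param context a [selection_context()].
#' @param n number of independent cycles to resolve.
#' @return character vector of length `n`: the fired production's name, or
#'   `"MICROLAPSE"`.
#' @export
resolve_conflict <- function(context, n = 1) {
  stopifnot(inherits(context, "selection_context"))
  u <- context$utilities
  k <- length(u)
  if (context$s == 0) {
    pr <- selection_probabilities(context)
    out <- if (pr$p_microlapse == 1) "MICROLAPSE" else names(which(pr$p_select == 1))
    return(rep(out, n))
  }
  noisy <- matrix(rlogis(n * k, 0, context$s), nrow = k) + u
  winner <- max.col(t(noisy), ties.method = "first")
  fired <- noisy[cbind(winner, seq_len(n))] >= context$threshold
  ifelse(fired, names(u)[winner], "MICROLAPSE")
}
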