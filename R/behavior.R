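#' Classify a PVT response
#'
#' Standard PVT response typing: a press before the stimulus or an RT below
#' 150 ms is a false start; 150-500 ms is an alert response; above 500 ms a
#' lapse; at or beyond 30,000 ms (the timeout) a sleep attack. The
#' pre-stimulus rule takes precedence, and the bands partition all positive
#' RTs exactly once.
#'
#' @param rt_ms response time in ms (vectorised); may be `NA` when
#'   `pressed_pre_stimulus` is TRUE.
#' @param pressed_pre_stimulus logical, press occurred before stimulus onset.
#' @return character vector of response types.
#' @export
classify_response <- function(rt_ms, pressed_pre_stimulus = FALSE) {
  n <- max(length(rt_ms), length(pressed_pre_stimulus))
  rt_ms <- rep_len(rt_ms, n)
  pre <- rep_len(pressed_pre_stimulus, n)
  if (any(!pre & (is.na(rt_ms) | rt_ms <= 0))) {
    stop("classify_response: rt_ms must be > 0 unless the press was pre-stimulus",
         call. = FALSE)
  }
  out <- character(n)
  out[pre] <- "false_start"
  idx <- !pre
  out[idx & rt_ms < 150] <- "false_start"
  out[idx & rt_ms >= 150 & rt_ms <= 500] <- "alert"
  out[idx & rt_ms > 500 & rt_ms < 30000] <- "lapse"
  out[idx & rt_ms >= 30000] <- "sleep_attack"
  out
}

#' Assign 2-minute time bins
#'
#' Five right-open 120-s bins over a 600-s session; the final bin is closed
#' at 600 so the bins partition the session exactly.
#'
#' @param onset_s stimulus onset time(s) in seconds from session start.
#' @param duration_s session duration.
#' @param n_bins number of bins.
#' @return integer bin in 1..`n_bins`.
#' @export
assign_time_bins <- function(onset_s, duration_s = 600, n_bins = 5) {
  if (any(onset_s < 0 | onset_s > duration_s)) {
    stop("assign_time_bins: onset outside the session", call. = FALSE)
  }
  pmin(floor(onset_s / (duration_s / n_bins)) + 1, n_bins)
}

#' Inverse response-time transform
#'
#' The speed score `1000 / RT`, used to de-skew mean-RT distributions before
#' statistical analysis.
#'
#' @param rt_ms response time(s) in ms, > 0.
#' @export
inverse_rt <- function(rt_ms) {
  if (any(is.na(rt_ms) | rt_ms <= 0)) {
    stop("inverse_rt: rt_ms must be > 0", call. = FALSE)
  }
  1000 / rt_ms
}

#' Aggregate RT quintile counts by time bin
#'
#' Per subject, responses with a measurable RT are rank-ordered (stable: ties
#' broken by trial order) and cut into five near-equal quintiles from fastest
#' (Q1) to slowest (Q5); quintile membership is then counted within each
#' 2-minute time bin and summed over subjects. Subjects with fewer than 5
#' classifiable RTs are excluded with a warning. Row sums equal the per-bin
#' trial counts by construction.
#'
#' @param trials data.frame with columns `subject`, `onset_s`, `rt_ms`
#'   (false starts / sleep attacks carry NA or are excluded by `types`).
#' @param types response types (of [classify_response()]) entering the
#'   distributional analysis.
#' @param duration_s session duration used for binning.
#' @return 5 x 5 integer matrix (time bin x quintile), class `quintile_table`.
#' @export
quintile_table <- function(trials, types = c("alert", "lapse"),
                           duration_s = 600) {
  if (!all(c("subject", "onset_s", "rt_ms") %in% names(trials))) {
    stop("quintile_table: need columns subject, onset_s, rt_ms", call. = FALSE)
  }
  if (!"type" %in% names(trials)) {
    trials$type <- classify_response(trials$rt_ms)
  }
  keep <- trials$type %in% types & !is.na(trials$rt_ms)
  d <- trials[keep, , drop = FALSE]
  tab <- matrix(0L, nrow = 5, ncol = 5,
                dimnames = list(bin = paste0("bin", 1:5),
                                quintile = paste0("Q", 1:5)))
  for (subj in unique(d$subject)) {
    ds <- d[d$subject == subj, , drop = FALSE]
    n <- nrow(ds)
    if (n < 5) {
      warning("quintile_table: subject ", subj, " has fewer than 5 classifiable RTs; excluded")
      next
    }
    r <- rank(ds$rt_ms, ties.method = "first")
    q <- floor((r - 1) * 5 / n) + 1   # near-equal sizes, difference <= 1
    b <- assign_time_bins(ds$onset_s, duration_s)
    for (i in seq_len(n)) tab[b[i], q[i]] <- tab[b[i], q[i]] + 1L
  }
  structure(tab, class = c("quintile_table", "matrix"))
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic `sum (O - E)^2 / E` with expected counts from the
#' row/column margins, no continuity correction; `df = (r - 1)(c - 1)` (16
#' for the 5 x 5 bin-by-quintile table).
#'
#' @param table matrix of non-negative counts with positive margins.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(table) {
  table <- unclass(as.matrix(table))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi_square_independence: zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Lagged gamma-to-RT cross-correlation with bootstrap CI
#'
#' Pearson correlation between the previous trial's gamma power
#' (gamma at k-1) and the current trial's RT (at k), with a percentile 95%
#' confidence interval from i.i.d. resampling of the lagged pairs.
#'
#' @param gamma per-trial gamma power (aligned with `rt_ms`).
#' @param rt_ms per-trial response times.
#' @param n_boot bootstrap replicates (>= 100).
#' @param conf confidence level.
#' @return list with `r`, `ci` (length 2), `n_pairs`, `n_boot`.
#' @export
lagged_crosscorr_bootstrap <- function(gamma, rt_ms, n_boot = 1000,
                                       conf = 0.95) {
  g <- if (inherits(gamma, "gamma_series")) gamma$gamma_power else gamma
  if (length(g) != length(rt_ms)) {
    stop("lagged_crosscorr_bootstrap: series must be aligned", call. = FALSE)
  }
  if (length(g) < 3) stop("lagged_crosscorr_bootstrap: need length >= 3", call. = FALSE)
  if (n_boot < 100) stop("lagged_crosscorr_bootstrap: need n_boot >= 100", call. = FALSE)
  ok <- !is.na(g[-length(g)]) & !is.na(rt_ms[-1])
  x <- g[-length(g)][ok]
  y <- rt_ms[-1][ok]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("lagged_crosscorr_bootstrap: zero variance, correlation undefined",
         call. = FALSE)
  }
  r <- cor(x, y)
  n <- length(x)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sd(x[idx]) == 0 || sd(y[idx]) == 0) return(NA_real_)
    cor(x[idx], y[idx])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  list(r = r, ci = ci, n_pairs = n, n_boot = n_boot)
}

#' Lapse proportion by time window
#'
#' Fraction of stimulus-present trials (false starts excluded) whose RT
#' exceeds 500 ms; timeouts (sleep attacks) exceed 500 ms by definition and
#' count as lapses — the standard PVT lapse rule.
#'
#' @param trials trial data.frame with `onset_s`, `rt_ms`, `type`.
#' @param from_s,to_s half-open onset window `[from_s, to_s)`.
#' @return proportion in \[0, 1\], or `NA` when no trial qualifies.
#' @export
lapse_proportion <- function(trials, from_s = 0, to_s = Inf) {
  d <- trials[trials$onset_s >= from_s & trials$onset_s < to_s &
                trials$type != "false_start", , drop = FALSE]
  if (nrow(d) == 0) return(NA_real_)
  mean(d$type == "sleep_attack" | (!is.na(d$rt_ms) & d$rt_ms > 500))
}
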