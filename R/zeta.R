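#' Per-trial gamma power series
#'
#' Strictly positive high-gamma (70-80 Hz) band power per trial for one
#' subject, optionally with 2-minute bin labels (1-5).
#'
#' @param gamma_power numeric vector, all > 0, length >= 1.
#' @param subject subject identifier.
#' @param bin optional integer bin labels in 1..5, same length.
#' @export
gamma_series <- function(gamma_power, subject = "s1", bin = NULL) {
  if (length(gamma_power) < 1) stop("gamma_series: length must be >= 1", call. = FALSE)
  if (any(!is.finite(gamma_power)) || any(gamma_power <= 0)) {
    stop("gamma_series: all gamma power values must be strictly positive",
         call. = FALSE)
  }
  if (!is.null(bin)) {
    if (length(bin) != length(gamma_power) || any(!bin %in% 1:5)) {
      stop("gamma_series: `bin` must match length and lie in 1..5", call. = FALSE)
    }
  }
  structure(list(subject = subject, gamma_power = as.numeric(gamma_power),
                 bin = bin),
            class = "gamma_series")
}

#' @export
print.gamma_series <- function(x, ...) {
  cat(sprintf("gamma series: subject %s, %d trials%s\n", x$subject,
              length(x$gamma_power),
              if (is.null(x$bin)) "" else ", binned"))
  invisible(x)
}

#' Settings for the gamma-to-motivation transform
#'
#' @param mode `"binned"` (one zeta per time bin) or `"trial"` (one per trial).
#' @param k baseline-trial count for trial mode (default 10).
#' @param b logarithm base for trial mode. The stated convention is a multiple
#'   of 10 with default 10; any other base > 1 is accepted with a warning
#'   since nothing in the transform requires the restriction.
#' @export
zeta_config <- function(mode = c("binned", "trial"), k = 10, b = 10) {
  mode <- match.arg(mode)
  if (k < 1 || k != round(k)) stop("zeta_config: `k` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1 || b <= 1) {
    stop("zeta_config: `b` must be > 1", call. = FALSE)
  }
  if (b < 10 || b %% 10 != 0) {
    warning("zeta_config: `b` is conventionally a multiple of 10 (default 10); ",
            "accepting b = ", b)
  }
  structure(list(mode = mode, k = as.integer(k), b = b), class = "zeta_config")
}

#' Binned motivation transform (Model 1)
#'
#' `zeta_t = 1 + (gamma_t - gamma_1) / range(gamma)`: each bin's deviation
#' from the first bin, scaled by the range, so the first bin is exactly 1 and
#' every value lies in \[0, 2\]. A zero range (constant power) yields an
#' all-ones series with a warning — effort at baseline throughout. The
#' transform is invariant to positive affine rescaling of the power values.
#'
#' @param binned_gamma per-bin gamma power (>= 2 bins, all > 0).
#' @return numeric zeta per bin.
#' @examples
#' zeta_binned(c(10, 12, 8, 11, 9))  # (1, 1.5, 0.5, 1.25, 0.75)
#' @export
zeta_binned <- function(binned_gamma) {
  if (length(binned_gamma) < 2) {
    stop("zeta_binned: need at least two bins", call. = FALSE)
  }
  if (any(binned_gamma <= 0)) {
    stop("zeta_binned: all gamma values must be > 0", call. = FALSE)
  }
  rng <- max(binned_gamma) - min(binned_gamma)
  if (rng == 0) {
    warning("zeta_binned: zero range (constant binned power); returning all ones")
    return(rep(1, length(binned_gamma)))
  }
  1 + (binned_gamma - binned_gamma[1]) / rng
}

#' Baseline gamma power
#'
#' Arithmetic mean of the first `k` trials, the reference against which
#' single-trial motivation is expressed.
#'
#' @param series a [gamma_series()] or numeric vector.
#' @param k number of baseline trials (1 <= k <= length).
#' @export
baseline_mean <- function(series, k) {
  g <- if (inherits(series, "gamma_series")) series$gamma_power else series
  if (k < 1 || k > length(g)) {
    stop("baseline_mean: `k` must lie in 1..length(series)", call. = FALSE)
  }
  mean(g[seq_len(k)])
}

#' Single-trial motivation transform (Model 2)
#'
#' `zeta_t = 1 + log_b(gamma_t / mean(gamma_1..gamma_k))`, a decibel-style
#' ratio against the mean power of the first `k` trials (baseline trials
#' included in the output, so early zeta hovers near 1). Values below zero —
#' possible for very small powers — are clamped to 0, since effort cannot go
#' below absolute fatigue; the number of clamped trials is reported via
#' attribute `n_clamped`. Scale-invariant in gamma, but not shift-invariant.
#'
#' @param series a [gamma_series()] or numeric vector, length > `k`.
#' @param config a [zeta_config()] (mode `"trial"`).
#' @return numeric zeta per trial with attribute `n_clamped`.
#' @export
zeta_trial <- function(series, config = zeta_config("trial")) {
  g <- if (inherits(series, "gamma_series")) series$gamma_power else series
  if (any(g <= 0)) stop("zeta_trial: all gamma values must be > 0", call. = FALSE)
  if (length(g) <= config$k) {
    stop("zeta_trial: series length must exceed the baseline count k = ",
         config$k, call. = FALSE)
  }
  mu <- baseline_mean(g, config$k)
  z <- 1 + log(g / mu, base = config$b)
  n_clamped <- sum(z < 0)
  if (n_clamped > 0) {
    message("zeta_trial: clamped ", n_clamped, " trial(s) at zero")
  }
  z <- pmax(z, 0)
  attr(z, "n_clamped") <- n_clamped
  z
}

#' Read / write per-trial gamma power tables
#'
#' CSV with columns `subject`, `trial`, `gamma_power` and optionally `bin`
#' (and, on output, `zeta`).
#'
#' @param path file path.
#' @return `read_gamma_csv`: a data.frame; the writer returns `path`
#'   invisibly.
#' @export
read_gamma_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "gamma_power")
  if (!all(need %in% names(d))) {
    stop("read_gamma_csv: need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  d
}

#' @rdname read_gamma_csv
#' @param d data.frame of gamma power (and optional zeta) values.
#' @export
write_gamma_csv <- function(d, path) {
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
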