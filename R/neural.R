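#' Epoch matrix of EEG voltage
#'
#' Trials x samples of voltage (microvolts) around stimulus onset. The
#' sampling rate must exceed twice the top of the high-gamma band (80 Hz) so
#' the 70-80 Hz power is resolvable.
#'
#' @param data numeric matrix, one trial per row.
#' @param rate_hz sampling rate (default 512).
#' @param span_ms length-2 epoch span in ms relative to stimulus onset.
#' @export
epoch_matrix <- function(data, rate_hz = 512, span_ms = c(-1500, 1500)) {
  data <- as.matrix(data)
  if (rate_hz <= 200) {
    stop("epoch_matrix: sampling rate must exceed 200 Hz (Nyquist for 70-80 Hz)",
         call. = FALSE)
  }
  expected <- floor(diff(span_ms) * rate_hz / 1000)
  if (abs(ncol(data) - expected) > 1) {
    stop("epoch_matrix: sample count ", ncol(data),
         " inconsistent with span/rate (expected ~", expected, ")", call. = FALSE)
  }
  structure(list(data = data, rate_hz = rate_hz, span_ms = span_ms),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("epoch matrix: %d trials x %d samples @ %g Hz, span %g..%g ms\n",
              nrow(x$data), ncol(x$data), x$rate_hz, x$span_ms[1], x$span_ms[2]))
  invisible(x)
}

#' Extract the peri-stimulus analysis window
#'
#' Sub-sets each epoch to the stated window (default -300..800 ms around
#' onset, 1100 ms). Sample indices are `floor(ms * rate / 1000)`, 0-based and
#' half-open, so -300..800 ms at 512 Hz yields 563 samples.
#'
#' @param epochs an [epoch_matrix()].
#' @param start_ms,end_ms window bounds in ms relative to onset.
#' @return an [epoch_matrix()] restricted to the window.
#' @export
extract_analysis_window <- function(epochs, start_ms = -300, end_ms = 800) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  if (start_ms >= end_ms) stop("extract_analysis_window: start >= end", call. = FALSE)
  if (start_ms < epochs$span_ms[1] || end_ms > epochs$span_ms[2]) {
    stop("extract_analysis_window: window outside the epoch span", call. = FALSE)
  }
  i0 <- floor((start_ms - epochs$span_ms[1]) * epochs$rate_hz / 1000)
  i1 <- floor((end_ms - epochs$span_ms[1]) * epochs$rate_hz / 1000)
  idx <- seq.int(i0 + 1, i1)   # half-open [i0, i1) in 0-based indexing
  epoch_matrix(epochs$data[, idx, drop = FALSE], epochs$rate_hz,
               c(start_ms, start_ms + length(idx) * 1000 / epochs$rate_hz))
}

# Periodic Hamming window of length n.
hamming_periodic <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / n)
}

#' Welch power spectral density of one trial
#'
#' Averages periodograms of periodic-Hamming-windowed segments (default
#' 367 ms, 25% overlap). Each segment is zero-padded to a power-of-two FFT
#' length giving at least 2,560 bins up to 256 Hz, and the averaged spectrum
#' is linearly interpolated onto a 2,560-point grid over 0-256 Hz (clipped at
#' the Nyquist frequency for lower sampling rates). Density scaling, so power
#' is in signal-units^2/Hz.
#'
#' @param signal numeric vector, one trial's samples.
#' @param rate_hz sampling rate.
#' @param window_ms segment length in ms.
#' @param overlap fractional segment overlap.
#' @param n_grid output grid size.
#' @return list of class `psd_result` with `freq`, `power`, `window` metadata.
#' @export
welch_psd <- function(signal, rate_hz = 512, window_ms = 367, overlap = 0.25,
                      n_grid = 2560) {
  n <- length(signal)
  L <- floor(window_ms * rate_hz / 1000)
  if (n < L) stop("welch_psd: signal shorter than one window", call. = FALSE)
  step <- L - floor(overlap * L)
  starts <- seq(1, n - L + 1, by = step)
  w <- hamming_periodic(L)
  scale <- rate_hz * sum(w^2)
  f_max <- min(256, rate_hz / 2)
  # native bin spacing no coarser than the output grid spacing
  nfft <- 2^ceiling(log2(max(L, ceiling(rate_hz * (n_grid - 1) / f_max))))
  acc <- numeric(nfft %/% 2 + 1)
  for (s0 in starts) {
    seg <- signal[s0:(s0 + L - 1)] * w
    sp <- Mod(fft(c(seg, numeric(nfft - L))))^2 / scale
    half <- sp[1:(nfft %/% 2 + 1)]
    half[2:(nfft %/% 2)] <- 2 * half[2:(nfft %/% 2)]  # one-sided
    acc <- acc + half
  }
  acc <- acc / length(starts)
  freq_native <- seq(0, rate_hz / 2, length.out = nfft %/% 2 + 1)
  grid <- seq(0, f_max, length.out = n_grid)
  power <- approx(freq_native, acc, xout = grid)$y
  structure(list(freq = grid, power = power,
                 window = list(window_ms = window_ms, n_window = L,
                               overlap = overlap, n_segments = length(starts),
                               nfft = nfft, rate_hz = rate_hz)),
            class = "psd_result")
}

#' High-gamma band power with log transform
#'
#' Sums spectral power over the grid points in `[lo, hi]` Hz (band edges
#' inclusive, default 70-80) and natural-log transforms the sum for
#' statistical analysis. A non-positive band sum (degenerate all-zero input)
#' flags the log as undefined rather than returning -Inf.
#'
#' @param psd a `psd_result` from [welch_psd()].
#' @param lo,hi band edges in Hz.
#' @return list with `band_power`, `log_band_power` (NA when undefined) and
#'   `log_defined`.
#' @export
band_power_log <- function(psd, lo = 70, hi = 80) {
  stopifnot(inherits(psd, "psd_result"))
  if (lo < min(psd$freq) || hi > max(psd$freq)) {
    stop("band_power_log: band outside the frequency grid", call. = FALSE)
  }
  sel <- psd$freq >= lo & psd$freq <= hi
  bp <- sum(psd$power[sel])
  if (bp > 0) {
    list(band_power = bp, log_band_power = log(bp), log_defined = TRUE)
  } else {
    list(band_power = bp, log_band_power = NA_real_, log_defined = FALSE)
  }
}

#' Per-trial gamma power from an epoch matrix
#'
#' Convenience pipeline: analysis window, Welch PSD and 70-80 Hz band power
#' for every trial.
#'
#' @param epochs an [epoch_matrix()].
#' @param lo,hi band edges in Hz.
#' @param ... passed to [extract_analysis_window()].
#' @return data.frame with `trial`, `gamma_power`, `log_gamma_power`.
#' @export
trial_band_power <- function(epochs, lo = 70, hi = 80, ...) {
  win <- extract_analysis_window(epochs, ...)
  res <- t(apply(win$data, 1, function(x) {
    bp <- band_power_log(welch_psd(x, win$rate_hz), lo, hi)
    c(bp$band_power, bp$log_band_power)
  }))
  data.frame(trial = seq_len(nrow(res)), gamma_power = res[, 1],
             log_gamma_power = res[, 2])
}

#' Aggregate per-trial power into time bins
#'
#' Per-bin total (the convention for binned gamma power) or mean. Sum mode
#' conserves the overall total.
#'
#' @param powers per-trial values.
#' @param bins integer bin labels in 1..5.
#' @param mode `"sum"` or `"mean"`.
#' @return named numeric vector, one value per occupied bin (error if a bin
#'   in 1..max(bins) is empty).
#' @export
bin_aggregate <- function(powers, bins, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (length(powers) != length(bins)) {
    stop("bin_aggregate: powers and bins must align", call. = FALSE)
  }
  if (any(!bins %in% 1:5)) stop("bin_aggregate: bins must lie in 1..5", call. = FALSE)
  lv <- seq_len(max(bins))
  empty <- setdiff(lv, unique(bins))
  if (length(empty) > 0) {
    stop("bin_aggregate: empty bin ", paste(empty, collapse = ", "), call. = FALSE)
  }
  f <- factor(bins, levels = lv)
  out <- tapply(powers, f, if (mode == "sum") sum else mean)
  setNames(as.numeric(out), paste0("bin", lv))
}
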