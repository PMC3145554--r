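#' Stationary colored noise with a prescribed fluctuation exponent
#'
#' Synthesizes a zero-mean, unit-variance Gaussian series whose detrended
#' fluctuation analysis (DFA) exponent is approximately `alpha`: 0.5 gives
#' uncorrelated (white) noise, values below 0.5 anticorrelated noise, values
#' above 0.5 correlated noise, and 1.5 Brownian noise (integrated white
#' noise). Synthesis is by spectral shaping: white Gaussian noise is
#' filtered in the Fourier domain with a power-law amplitude
#' `f^(-beta/2)`, `beta = 2 alpha - 1`, and the DC component is removed.
#'
#' @param alpha target fluctuation exponent, in `[0.05, 2]`.
#' @param n_samples series length (>= 16).
#' @param seed integer seed; the same spec always yields the same series.
#' @param sampling_rate_hz nominal sampling frequency attached to the output
#'   (default 1 Hz; the exponent is scale-free).
#' @return A [signal()].
#' @examples
#' x <- colored_noise(0.5, 1024, seed = 1)
#' @seealso [dfa_alpha()] to recover the exponent.
#' @export
colored_noise <- function(alpha, n_samples, seed,
                          sampling_rate_hz = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0.05 || alpha > 2) {
    stop("`alpha` must lie in [0.05, 2]", call. = FALSE)
  }
  n <- as.integer(n_samples)
  if (is.na(n) || n < 16L) stop("`n_samples` must be >= 16", call. = FALSE)
  beta <- 2 * alpha - 1
  x <- withr::with_seed(as.integer(seed), {
    w <- stats::rnorm(n)
    # frequencies of the DFT bins, folded to [0, 1/2]
    k <- 0:(n - 1)
    f <- pmin(k, n - k) / n
    gain <- c(0, f[-1]^(-beta / 2))  # DC removed
    Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
  })
  x <- (x - mean(x)) / stats::sd(x)
  signal(x, sampling_rate_hz,
         label = sprintf("colored noise alpha=%g seed=%d", alpha, as.integer(seed)))
}

#' Linear chirp
#'
#' The sampled signal `x(t_k) = sin(a t_k^2 + b t_k)` with `t_k = k dt`: a
#' sinusoid whose instantaneous angular frequency `2 a t + b` grows linearly
#' with time. For the sine chirp each falling arm is shorter than the rising
#' arm preceding it, so the symbol-0 and symbol-1 seq-spectra differ - the
#' hallmark of a regularly accelerating oscillation.
#'
#' The default duration (`n_samples = 10001`, i.e. `t` in `[0, 10]` s at
#' `dt = 0.001`) keeps the instantaneous frequency low enough that every
#' half-wave is hundreds of samples long and essentially no two half-waves
#' share a length; in that regime each occupancy equals `N / I` and the
#' spectrum is linear in `N`.
#'
#' @param a quadratic-phase coefficient (rad/s^2); default 1.
#' @param b linear-phase coefficient (rad/s); default 0. With `a = 0` the
#'   chirp degenerates to a pure sinusoid of angular frequency `b`.
#' @param dt positive time step in seconds; default 0.001.
#' @param n_samples series length; default 10001.
#' @return A [signal()] with sampling rate `1/dt`.
#' @examples
#' ch <- linear_chirp()
#' @export
linear_chirp <- function(a = 1, b = 0, dt = 0.001, n_samples = 10001L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(c(a, b)))) stop("`a` and `b` must be finite", call. = FALSE)
  n <- as.integer(n_samples)
  if (is.na(n) || n < 2L) stop("`n_samples` must be >= 2", call. = FALSE)
  t <- (0:(n - 1)) * dt
  signal(sin(a * t^2 + b * t), 1 / dt,
         label = sprintf("linear chirp a=%g b=%g dt=%g", a, b, dt))
}

#' Sum of harmonics
#'
#' Deterministic multi-periodic signal `sum_j A_j sin(2 pi f_j t)`. The
#' default reproduces the reference five-harmonic construction: equal unit
#' amplitudes at 5, 8, 9, 12 and 13 Hz, sampled at 128 Hz.
#'
#' @param frequencies_hz positive frequencies, all below Nyquist.
#' @param amplitudes positive amplitudes, same length as `frequencies_hz`.
#' @param sampling_rate_hz sampling frequency in Hz; default 128.
#' @param duration_s duration in seconds; default 60.
#' @return A [signal()].
#' @examples
#' h <- harmonic_sum()
#' @export
harmonic_sum <- function(frequencies_hz = c(5, 8, 9, 12, 13),
                         amplitudes = rep(1, length(frequencies_hz)),
                         sampling_rate_hz = 128, duration_s = 60) {
  if (length(frequencies_hz) != length(amplitudes)) {
    stop("`frequencies_hz` and `amplitudes` must have the same length",
         call. = FALSE)
  }
  if (any(frequencies_hz <= 0) || any(amplitudes < 0)) {
    stop("frequencies must be positive and amplitudes non-negative",
         call. = FALSE)
  }
  if (any(frequencies_hz >= sampling_rate_hz / 2)) {
    stop("all frequencies must be below the Nyquist frequency ",
         sampling_rate_hz / 2, " Hz", call. = FALSE)
  }
  n <- as.integer(round(sampling_rate_hz * duration_s))
  t <- (0:(n - 1)) / sampling_rate_hz
  x <- rep(0, n)
  for (j in seq_along(frequencies_hz)) {
    x <- x + amplitudes[j] * sin(2 * pi * frequencies_hz[j] * t)
  }
  signal(x, sampling_rate_hz,
         label = sprintf("harmonics [%s] Hz",
                         paste(frequencies_hz, collapse = ", ")))
}

#' Contaminate a signal with Gaussian noise at a given SNR
#'
#' Adds iid Gaussian noise scaled so that the signal-to-noise ratio,
#' defined as the variance ratio in decibels
#' `10 log10(var(signal) / var(noise))`, equals `snr_db`. `snr_db = Inf`
#' returns the signal unchanged.
#'
#' @param x a [signal()]; must not be constant.
#' @param snr_db target SNR in dB (may be `Inf` for no noise).
#' @param seed integer seed for the noise draw.
#' @return A [signal()] of the same length and rate.
#' @examples
#' noisy <- add_noise_snr(harmonic_sum(), 10, seed = 1)
#' @export
add_noise_snr <- function(x, snr_db, seed) {
  if (!inherits(x, "seq_signal")) stop("`x` must be a seq_signal", call. = FALSE)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    stop("`snr_db` must be a single number (possibly Inf)", call. = FALSE)
  }
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  v <- stats::var(x$samples)
  if (v == 0) {
    stop("signal is constant (zero variance); SNR is undefined", call. = FALSE)
  }
  sd_noise <- sqrt(v / 10^(snr_db / 10))
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(x$samples), sd = sd_noise))
  signal(x$samples + noise, x$sampling_rate_hz,
         label = sprintf("%s + noise %g dB", x$label, snr_db))
}

#' Remove every second section of random length
#'
#' Emulates a simple nonstationarity: the series is partitioned into
#' consecutive sections with iid uniform integer lengths in
#' `[min_len, max_len]`, every second section (the 2nd, 4th, ...) is
#' discarded, and the kept sections are concatenated. The splices destroy
#' the Fourier line spectrum of a periodic input while leaving its
#' monotone-interval structure largely intact.
#'
#' @param x a [signal()].
#' @param min_len,max_len section length bounds in samples,
#'   `1 <= min_len <= max_len`; defaults 50 and 500.
#' @param seed integer seed for the section lengths.
#' @return A [signal()] (shorter than the input whenever at least two
#'   sections fit).
#' @examples
#' cut <- remove_random_sections(harmonic_sum(), seed = 1)
#' @export
remove_random_sections <- function(x, min_len = 50L, max_len = 500L, seed) {
  if (!inherits(x, "seq_signal")) stop("`x` must be a seq_signal", call. = FALSE)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len < 1L || max_len < min_len) {
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  }
  n <- length(x$samples)
  if (min_len > n) {
    stop("`min_len` (", min_len, ") exceeds the signal length (", n, ")",
         call. = FALSE)
  }
  lens <- withr::with_seed(as.integer(seed), {
    out <- integer(0)
    total <- 0L
    while (total < n) {
      l <- as.integer(sample.int(max_len - min_len + 1L, 1L)) + min_len - 1L
      out <- c(out, l)
      total <- total + l
    }
    out
  })
  # truncate the last section at the end of the signal
  ends <- pmin(cumsum(lens), n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- which(seq_along(lens) %% 2L == 1L & starts <= n)
  kept <- unlist(lapply(keep, function(i) x$samples[starts[i]:ends[i]]))
  signal(kept, x$sampling_rate_hz,
         label = sprintf("%s, odd sections of %d-%d", x$label, min_len, max_len))
}

#' Logistic-map trajectory
#'
#' Iterates the logistic map `x[k+1] = r x[k] (1 - x[k])`, discards an
#' initial transient, and returns the remainder as a signal with nominal
#' sampling rate 1. At `r=4` the map is fully chaotic; a descending step
#' requires `x > 1 - 1/r`, and at `r=4` the map sends `(3/4, 1)` into
#' `(0, 3/4)`, so descents can never chain - all symbol-0 mono-sequences
#' have length 1 while the symbol-1 spectrum is much wider.
#'
#' @param r map parameter in `(0, 4]`; default 4.
#' @param x0 initial value in `(0, 1)`; default 0.3.
#' @param n_samples number of returned samples; default 10000.
#' @param transient_discard iterations dropped before recording; default 100.
#' @return A [signal()].
#' @examples
#' lg <- logistic_series()
#' @export
logistic_series <- function(r = 4, x0 = 0.3, n_samples = 10000L,
                            transient_discard = 100L) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0 || r > 4) {
    stop("`r` must lie in (0, 4]", call. = FALSE)
  }
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) ||
      x0 <= 0 || x0 >= 1) {
    stop("`x0` must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- as.integer(n_samples)
  burn <- as.integer(transient_discard)
  if (is.na(n) || n < 2L) stop("`n_samples` must be >= 2", call. = FALSE)
  if (is.na(burn) || burn < 0L) stop("`transient_discard` must be >= 0", call. = FALSE)
  total <- n + burn
  x <- numeric(total)
  x[1] <- x0
  for (k in seq_len(total - 1L)) {
    x[k + 1L] <- r * x[k] * (1 - x[k])
  }
  signal(x[(burn + 1L):total], 1,
         label = sprintf("logistic map r=%g x0=%g", r, x0))
}

#' Dominant periodogram frequencies
#'
#' Returns the frequencies of the `n_peaks` strongest local maxima of the
#' raw periodogram (mean removed, no taper). Used to check whether the
#' Fourier line spectrum of a multi-periodic signal survives a manipulation
#' such as [remove_random_sections()].
#'
#' @param x a [signal()].
#' @param n_peaks number of peaks to return; default 5.
#' @return Numeric vector of peak frequencies in Hz, sorted ascending.
#' @examples
#' dominant_frequencies(harmonic_sum())  # 5 8 9 12 13
#' @export
dominant_frequencies <- function(x, n_peaks = 5L) {
  if (!inherits(x, "seq_signal")) stop("`x` must be a seq_signal", call. = FALSE)
  s <- x$samples - mean(x$samples)
  n <- length(s)
  p <- Mod(stats::fft(s))^2
  half <- 2:(floor(n / 2))  # skip DC, stay below Nyquist
  p <- p[half]
  freqs <- (half - 1) * x$sampling_rate_hz / n
  # local maxima of the periodogram: interior bins above both neighbours
  interior <- 2:(length(p) - 1)
  is_peak <- rep(FALSE, length(p))
  is_peak[interior] <- p[interior] > p[interior - 1] & p[interior] > p[interior + 1]
  idx <- which(is_peak)
  if (length(idx) == 0L) idx <- order(p, decreasing = TRUE)[seq_len(min(n_peaks, length(p)))]
  top <- idx[order(p[idx], decreasing = TRUE)][seq_len(min(n_peaks, length(idx)))]
  sort(freqs[top])
}
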