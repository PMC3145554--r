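#' Binary occupancy: the sequential spectrum of a run-count distribution
#'
#' The binary occupancy of the mono-sequence class `[N x s]` is the fraction
#' of the symbol series that those runs occupy,
#' \deqn{O[N \times s] = N \, L[N \times s] / I,}
#' where `I` is the symbol-series length. Because maximal runs partition the
#' series, occupancies sum exactly to 1 over all `(N, s)`, which makes
#' spectra of different recordings directly comparable and differences
#' between them (relative spectra) scale-free.
#'
#' @param counts a `mono_counts` object from [extract_mono_sequences()].
#' @param sampling_rate_hz optional sampling frequency; when supplied every
#'   length `N` is annotated with its related frequency `f_s / (2 N)`.
#' @param label free-text label stored on the spectrum.
#' @return A data frame of class `seq_spectrum` with columns `symbol`,
#'   `length`, `count`, `occupancy` and (if a rate is known) `frequency_hz`,
#'   ordered by symbol then length; attributes `source_length_I`,
#'   `sampling_rate_hz`, `label`.
#' @examples
#' p <- encode_signal(c(0, 1, 2, 1, 0, 1))
#' binary_occupancy(extract_mono_sequences(p))
#' @export
binary_occupancy <- function(counts, sampling_rate_hz = NULL, label = "") {
  if (!inherits(counts, "mono_counts")) {
    stop("`counts` must be a mono_counts object", call. = FALSE)
  }
  I <- counts$source_length_I
  if (is.null(I) || I <= 0L) {
    stop("source symbol series has length 0; occupancy is undefined",
         call. = FALSE)
  }
  tab <- counts$table
  tab$occupancy <- tab$length * tab$count / I
  if (!is.null(sampling_rate_hz)) {
    tab$frequency_hz <- length_to_frequency(tab$length, sampling_rate_hz)
  }
  structure(
    tab,
    source_length_I = I,
    sampling_rate_hz = if (is.null(sampling_rate_hz)) NA_real_ else as.numeric(sampling_rate_hz),
    label = as.character(label)[1L],
    class = c("seq_spectrum", "data.frame")
  )
}

#' Sequential spectrum of a signal
#'
#' Convenience wrapper running the full chain
#' encode -> count maximal runs -> binary occupancy.
#'
#' @inheritParams encode_signal
#' @return A `seq_spectrum` data frame (see [binary_occupancy()]). When `x`
#'   is a [signal()], its sampling rate and label are carried over.
#' @examples
#' seq_spectrum(signal(sin(2 * pi * 5 * (0:511) / 128), 128, "5 Hz"))
#' @export
seq_spectrum <- function(x, epsilon = 0) {
  fs <- if (inherits(x, "seq_signal")) x$sampling_rate_hz else NULL
  lab <- if (inherits(x, "seq_signal")) x$label else ""
  binary_occupancy(
    extract_mono_sequences(encode_signal(x, epsilon = epsilon)),
    sampling_rate_hz = fs, label = lab
  )
}

#' @export
print.seq_spectrum <- function(x, ...) {
  fs <- attr(x, "sampling_rate_hz")
  cat(sprintf("<seq_spectrum> %s  (I = %d%s)\n",
              if (nzchar(attr(x, "label"))) attr(x, "label") else "(unlabelled)",
              attr(x, "source_length_I"),
              if (is.finite(fs)) sprintf(", fs = %g Hz", fs) else ""))
  print(as.data.frame(x))
  invisible(x)
}

#' Frequency related to a mono-sequence length
#'
#' A mono-sequence of length `N` corresponds to a half-wave (one monotone
#' arm) of an oscillation, so at sampling frequency `f_s` its related
#' frequency is `f = f_s / (2 N)`. `N = 1` maps to the Nyquist frequency;
#' the mapping is strictly decreasing in `N`.
#'
#' @param N positive integer length(s).
#' @param sampling_rate_hz positive sampling frequency in Hz.
#' @return Frequency in Hz, vectorized over `N`.
#' @examples
#' length_to_frequency(16, 128)  # 4 Hz
#' @export
length_to_frequency <- function(N, sampling_rate_hz) {
  if (length(N) == 0L || any(!is.finite(N)) || any(N < 1)) {
    stop("`N` must contain positive integers (>= 1)", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number", call. = FALSE)
  }
  sampling_rate_hz / (2 * N)
}

# occupancy of one symbol as a named vector indexed by length
occupancy_by_length <- function(spectrum, sym) {
  rows <- spectrum[spectrum$symbol == sym & spectrum$occupancy > 0, , drop = FALSE]
  stats::setNames(rows$occupancy, rows$length)
}

# align two length-indexed occupancy vectors on the union support (zero fill)
align_lengths <- function(a, b) {
  lens <- sort(unique(as.integer(c(names(a), names(b)))))
  key <- as.character(lens)
  pick <- function(v) {
    out <- rep(0, length(lens))
    out[match(names(v), key)] <- v
    out
  }
  list(length = lens, a = pick(a), b = pick(b))
}

#' Relative sequential spectrum between a state and a reference
#'
#' Per-length difference of two seq-spectra,
#' `delta[N x s] = O_state[N x s] - O_reference[N x s]`, with the two
#' supports aligned by zero-padding (an absent run length means zero
#' occupancy). The reference state against itself is identically zero - the
#' flat baseline against which other states are read. Summed over both
#' symbols the deltas cancel exactly, since both spectra sum to 1.
#'
#' @param state,reference `seq_spectrum` objects.
#' @param symbol which symbol block(s) to difference: `"both"` (default),
#'   `"0"`/`0` or `"1"`/`1`. A symbol absent from both spectra yields an
#'   empty result with a warning.
#' @return A data frame of class `rel_seq_spectrum` with columns `symbol`,
#'   `length`, `delta`; attributes `state_label`, `reference_label`.
#' @examples
#' a <- seq_spectrum(signal(cumsum(rnorm(500)), 100, "state"))
#' b <- seq_spectrum(signal(rnorm(500), 100, "reference"))
#' head(relative_seq_spectrum(a, b))
#' @export
relative_seq_spectrum <- function(state, reference, symbol = "both") {
  for (sp in list(state, reference)) {
    if (!inherits(sp, "seq_spectrum")) {
      stop("`state` and `reference` must be seq_spectrum objects", call. = FALSE)
    }
  }
  symbol <- as.character(symbol)
  symbol <- match.arg(symbol, c("both", "0", "1"))
  wanted <- if (symbol == "both") c(0L, 1L) else as.integer(symbol)

  blocks <- lapply(wanted, function(s) {
    al <- align_lengths(occupancy_by_length(state, s),
                        occupancy_by_length(reference, s))
    if (length(al$length) == 0L) return(NULL)
    data.frame(symbol = s, length = al$length, delta = al$a - al$b)
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) == 0L) {
    warning("requested symbol absent from both spectra; empty relative spectrum")
    out <- data.frame(symbol = integer(0), length = integer(0),
                      delta = numeric(0))
  } else {
    out <- do.call(rbind, blocks)
  }
  rownames(out) <- NULL
  structure(
    out,
    state_label = attr(state, "label"),
    reference_label = attr(reference, "label"),
    class = c("rel_seq_spectrum", "data.frame")
  )
}

#' @export
print.rel_seq_spectrum <- function(x, ...) {
  cat(sprintf("<rel_seq_spectrum> %s relative to %s\n",
              attr(x, "state_label"), attr(x, "reference_label")))
  print(as.data.frame(x))
  invisible(x)
}

#' Congruity between the symbol-0 and symbol-1 spectra
#'
#' Stationary random signals show near-identical seq-spectra for decreasing
#' (`s = 0`) and increasing (`s = 1`) mono-sequences, while chirps, chaotic
#' maps and signals with constant epochs break that symmetry. This index
#' quantifies the congruity as one minus the total-variation distance
#' between the two per-symbol spectra, each renormalized to unit sum over
#' `N` and aligned by zero-padding:
#' \deqn{S = 1 - \tfrac{1}{2} \sum_N |\tilde O_0[N] - \tilde O_1[N]|.}
#' `S = 1` iff the restrictions coincide, `S = 0` iff their supports are
#' disjoint.
#'
#' @param spectrum a `seq_spectrum` containing both symbols, or the symbol-0
#'   spectrum when `spectrum1` is given.
#' @param spectrum1 optional second `seq_spectrum`; its symbol-1 block is
#'   compared against the symbol-0 block of `spectrum`.
#' @return A number in `[0, 1]`.
#' @examples
#' symmetry_index(seq_spectrum(signal(rnorm(5000), 100)))  # close to 1
#' @export
symmetry_index <- function(spectrum, spectrum1 = NULL) {
  if (!inherits(spectrum, "seq_spectrum")) {
    stop("`spectrum` must be a seq_spectrum object", call. = FALSE)
  }
  o0 <- occupancy_by_length(spectrum, 0L)
  o1 <- occupancy_by_length(if (is.null(spectrum1)) spectrum else spectrum1, 1L)
  if (length(o0) == 0L || length(o1) == 0L) {
    stop("both symbol restrictions must be non-empty", call. = FALSE)
  }
  o0 <- o0 / sum(o0)
  o1 <- o1 / sum(o1)
  al <- align_lengths(o0, o1)
  1 - 0.5 * sum(abs(al$a - al$b))
}

#' Windowed sequential spectrogram
#'
#' Time-resolved extension of the seq-spectrum, after the fashion of
#' time-frequency methods: the encode -> count -> occupancy chain is applied
#' to sliding windows of the signal. A trailing window that would not fit
#' entirely inside the signal is dropped.
#'
#' @param x a [signal()] object.
#' @param window_length_samples window length in samples (>= 2); default 512.
#' @param step_samples hop between window starts (>= 1); default 256, i.e.
#'   50 percent overlap.
#' @param epsilon tie tolerance passed to [encode_signal()].
#' @return An object of class `seq_spectrogram`: a list with the windowing
#'   parameters and `frames`, an ordered list of `(start, spectrum)` pairs
#'   (1-based window start index, `seq_spectrum`). Use `as.data.frame()` for
#'   a long table `(frame_start, symbol, length, occupancy)`.
#' @examples
#' x <- signal(sin(2 * pi * 3 * (0:2047) / 128), 128)
#' sg <- compute_spectrogram(x, 512, 256)
#' head(as.data.frame(sg))
#' @export
compute_spectrogram <- function(x, window_length_samples = 512L,
                                step_samples = 256L, epsilon = 0) {
  if (!inherits(x, "seq_signal")) {
    stop("`x` must be a seq_signal object", call. = FALSE)
  }
  w <- as.integer(window_length_samples)
  step <- as.integer(step_samples)
  n <- length(x$samples)
  if (is.na(w) || w < 2L) stop("`window_length_samples` must be >= 2", call. = FALSE)
  if (is.na(step) || step < 1L) stop("`step_samples` must be >= 1", call. = FALSE)
  if (w > n) {
    stop("window (", w, " samples) is longer than the signal (", n, ")",
         call. = FALSE)
  }
  starts <- seq.int(1L, n - w + 1L, by = step)
  frames <- lapply(starts, function(s0) {
    chunk <- x$samples[s0:(s0 + w - 1L)]
    sp <- binary_occupancy(
      extract_mono_sequences(encode_signal(chunk, epsilon = epsilon)),
      sampling_rate_hz = x$sampling_rate_hz,
      label = sprintf("%s[%d:%d]", x$label, s0, s0 + w - 1L)
    )
    list(start = s0, spectrum = sp)
  })
  structure(
    list(window_length_samples = w, step_samples = step, frames = frames),
    class = "seq_spectrogram"
  )
}

#' @export
print.seq_spectrogram <- function(x, ...) {
  cat(sprintf("<seq_spectrogram> %d frames, window %d samples, step %d\n",
              length(x$frames), x$window_length_samples, x$step_samples))
  invisible(x)
}

#' @export
as.data.frame.seq_spectrogram <- function(x, ...) {
  out <- do.call(rbind, lapply(x$frames, function(fr) {
    data.frame(
      frame_start = fr$start,
      symbol = fr$spectrum$symbol,
      length = fr$spectrum$length,
      occupancy = fr$spectrum$occupancy
    )
  }))
  rownames(out) <- NULL
  out
}
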