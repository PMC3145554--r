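#' Construct a sampled signal
#'
#' A `seq_signal` is the raw input of the method: an ordered series of finite
#' real samples together with its sampling frequency. The sampling frequency
#' is what later maps a mono-sequence length \eqn{N} to a frequency
#' \eqn{f_s/(2N)}; it is therefore required up front.
#'
#' @param samples numeric vector of finite values, length at least 2.
#' @param sampling_rate_hz positive sampling frequency in Hz.
#' @param label free-text identifier carried through to spectra.
#' @return An object of class `seq_signal` with fields `samples`,
#'   `sampling_rate_hz` and `label`.
#' @examples
#' s <- signal(sin(2 * pi * 4 * (0:127) / 128), 128, "4 Hz tone")
#' s
#' @export
signal <- function(samples, sampling_rate_hz, label = "") {
  samples <- validate_samples(samples)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      label = as.character(label)[1L]
    ),
    class = "seq_signal"
  )
}

# shared validation: >= 2 finite samples, report the first offending index
validate_samples <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a signal needs at least 2 samples (got ", length(samples), ")",
         call. = FALSE)
  }
  bad <- which(!is.finite(samples))
  if (length(bad) > 0L) {
    stop("non-finite sample at index ", bad[1L], call. = FALSE)
  }
  samples
}

#' @export
print.seq_signal <- function(x, ...) {
  cat(sprintf("<seq_signal> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d samples at %g Hz (%.6g s)\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  cat(sprintf("  range [%.6g, %.6g]\n", min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.seq_signal <- function(x) length(x$samples)

#' @export
as.data.frame.seq_signal <- function(x, ...) {
  data.frame(
    time_s = (seq_along(x$samples) - 1) / x$sampling_rate_hz,
    value = x$samples
  )
}

# Accept either a seq_signal or a bare numeric vector where only the sample
# values matter; returns the numeric samples, validated.
signal_samples <- function(x) {
  if (inherits(x, "seq_signal")) x$samples else validate_samples(x)
}
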