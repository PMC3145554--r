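#' Detrended fluctuation analysis exponent
#'
#' First-order DFA: the series is integrated into a profile, the profile is
#' split into non-overlapping boxes of size `s` (scanned from both ends so
#' no tail is wasted), a least-squares line is removed in every box, and the
#' root-mean-square residual `F(s)` is recorded. The fluctuation exponent
#' `alpha` is the slope of `log F(s)` against `log s`. For white noise
#' `alpha = 0.5`; anticorrelated noise gives smaller values, correlated
#' noise larger, and Brownian noise (integrated white) `alpha = 1.5`.
#'
#' Used here to verify, independently of the spectral synthesis route, that
#' [colored_noise()] produces series with the requested exponent.
#'
#' @param x a [signal()] or numeric vector, length >= 64.
#' @param scales integer box sizes; default about 20 sizes log-spaced
#'   between 8 and `n/8`.
#' @return The estimated exponent (single number).
#' @examples
#' dfa_alpha(rnorm(4096))          # about 0.5
#' dfa_alpha(cumsum(rnorm(4096)))  # about 1.5
#' @export
dfa_alpha <- function(x, scales = NULL) {
  s <- signal_samples(x)
  n <- length(s)
  if (n < 64L) stop("DFA needs at least 64 samples", call. = FALSE)
  if (is.null(scales)) {
    scales <- unique(round(exp(seq(log(8), log(n / 8), length.out = 20))))
  }
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 4L) || any(scales > n / 2)) {
    stop("scales must lie in [4, n/2]", call. = FALSE)
  }
  profile <- cumsum(s - mean(s))
  fluct <- vapply(scales, function(sc) {
    nb <- n %/% sc
    used <- nb * sc
    # forward and backward segmentations, per standard practice
    segs <- list(profile[seq_len(used)], profile[(n - used + 1L):n])
    ss <- 0
    for (seg in segs) {
      m <- matrix(seg, nrow = sc)
      t <- seq_len(sc)
      tc <- t - mean(t)
      denom <- sum(tc^2)
      slope <- colSums(m * tc) / denom
      inter <- colMeans(m)
      resid <- m - outer(tc, slope) - matrix(inter, sc, nb, byrow = TRUE)
      ss <- ss + sum(resid^2)
    }
    sqrt(ss / (2 * used))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(fluct) ~ log(scales)))[2])
}
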