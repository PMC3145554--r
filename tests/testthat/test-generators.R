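test_that("all generators are seed-deterministic and emit valid signals", {
  pairs <- list(
    list(colored_noise(0.8, 1024, seed = 3), colored_noise(0.8, 1024, seed = 3)),
    list(add_noise_snr(harmonic_sum(duration_s = 2), 5, seed = 4),
         add_noise_snr(harmonic_sum(duration_s = 2), 5, seed = 4)),
    list(remove_random_sections(harmonic_sum(duration_s = 10), seed = 5),
         remove_random_sections(harmonic_sum(duration_s = 10), seed = 5))
  )
  for (p in pairs) {
    expect_identical(p[[1]]$samples, p[[2]]$samples)
    expect_s3_class(p[[1]], "seq_signal")
    expect_true(all(is.finite(p[[1]]$samples)))
  }
  # a different seed changes the draw
  expect_false(identical(colored_noise(0.8, 1024, seed = 3)$samples,
                         colored_noise(0.8, 1024, seed = 4)$samples))
})

test_that("DFA estimator recovers known exponents of canonical processes", {
  set.seed(1)
  expect_lt(abs(dfa_alpha(rnorm(2^14)) - 0.5), 0.1)
  expect_lt(abs(dfa_alpha(cumsum(rnorm(2^14))) - 1.5), 0.1)
})

test_that("colored noise carries the requested fluctuation exponent", {
  expect_lt(abs(dfa_alpha(colored_noise(0.5, 2^16, seed = 1)) - 0.5), 0.1)
  expect_lt(abs(dfa_alpha(colored_noise(1.5, 2^16, seed = 1)) - 1.5), 0.1)
  expect_error(colored_noise(2.5, 1024, seed = 1), "0.05")
  expect_error(colored_noise(0.5, 8, seed = 1), ">= 16")
})

test_that("the degenerate chirp a = 0 is a pure sinusoid", {
  b <- 2 * pi * 3
  ch <- linear_chirp(a = 0, b = b, dt = 0.001, n_samples = 2000)
  t <- (0:1999) * 0.001
  expect_equal(ch$samples, sin(b * t))
  expect_equal(ch$sampling_rate_hz, 1000)
  expect_error(linear_chirp(dt = 0), "positive")
})

test_that("chirp run lengths shrink as the instantaneous frequency grows", {
  # t in [0, 100] at dt = 0.001; integer run lengths may tick up by one
  # sample from phase quantization, never more
  ch <- linear_chirp(n_samples = 100001L)
  mc <- extract_mono_sequences(encode_signal(ch))
  r1 <- mc$runs$length[mc$runs$symbol == 1]
  d <- diff(r1[-1])  # past the first full cycle
  expect_true(all(d <= 1))
  expect_gt(mean(d <= 0), 0.8)
  # long-range decrease is strict and large
  expect_gt(r1[2], 10 * r1[length(r1)])
})

test_that("chirp occupancy grows linearly with run length at defaults", {
  sp <- seq_spectrum(linear_chirp())
  s1 <- sp[sp$symbol == 1, ]
  # the fit can be numerically perfect, which lm's summary warns about
  fit <- suppressWarnings(summary(stats::lm(occupancy ~ length, data = s1)))
  expect_gte(fit$r.squared, 0.9)
})

test_that("a single sampled harmonic has half-wave runs within one sample", {
  # fs/(2f) = 16 samples per monotone arm
  h <- harmonic_sum(frequencies_hz = 4, amplitudes = 1,
                    sampling_rate_hz = 128, duration_s = 30)
  mc <- extract_mono_sequences(encode_signal(h))
  interior <- mc$runs$length[-c(1, nrow(mc$runs))]
  expect_true(all(interior %in% 15:17))
})

test_that("the five-harmonic signal shows exactly its five Fourier lines", {
  expect_equal(dominant_frequencies(harmonic_sum()), c(5, 8, 9, 12, 13),
               tolerance = 1e-8)
  expect_error(harmonic_sum(frequencies_hz = c(5, 70)), "Nyquist")
  expect_error(harmonic_sum(frequencies_hz = c(5, 8), amplitudes = 1),
               "same length")
})

test_that("zero-amplitude harmonics give a constant, all-1-encoded signal", {
  h <- harmonic_sum(frequencies_hz = c(5, 8), amplitudes = c(0, 0),
                    sampling_rate_hz = 128, duration_s = 1)
  expect_true(all(unclass(encode_signal(h)) == 1L))
})

test_that("SNR contamination hits the requested variance ratio", {
  h <- signal(sin(2 * pi * 5 * (0:99999) / 1000), 1000)
  expect_identical(add_noise_snr(h, Inf, seed = 1)$samples, h$samples)
  noisy <- add_noise_snr(h, 0, seed = 8)
  noise_var <- stats::var(noisy$samples - h$samples)
  expect_equal(noise_var / stats::var(h$samples), 1, tolerance = 0.01)
  expect_error(add_noise_snr(signal(rep(1, 100), 10), 0, seed = 1), "constant")
})

test_that("short-run occupancy grows monotonically with noise amplitude", {
  h <- harmonic_sum(duration_s = 30)
  o1 <- vapply(c(20, 10, 0), function(snr) {
    mean(vapply(1:10, function(s) {
      sp <- seq_spectrum(add_noise_snr(h, snr, seed = s))
      sum(sp$occupancy[sp$length == 1])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(o1) > 0))
})

test_that("fixed-length section removal keeps exactly the odd sections", {
  x <- signal(as.numeric(1:400), 10)
  out <- remove_random_sections(x, min_len = 50, max_len = 50, seed = 1)
  expect_equal(out$samples,
               as.numeric(c(1:50, 101:150, 201:250, 301:350)))
})

test_that("section removal contracts the series and preserves sample order", {
  h <- harmonic_sum(duration_s = 20)
  cut <- remove_random_sections(h, seed = 9)
  expect_lt(length(cut$samples), length(h$samples))
  # every kept sample occurs in the input in order (subsequence check)
  idx <- 0L
  ok <- TRUE
  pool <- h$samples
  for (v in cut$samples) {
    nxt <- which(pool[(idx + 1L):length(pool)] == v)[1L]
    if (is.na(nxt)) { ok <- FALSE; break }
    idx <- idx + nxt
  }
  expect_true(ok)
  expect_error(remove_random_sections(h, min_len = 1e6, max_len = 1e6, seed = 1),
               "exceeds")
})

test_that("logistic map iterates exactly and honors its parameter regimes", {
  lg <- logistic_series(r = 4, x0 = 0.3, n_samples = 3, transient_discard = 0)
  expect_equal(lg$samples[1:2], c(0.3, 0.84))
  # stable fixed point 1 - 1/r at r = 2
  fix <- logistic_series(r = 2, x0 = 0.11, n_samples = 50, transient_discard = 200)
  expect_equal(fix$samples, rep(0.5, 50), tolerance = 1e-12)
  expect_error(logistic_series(x0 = 0), "x0")
  expect_error(logistic_series(r = 5), "r")
})

test_that("chaotic logistic descents never chain while ascents do", {
  sp <- seq_spectrum(logistic_series(r = 4, x0 = 0.3, n_samples = 1e4,
                                     transient_discard = 100))
  s0 <- sp$length[sp$symbol == 0]
  s1 <- sp$length[sp$symbol == 1]
  expect_lte(length(s0), 2L)       # at most lengths 1 and 2 appear
  expect_lte(max(s0), 2L)
  expect_gt(max(s1), max(s0))      # symbol-1 support strictly wider
})
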