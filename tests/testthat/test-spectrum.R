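test_that("binary occupancy matches N*L/I on the worked series and sums to 1", {
  sp <- binary_occupancy(extract_mono_sequences(worked_series()))
  expect_equal(occupancy_of(sp, 1, 3), 6 / 33)
  expect_equal(occupancy_of(sp, 0, 8), 8 / 33)
  expect_equal(sum(sp$occupancy), 1, tolerance = 1e-14)
  expect_true(all(sp$occupancy > 0 & sp$occupancy <= 1))
})

test_that("a single-run series has occupancy 1 at its full length", {
  sp <- binary_occupancy(extract_mono_sequences(
    structure(c(1L, 1L, 1L), class = "symbol_series")))
  expect_equal(nrow(sp), 1L)
  expect_equal(occupancy_of(sp, 1, 3), 1)
})

test_that("occupancies of random series always sum to one with support <= I", {
  set.seed(123)
  for (rep_i in 1:100) {
    p <- random_symbol_series(sample(2:500, 1))
    sp <- binary_occupancy(extract_mono_sequences(p))
    expect_lt(abs(sum(sp$occupancy) - 1), 1e-12)
    expect_lte(max(sp$length), attr(sp, "source_length_I"))
  }
})

test_that("mono-sequence length maps to the half-wave frequency", {
  expect_equal(length_to_frequency(16, 128), 4)
  expect_equal(length_to_frequency(1, 128), 64)  # Nyquist
  k <- c(1, 3, 10)
  expect_equal(length_to_frequency(2 * k, 500), length_to_frequency(k, 500) / 2)
  expect_error(length_to_frequency(0, 128), "positive")
  expect_error(length_to_frequency(4, -1), "positive")
  # cross-check against an actual sampled sinusoid: a 4 Hz tone at 128 Hz
  # spends 16 samples on each monotone arm
  tone <- signal(sin(2 * pi * 4 * (0:4095) / 128), 128)
  mc <- extract_mono_sequences(encode_signal(tone))
  interior <- mc$runs$length[-c(1, nrow(mc$runs))]
  expect_true(all(abs(interior - 16) <= 1))
  expect_equal(length_to_frequency(round(mean(interior)), 128), 4)
})

test_that("relative spectrum of a state against itself is identically zero", {
  x <- signal(rnorm(1000), 100, "A")
  rel <- relative_seq_spectrum(seq_spectrum(x), seq_spectrum(x))
  expect_true(all(rel$delta == 0))
})

test_that("unit-mass spectra difference to the forced +1/-1 pattern", {
  one0 <- binary_occupancy(extract_mono_sequences(
    structure(0L, class = "symbol_series")))
  two0 <- binary_occupancy(extract_mono_sequences(
    structure(c(0L, 0L), class = "symbol_series")))
  rel <- relative_seq_spectrum(one0, two0, symbol = "0")
  expect_equal(rel$delta[rel$length == 1], 1)
  expect_equal(rel$delta[rel$length == 2], -1)
  expect_equal(sum(rel$delta), 0)
})

test_that("relative spectra of random pairs cancel over both symbols", {
  set.seed(77)
  for (rep_i in 1:100) {
    a <- binary_occupancy(extract_mono_sequences(random_symbol_series(sample(2:400, 1))))
    b <- binary_occupancy(extract_mono_sequences(random_symbol_series(sample(2:400, 1))))
    rel <- relative_seq_spectrum(a, b)
    expect_lt(abs(sum(rel$delta)), 1e-12)
  }
})

test_that("a symbol absent from both spectra warns and returns empty", {
  ones <- binary_occupancy(extract_mono_sequences(
    structure(c(1L, 1L), class = "symbol_series")))
  expect_warning(rel <- relative_seq_spectrum(ones, ones, symbol = "0"),
                 "absent")
  expect_equal(nrow(rel), 0L)
})

test_that("symmetry index is 1 for identical restrictions, 0 for disjoint ones", {
  alt <- binary_occupancy(extract_mono_sequences(
    structure(rep(c(0L, 1L), 20), class = "symbol_series")))
  expect_equal(symmetry_index(alt), 1)
  # 0-runs only at N = 1, 1-runs only at N = 5: disjoint supports
  skew <- binary_occupancy(extract_mono_sequences(
    structure(rep(c(1L, 1L, 1L, 1L, 1L, 0L), 10), class = "symbol_series")))
  expect_equal(symmetry_index(skew), 0)
  ones <- binary_occupancy(extract_mono_sequences(
    structure(c(1L, 1L), class = "symbol_series")))
  expect_error(symmetry_index(ones), "non-empty")
})

test_that("iid Gaussian noise has highly congruent symbol-0/1 spectra", {
  x <- colored_noise(0.5, 1e5, seed = 2026)
  expect_gte(symmetry_index(seq_spectrum(x)), 0.95)
})

test_that("spectrogram frames are unit-sum and cover the signal on a grid", {
  x <- signal(rnorm(3000), 100, "grid")
  sg <- compute_spectrogram(x, 512, 256)
  starts <- vapply(sg$frames, `[[`, numeric(1), "start")
  expect_equal(starts, seq(1, 3000 - 512 + 1, by = 256))
  for (fr in sg$frames) {
    expect_lt(abs(sum(fr$spectrum$occupancy) - 1), 1e-12)
  }
  # non-overlapping tiling gives floor(n / W) frames
  sg2 <- compute_spectrogram(x, 500, 500)
  expect_length(sg2$frames, 6L)
  expect_error(compute_spectrogram(x, 5000, 100), "longer than the signal")
})

test_that("every frame of a constant signal is one full-window 1-run", {
  x <- signal(rep(3.5, 1000), 10, "flat")
  sg <- compute_spectrogram(x, 100, 50)
  for (fr in sg$frames) {
    expect_equal(occupancy_of(fr$spectrum, 1, 99), 1)
  }
})

test_that("spectrogram tracks a slow-to-fast frequency switch", {
  fs <- 100
  t <- (0:1999) / fs
  slow_then_fast <- signal(c(sin(2 * pi * 1 * t), sin(2 * pi * 20 * t)), fs)
  sg <- compute_spectrogram(slow_then_fast, 512, 512)
  argmax_n <- vapply(sg$frames, function(fr) {
    sp <- fr$spectrum
    sp$length[which.max(sp$occupancy)]
  }, numeric(1))
  expect_gt(argmax_n[1], argmax_n[length(argmax_n)])
})
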