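test_that("gaus4 is even, zero-mean and unit-norm", {
  t <- seq(0.1, 6, by = 0.37)
  expect_equal(mother_wavelet(t), mother_wavelet(-t))
  expect_gt(mother_wavelet(0), 0)
  zm <- integrate(function(u) mother_wavelet(u), -12, 12,
                  rel.tol = 1e-10, abs.tol = 1e-12)$value
  expect_lt(abs(zm), 1e-6)
  nrm <- integrate(function(u) mother_wavelet(u)^2, -12, 12,
                   rel.tol = 1e-10)$value
  expect_lt(abs(nrm - 1), 1e-6)
  expect_error(mother_wavelet(0, "haar"), "unsupported wavelet_id")
})

test_that("optional wavelets are normalised too", {
  for (id in c("mexh", "morl")) {
    nrm <- integrate(function(u) mother_wavelet(u, id)^2, -12, 12)$value
    expect_lt(abs(nrm - 1), 1e-6)
  }
})

test_that("the transform is linear and annihilates constants", {
  x <- smooth_random_signal(200, seed = 41)
  a <- cwt_spectrum(x, c(4, 16))
  b <- cwt_spectrum(2.5 * x, c(4, 16))
  expect_equal(b, 2.5 * a)
  y <- smooth_random_signal(200, seed = 42)
  expect_equal(cwt_spectrum(x + y, 8), cwt_spectrum(x, 8) + cwt_spectrum(y, 8))
  const <- cwt_spectrum(rep(0.42, 300), c(2, 8, 32))
  expect_lt(max(abs(const)), 1e-8)
})

test_that("FFT path matches a direct-summation evaluation exactly", {
  x <- smooth_random_signal(150, seed = 43)
  for (a in c(3, 8, 17)) {
    expect_equal(drop(cwt_spectrum(x, a)), cwt_direct(x, a),
                 tolerance = 1e-12)
  }
})

test_that("coefficients match a dense quadrature oracle on interior bands", {
  n <- 400
  x <- smooth_random_signal(n, seed = 44)
  for (a in c(8, 16)) {
    b_idx <- seq(8 * a + 1, n - 8 * a, by = 7)
    mine <- drop(cwt_spectrum(x, a))[b_idx]
    oracle <- cwt_dense_quadrature(x, a, b_idx)
    rel <- sqrt(sum((mine - oracle)^2) / sum(oracle^2))
    expect_lt(rel, 0.02)
  }
})

test_that("coefficients match the independent PyWavelets-based reference", {
  n <- 500
  x <- smooth_random_signal(n, seed = 45)
  scales <- c(8, 16, 32)
  mine <- cwt_spectrum(x, scales)
  ref <- pywt_reference_cwt(x, scales)
  for (s in seq_along(scales)) {
    a <- scales[s]
    interior <- (8 * a + 1):(n - 8 * a)
    rel <- sqrt(sum((mine[s, interior] - ref[s, interior])^2) /
                  sum(ref[s, interior]^2))
    expect_lt(rel, 0.02)
  }
})

test_that("a Gaussian bump is localised at its center by the matched scale", {
  n <- 400
  center <- 187
  sigma <- 12
  x <- 0.5 - 0.2 * exp(-((seq_len(n) - center)^2) / (2 * sigma^2))
  scales <- 2^(1:7)
  w <- cwt_spectrum(x, scales)
  best <- which.max(apply(abs(w), 1, max))
  peak <- which.max(abs(w[best, ]))
  expect_lte(abs(peak - center), 2)
  # dense-quadrature oracle localises identically
  b_idx <- (center - 10):(center + 10)
  oracle <- cwt_dense_quadrature(x, scales[best], b_idx)
  expect_lte(abs(b_idx[which.max(abs(oracle))] - center), 2)
})

test_that("the transform is shift-covariant on interior bands", {
  n <- 300
  shift <- 11
  base <- 0.5 - 0.2 * exp(-((seq_len(n + shift) - 140)^2) / 128)
  a <- 8
  w1 <- drop(cwt_spectrum(base[1:n], a))
  w2 <- drop(cwt_spectrum(base[(1 + shift):(n + shift)], a))
  interior <- (8 * a + 1):(n - 8 * a - shift)
  expect_equal(w2[interior], w1[interior + shift], tolerance = 1e-10)
})

test_that("matched-scale response lifts a smooth feature above white noise", {
  # under 1/sqrt(a) normalisation the white-noise coefficient energy is
  # scale-flat, while a smooth feature's response grows toward its
  # matching scale: the signal-to-noise ratio therefore improves with
  # scale up to the match.
  n <- 600
  sigma <- 20
  sig <- -0.1 * exp(-((seq_len(n) - 300)^2) / (2 * sigma^2))
  scales <- c(2, 32)
  w_sig <- cwt_spectrum(sig, scales)
  noise_energy <- matrix(0, 2, 30)
  tanninspec:::with_seed(46, {
    for (r in 1:30) {
      w_n <- cwt_spectrum(rnorm(n, sd = 0.01), scales)
      noise_energy[, r] <- rowMeans(w_n[, 150:450]^2)
    }
  })
  snr <- apply(w_sig^2, 1, max) / rowMeans(noise_energy)
  expect_gt(snr[2], snr[1])
})

test_that("feature extraction covers the dyadic ladder and four sources", {
  ds <- generate_dataset(generator_config(n_samples = 3,
                                          replicates_per_sample = 1,
                                          n_bands = 1100, seed = 47))
  avg <- average_replicates(ds$spectra)
  wf <- cwt_features(avg)
  expect_equal(wf$scales, c(2, 4, 8, 16, 32, 64, 128, 256, 512, 1024))
  expect_length(wf$coefficients, 10)
  expect_true(all(vapply(wf$coefficients, function(m)
    all(is.finite(m)) && ncol(m) == 1100, logical(1))))

  bank <- transform_bank(avg)
  blocks <- lapply(c("R", "R'", "lg'R", "lg'(1/R)"), function(tag) {
    cwt_features(bank[[tag]], scales = c(4, 16))
  })
  expect_identical(vapply(blocks, `[[`, "", "source_tag"),
                   c("R", "R'", "lg'R", "lg'(1/R)"))
})

test_that("oversized scales and bad inputs error", {
  expect_error(cwt_spectrum(rnorm(50), 64), "exceeds signal length")
  expect_error(cwt_spectrum(rnorm(50), -2), "positive")
  expect_error(cwt_spectrum(0.5, 2), "length >= 2")
})
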