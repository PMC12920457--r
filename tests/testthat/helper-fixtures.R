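# Shared fixtures: small, fast configurations used across tests.

# Modes with no baseline offset: only tannin-coupled absorptions carry
# information, so uncoupled bands are pure noise.
modes_flat <- function() {
  m <- default_management_modes()
  m$baseline_offset <- 0
  m
}

# A small clean dataset for quick structural tests.
tiny_dataset <- function(seed = 1, n_samples = 12, n_bands = 64,
                         replicates = 3, noise = 0.002) {
  generate_dataset(generator_config(
    n_samples = n_samples, replicates_per_sample = replicates,
    n_bands = n_bands, scan_noise_sd = noise, seed = seed))
}

# Study conditions of the parameter-recovery suite: high coupling, low
# noise, flat mode offsets (only coupled bands informative).
recovery_generator <- function(seed, n_samples = 180, n_bands = 300) {
  generator_config(
    n_samples = n_samples, n_bands = n_bands,
    management_modes = modes_flat(),
    coupling_strength = 0.006, scan_noise_sd = 0.005, seed = seed)
}

# Coupled-window membership: center +/- 2 sigma of any coupled band.
in_coupled_window <- function(wavenumbers,
                              bands = default_absorption_bands()) {
  bands <- bands[bands$tannin_coupled, ]
  vapply(wavenumbers, function(w) {
    any(abs(w - bands$center) <= 2 * bands$width)
  }, logical(1))
}

# Wavenumber parsed back from pipeline feature names ("wn1234.5").
feature_wavenumber <- function(feature_names) {
  as.numeric(sub("^wn", "", feature_names))
}

# Direct-summation CWT oracle (no FFT): same discretisation contract as
# cwt_spectrum, evaluated naively.
cwt_direct <- function(signal, a, wavelet_id = "gaus4", radius = 8) {
  n <- length(signal)
  L <- ceiling(radius * a)
  m <- seq(-L, L)
  k <- mother_wavelet(m / a, wavelet_id) / sqrt(a)
  vapply(seq_len(n), function(b) {
    idx <- tanninspec:::reflect_index(b + m, n)
    sum(signal[idx] * k)
  }, numeric(1))
}

# Dense quadrature CWT oracle: linear interpolation of the sampled signal
# integrated against the continuous wavelet on a fine grid (step `h`).
cwt_dense_quadrature <- function(signal, a, b_idx, h = 0.05, radius = 8) {
  n <- length(signal)
  vapply(b_idx, function(b) {
    t_grid <- seq(b - radius * a, b + radius * a, by = h)
    idx <- tanninspec:::reflect_index(floor(t_grid), n)
    idx2 <- tanninspec:::reflect_index(floor(t_grid) + 1, n)
    frac <- t_grid - floor(t_grid)
    f <- signal[idx] * (1 - frac) + signal[idx2] * frac
    sum(f * mother_wavelet((t_grid - b) / a) / sqrt(a)) * h
  }, numeric(1))
}

# Independent reference CWT through PyWavelets' tabulated gaus4
# (numerically converged direct integration in numpy).  pywt's gaus4 is
# the 4th derivative of exp(-x^2); ours of exp(-t^2/2), so the reference
# is queried at scale a*sqrt(2) (exact correspondence).
pywt_reference_cwt <- function(signal, scales) {
  dir <- tempfile("pywtref")
  dir.create(dir)
  sig_file <- file.path(dir, "sig.txt")
  scl_file <- file.path(dir, "scales.txt")
  out_file <- file.path(dir, "ref.csv")
  writeLines(sprintf("%.17g", signal), sig_file)
  writeLines(sprintf("%.17g", scales * sqrt(2)), scl_file)
  script <- file.path(dir, "ref.py")
  writeLines(c(
    "import numpy as np, pywt, sys",
    sprintf("x = np.loadtxt(r'%s')", sig_file),
    sprintf("scales = np.atleast_1d(np.loadtxt(r'%s'))", scl_file),
    "n = len(x)",
    "w = pywt.ContinuousWavelet('gaus4')",
    "psi, t = w.wavefun(14)",
    "out = np.zeros((len(scales), n))",
    "tg = np.arange(n)",
    "for si, s in enumerate(scales):",
    "    for b in range(n):",
    "        arg = (tg - b) / s",
    "        out[si, b] = np.sum(x * np.interp(arg, t, psi, left=0.0, right=0.0)) / np.sqrt(s)",
    sprintf("np.savetxt(r'%s', out, delimiter=',')", out_file)
  ), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_file)) {
    stop("reference CWT script failed: ", paste(status, collapse = "\n"))
  }
  as.matrix(utils::read.csv(out_file, header = FALSE))
}

# A small random-forest regression on p features, for attribution tests.
small_forest <- function(p = 8, n = 60, seed = 91) {
  tanninspec:::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- sprintf("f%d", seq_len(p))
    y <- drop(X %*% seq(-1, 1, length.out = p)) + rnorm(n, sd = 0.2)
  })
  mod <- fit_rf(X, y, rf_config(tuning_iterations = 0, n_trees = 40,
                                min_leaf = 3, seed = seed))
  list(model = mod, X = X)
}

# A smooth random spectrum-like signal: ramp minus random Gaussian dips.
smooth_random_signal <- function(n, seed) {
  tanninspec:::with_seed(seed, {
    u <- seq(0, 1, length.out = n)
    x <- 0.3 + 0.3 * u
    for (k in 1:8) {
      x <- x - runif(1, 0.01, 0.08) *
        exp(-(u - runif(1))^2 / (2 * runif(1, 0.02, 0.08)^2))
    }
    x
  })
}
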