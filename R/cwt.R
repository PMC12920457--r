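#' @name cwt
#' @title Continuous wavelet decomposition of spectra
#'
#' @description
#' The continuous wavelet transform used here computes, for a spectrum
#' `v_j` sampled at band indices `j`, the coefficients
#' `w(a, b) = sum_j v_j * (1/sqrt(a)) * psi((j - b) / a)`,
#' a discrete approximation (band-index step = 1) of the inner product of
#' the spectrum with scaled and translated copies of a zero-mean mother
#' wavelet.  The translation `b` runs over every band index so each scale
#' yields a coefficient vector of the same length as the input; boundary
#' values are computed on a symmetric-reflection extension of the signal.
#' The default mother wavelet is `gaus4`, the fourth derivative of a
#' Gaussian, scaled to unit L2 norm with the sign fixed so `psi(0) > 0`.
#' Scales default to the dyadic ladder 2^1 .. 2^10.
NULL

# L2 normalisation constant of (t^4 - 6 t^2 + 3) exp(-t^2/2):
# integral of its square is 6.5625 * sqrt(pi) (Gaussian moments).
GAUS4_NORM <- 1 / sqrt(6.5625 * sqrt(pi))

# numerically-normalised constants for optional wavelets, computed lazily
.wavelet_env <- new.env(parent = emptyenv())

#' Evaluate a mother wavelet
#'
#' @param t Dimensionless argument (vectorised).
#' @param wavelet_id One of `"gaus4"` (default), `"mexh"`, `"morl"`.
#' @return `psi(t)`, unit-L2-norm, zero-mean, with `psi(0) > 0` for the
#'   even-symmetric wavelets.
#' @export
mother_wavelet <- function(t, wavelet_id = "gaus4") {
  switch(wavelet_id,
    gaus4 = GAUS4_NORM * (t^4 - 6 * t^2 + 3) * exp(-t^2 / 2),
    mexh = 2 / (sqrt(3) * pi^0.25) * (1 - t^2) * exp(-t^2 / 2),
    morl = {
      # real-valued Morlet (cosine-modulated Gaussian), numerically
      # normalised to unit L2 norm
      key <- "morl_norm"
      if (is.null(.wavelet_env[[key]])) {
        f <- function(u) (cos(5 * u) * exp(-u^2 / 2))^2
        .wavelet_env[[key]] <- 1 / sqrt(stats::integrate(f, -8, 8)$value)
      }
      .wavelet_env[[key]] * cos(5 * t) * exp(-t^2 / 2)
    },
    stopf("unsupported wavelet_id '%s' (supported: gaus4, mexh, morl)",
          wavelet_id)
  )
}

# effective one-sided support radius in t units (psi is numerically zero
# beyond this)
wavelet_support_radius <- function(wavelet_id) {
  switch(wavelet_id, gaus4 = 8, mexh = 8, morl = 8,
         stopf("unsupported wavelet_id '%s'", wavelet_id))
}

# reflect out-of-range indices back into 1..n (half-sample symmetric),
# repeatedly for extensions wider than the signal
reflect_index <- function(idx, n) {
  period <- 2 * n
  m <- ((idx - 1) %% period + period) %% period
  ifelse(m < n, m + 1, period - m)
}

#' Continuous wavelet transform of one signal
#'
#' @param signal Numeric vector (one spectrum, any transform form).
#' @param scales Positive scale factors; each must not exceed the signal
#'   length.
#' @param wavelet_id Mother wavelet (default `"gaus4"`).
#' @return Matrix with one row per scale and `length(signal)` columns.
#' @export
cwt_spectrum <- function(signal, scales, wavelet_id = "gaus4") {
  n <- length(signal)
  if (n < 2) stopf("signal must have length >= 2")
  if (any(scales <= 0)) stopf("scales must be positive")
  if (any(scales > n)) {
    stopf("scale %g exceeds signal length %d", max(scales), n)
  }
  out <- matrix(0, length(scales), n)
  for (s in seq_along(scales)) {
    out[s, ] <- cwt_rows(matrix(signal, nrow = 1), scales[s], wavelet_id)
  }
  out
}

# CWT of every row of `mat` at a single scale, FFT-convolution based.
cwt_rows <- function(mat, a, wavelet_id = "gaus4") {
  n <- ncol(mat)
  L <- ceiling(wavelet_support_radius(wavelet_id) * a)
  m <- seq(-L, L)
  kern <- mother_wavelet(m / a, wavelet_id) / sqrt(a)
  pad_idx <- reflect_index(seq(1 - L, n + L), n)
  npad <- n + 2L * L
  nk <- 2L * L + 1L
  # w(b) = sum_m y[b + L + m] * kern[m + L + 1]  (cross-correlation);
  # realised as FFT convolution with the reversed kernel
  nfft <- stats::nextn(npad + nk - 1L, 2)
  kern_fft <- stats::fft(c(rev(kern), numeric(nfft - nk)))
  res <- matrix(0, nrow(mat), n)
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, pad_idx]
    yf <- stats::fft(c(y, numeric(nfft - npad)))
    conv <- Re(stats::fft(yf * kern_fft, inverse = TRUE)) / nfft
    # full convolution index: conv[j] = sum_i y[i] revk[j - i + 1];
    # w(b) corresponds to j = b + 2L
    res[i, ] <- conv[seq_len(n) + 2L * L]
  }
  res
}

#' Wavelet features of a transformed spectra block
#'
#' Applies [cwt_spectrum()] row-wise to every sample spectrum at each
#' scale of the dyadic ladder.
#'
#' @param spectra A `transformed_spectra` (or `sample_spectra`) object.
#' @param scales Scale factors (default `2^(1:10)`).
#' @param wavelet_id Mother wavelet (default `"gaus4"`).
#' @return A `wavelet_features` object: list with `source_tag`,
#'   `wavelet_id`, `scales`, `wavenumbers`, `sample_id`, `coefficients`
#'   (named list of sample x band matrices, one per scale) and
#'   `boundary_width` (per-scale count of boundary-affected bands at each
#'   edge).
#' @export
cwt_features <- function(spectra, scales = 2^(1:10), wavelet_id = "gaus4") {
  if (inherits(spectra, "transformed_spectra")) {
    mat <- spectra$values
    tag <- spectra$tag
    wn <- spectra$wavenumbers
    ids <- spectra$sample_id
  } else if (inherits(spectra, "spectrum_set")) {
    mat <- spectra$reflectance
    tag <- "R"
    wn <- spectra$wavenumbers
    ids <- spectra$sample_id
  } else {
    stopf("spectra must be transformed_spectra or spectrum_set")
  }
  n <- ncol(mat)
  if (any(scales > n)) {
    stopf("scale %g exceeds band count %d", max(scales[scales > n]), n)
  }
  coef <- lapply(scales, function(a) cwt_rows(mat, a, wavelet_id))
  names(coef) <- as.character(scales)
  structure(list(
    source_tag = tag,
    wavelet_id = wavelet_id,
    scales = scales,
    wavenumbers = wn,
    sample_id = ids,
    coefficients = coef,
    boundary_width = pmin(
      ceiling(wavelet_support_radius(wavelet_id) * scales / 2), n)
  ), class = "wavelet_features")
}

#' @export
print.wavelet_features <- function(x, ...) {
  cat(sprintf(
    "wavelet_features [%s_CWT, %s]: %d scales (%s), %d samples x %d bands\n",
    x$source_tag, x$wavelet_id, length(x$scales),
    paste(range(x$scales), collapse = ".."),
    nrow(x$coefficients[[1]]), length(x$wavenumbers)))
  invisible(x)
}
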