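#' Configuration for the synthetic walnut-kernel spectra generator
#'
#' Builds the parameter set that [generate_dataset()] uses to simulate
#' near-infrared reflectance scans of ground walnut kernels together with a
#' per-sample tannin reference table.  The defaults emulate the structure of
#' a field study: 180 samples collected under three orchard management
#' modes, each scanned three times over 4000--10000 cm-1, with
#' hydroxyl-related absorption features in the 4000--5000 cm-1 combination
#' band region and near 7000 cm-1 (first O-H stretching overtone) whose
#' depths scale linearly with tannin content.
#'
#' @param n_samples Number of kernel samples (default 180).
#' @param replicates_per_sample Replicate scans per sample (default 3).
#' @param wavenumber_min,wavenumber_max Spectral range in cm-1
#'   (defaults 4000 and 10000).
#' @param n_bands Number of spectral points across the range (default 1557,
#'   about 3.86 cm-1 spacing).
#' @param management_modes Data frame with columns `label`, `tannin_mean`
#'   (mg/g), `tannin_sd` (mg/g) and `baseline_offset` (reflectance units),
#'   one row per orchard management mode.  Samples are assigned to modes in
#'   near-equal blocks.  The default three modes pool to a mean tannin of
#'   about 13.17 mg/g.
#' @param tannin_clip Length-2 numeric, the (low, high) truncation of the
#'   tannin distribution in mg/g (default c(4.73, 20.17)).
#' @param coupling_strength Absorption depth added per mg/g of tannin at
#'   tannin-coupled bands (reflectance units per mg/g, default 0.004).
#' @param absorption_bands Data frame with columns `center` (cm-1), `width`
#'   (Gaussian sigma, cm-1), `tannin_coupled` (logical) and `base_depth`
#'   (tannin-independent depth, reflectance units).
#' @param baseline_coef Polynomial coefficients (intercept first) of the
#'   smooth reflectance baseline, evaluated on the unit-normalised
#'   wavenumber axis; the default rises from about 0.25 to 0.60.
#' @param scan_noise_sd Standard deviation of i.i.d. Gaussian scan noise in
#'   reflectance units (default 0.002).
#' @param noise_ar1_rho Optional lag-1 autocorrelation of the scan noise
#'   along the wavenumber axis (default 0, i.e. white noise).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return An object of class `generator_config` (a named list).
#' @seealso [generate_dataset()], [inject_outliers()]
#' @export
generator_config <- function(n_samples = 180,
                             replicates_per_sample = 3,
                             wavenumber_min = 4000,
                             wavenumber_max = 10000,
                             n_bands = 1557,
                             management_modes = default_management_modes(),
                             tannin_clip = c(4.73, 20.17),
                             coupling_strength = 0.004,
                             absorption_bands = default_absorption_bands(),
                             baseline_coef = c(0.25, 0.40, -0.05),
                             scan_noise_sd = 0.002,
                             noise_ar1_rho = 0,
                             seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    stopf("invalid config: n_samples must be a positive count, got %s",
          format(n_samples))
  }
  if (!is.numeric(n_bands) || n_bands < 2) {
    stopf("invalid config: n_bands must be >= 2, got %s", format(n_bands))
  }
  if (replicates_per_sample < 1) {
    stopf("invalid config: replicates_per_sample must be >= 1")
  }
  if (wavenumber_min >= wavenumber_max) {
    stopf("invalid config: wavenumber_min must be < wavenumber_max")
  }
  if (length(tannin_clip) != 2 || tannin_clip[1] >= tannin_clip[2]) {
    stopf("invalid config: tannin_clip must be (low, high) with low < high")
  }
  if (tannin_clip[1] <= 0) {
    stopf("invalid config: tannin_clip low bound must be > 0")
  }
  if (coupling_strength < 0) {
    stopf("invalid config: coupling_strength must be >= 0")
  }
  needed <- c("label", "tannin_mean", "tannin_sd", "baseline_offset")
  if (!all(needed %in% names(management_modes))) {
    stopf("invalid config: management_modes needs columns %s",
          paste(needed, collapse = ", "))
  }
  needed <- c("center", "width", "tannin_coupled", "base_depth")
  if (!all(needed %in% names(absorption_bands))) {
    stopf("invalid config: absorption_bands needs columns %s",
          paste(needed, collapse = ", "))
  }
  structure(list(
    n_samples = as.integer(n_samples),
    replicates_per_sample = as.integer(replicates_per_sample),
    wavenumber_min = wavenumber_min,
    wavenumber_max = wavenumber_max,
    n_bands = as.integer(n_bands),
    management_modes = management_modes,
    tannin_clip = tannin_clip,
    coupling_strength = coupling_strength,
    absorption_bands = absorption_bands,
    baseline_coef = baseline_coef,
    scan_noise_sd = scan_noise_sd,
    noise_ar1_rho = noise_ar1_rho,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default orchard management modes
#'
#' Three modes (low-, medium- and high-yield management) with tannin means
#' chosen so the pooled mean is 13.17 mg/g, a common spread of 2.2 mg/g,
#' and small additive reflectance offsets that keep mode-average curves
#' near-parallel.
#'
#' @return A data frame with one row per mode.
#' @export
default_management_modes <- function() {
  data.frame(
    label = c("low_yield", "medium_yield", "high_yield"),
    tannin_mean = c(15.93, 13.17, 10.41),
    tannin_sd = c(2.2, 2.2, 2.2),
    baseline_offset = c(0.00, 0.02, 0.04),
    stringsAsFactors = FALSE
  )
}

#' Default absorption-band layout
#'
#' Three tannin-coupled Gaussian absorptions (two in the 4000--5000 cm-1
#' O-H combination-band region, one at the ~7050 cm-1 first O-H overtone)
#' plus two tannin-independent background absorptions standing in for other
#' kernel constituents.
#'
#' @return A data frame with one row per absorption feature.
#' @export
default_absorption_bands <- function() {
  data.frame(
    center = c(4400, 4800, 7050, 5600, 8600),
    width = c(150, 120, 180, 220, 260),
    tannin_coupled = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    base_depth = c(0, 0, 0, 0.05, 0.04)
  )
}

# Truncated-normal draws by rejection; deterministic under the caller's RNG.
rtruncnorm_rej <- function(n, mean, sd, low, high) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= low & draw <= high
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic spectra set and tannin reference table
#'
#' Simulates `n_samples x replicates_per_sample` reflectance scans.  Each
#' scan is a smooth increasing polynomial baseline, plus the management-mode
#' offset, minus a sum of Gaussian absorption features (tannin-coupled
#' depths equal `coupling_strength x tannin`), plus i.i.d. Gaussian scan
#' noise, finally clipped into (0, 1].  Tannin values are drawn per mode
#' from a truncated normal within `tannin_clip`.
#'
#' @param config A [generator_config()].
#' @return A list with elements `spectra` (a `spectrum_set`) and `tannins`
#'   (a data frame `sample_id`, `tannin` in mg/g).
#' @examples
#' ds <- generate_dataset(generator_config(n_samples = 12, n_bands = 64))
#' nrow(ds$spectra$reflectance)  # 36 scans
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    stopf("config must be a generator_config object")
  }
  with_seed(config$seed, {
    n <- config$n_samples
    reps <- config$replicates_per_sample
    wn <- round(seq(config$wavenumber_min, config$wavenumber_max,
                    length.out = config$n_bands), 4)
    modes <- config$management_modes
    n_modes <- nrow(modes)
    # near-equal contiguous blocks of samples per mode
    mode_of_sample <- sort(rep(seq_len(n_modes), length.out = n))
    sample_ids <- sprintf("S%03d", seq_len(n))

    tannin <- numeric(n)
    for (m in seq_len(n_modes)) {
      idx <- which(mode_of_sample == m)
      tannin[idx] <- rtruncnorm_rej(length(idx), modes$tannin_mean[m],
                                    modes$tannin_sd[m],
                                    config$tannin_clip[1],
                                    config$tannin_clip[2])
    }

    u <- (wn - config$wavenumber_min) /
      (config$wavenumber_max - config$wavenumber_min)
    baseline <- rep(0, length(wn))
    for (k in seq_along(config$baseline_coef)) {
      baseline <- baseline + config$baseline_coef[k] * u^(k - 1)
    }

    ab <- config$absorption_bands
    shapes <- vapply(seq_len(nrow(ab)), function(b) {
      exp(-(wn - ab$center[b])^2 / (2 * ab$width[b]^2))
    }, numeric(length(wn)))          # band x feature

    n_scan <- n * reps
    scan_sample <- rep(seq_len(n), each = reps)
    refl <- matrix(0, n_scan, length(wn))
    for (i in seq_len(n)) {
      depth <- ab$base_depth +
        ifelse(ab$tannin_coupled, config$coupling_strength * tannin[i], 0)
      clean <- baseline + modes$baseline_offset[mode_of_sample[i]] -
        drop(shapes %*% depth)
      rows <- which(scan_sample == i)
      for (r in rows) {
        if (config$scan_noise_sd > 0) {
          eps <- stats::rnorm(length(wn), 0, config$scan_noise_sd)
          if (config$noise_ar1_rho != 0) {
            eps <- as.numeric(stats::filter(eps, config$noise_ar1_rho,
                                            method = "recursive"))
            eps <- eps * sqrt(1 - config$noise_ar1_rho^2)
          }
          refl[r, ] <- clean + eps
        } else {
          refl[r, ] <- clean
        }
      }
    }
    refl <- pmin(pmax(refl, 1e-6), 1)

    spectra <- spectrum_set(
      wavenumbers = wn,
      reflectance = refl,
      sample_id = sample_ids[scan_sample],
      replicate = rep(seq_len(reps), times = n),
      mode = modes$label[mode_of_sample][scan_sample]
    )
    tannins <- data.frame(sample_id = sample_ids, tannin = tannin,
                          stringsAsFactors = FALSE)
    list(spectra = spectra, tannins = tannins)
  })
}

#' Inject known outliers into a generated dataset
#'
#' Shifts the reference tannin and/or the whole spectrum of the listed
#' samples, leaving every other row untouched.  Used to build fixtures for
#' the Monte-Carlo outlier screen.
#'
#' @param spectra A `spectrum_set` (raw scans or averaged spectra).
#' @param tannins Tannin reference data frame (`sample_id`, `tannin`).
#' @param sample_ids Character vector of sample ids to perturb.
#' @param y_shift Amount added to the listed samples' tannin (mg/g).
#' @param spectral_shift Amount added to every reflectance value of the
#'   listed samples' scans (reflectance units).
#' @return A list with perturbed `spectra` and `tannins`.
#' @export
inject_outliers <- function(spectra, tannins, sample_ids,
                            y_shift = 0, spectral_shift = 0) {
  stopifnot(inherits(spectra, "spectrum_set"))
  unknown <- setdiff(sample_ids, tannins$sample_id)
  if (length(unknown) > 0) {
    stopf("unknown sample_id(s): %s", paste(unknown, collapse = ", "))
  }
  hit <- tannins$sample_id %in% sample_ids
  tannins$tannin[hit] <- tannins$tannin[hit] + y_shift
  rows <- spectra$sample_id %in% sample_ids
  spectra$reflectance[rows, ] <- spectra$reflectance[rows, ] + spectral_shift
  list(spectra = spectra, tannins = tannins)
}

#' Tannin content from the colorimetric assay
#'
#' Converts a gallic-acid equivalent read off the standard curve into
#' tannin content of the original sample:
#' `X = C * V1 * N / (M * 1000)`, where `C` is the gallic acid content from
#' the standard curve (mg), `V1` the volume of the determination solution
#' (mL), `N` the dilution factor and `M` the sample mass (g).
#'
#' @param C Gallic acid content from the standard curve (mg).
#' @param V1 Volume of the sample determination solution (mL).
#' @param N Dilution factor.
#' @param M Mass of the walnut sample (g).
#' @return Tannin content in mg/g.
#' @examples
#' tannin_from_assay(C = 1, V1 = 100, N = 25, M = 1)  # 2.5
#' @export
tannin_from_assay <- function(C, V1, N, M) {
  if (any(M <= 0)) stopf("invalid input: sample mass M must be > 0")
  if (any(c(C, V1, N) < 0)) stopf("invalid input: C, V1, N must be >= 0")
  C * V1 * N / (M * 1000)
}
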