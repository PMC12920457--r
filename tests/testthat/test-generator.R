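test_that("generated scan counts and structure match the study design", {
  ds <- generate_dataset(generator_config(n_samples = 180,
                                          replicates_per_sample = 3,
                                          n_bands = 48, seed = 4))
  expect_equal(nrow(ds$spectra$reflectance), 540)
  expect_equal(length(unique(ds$spectra$sample_id)), 180)
  expect_equal(nrow(ds$tannins), 180)
  expect_true(all(diff(ds$spectra$wavenumbers) > 0))
  expect_true(all(ds$spectra$reflectance > 0 & ds$spectra$reflectance <= 1))
  expect_equal(sort(unique(table(ds$spectra$sample_id))), 3)
})

test_that("generation is deterministic per seed and seeds differ", {
  cfg <- generator_config(n_samples = 10, n_bands = 40, seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  c <- generate_dataset(generator_config(n_samples = 10, n_bands = 40,
                                         seed = 10))
  expect_false(identical(a$spectra$reflectance, c$spectra$reflectance))
})

test_that("zero scan noise makes replicate rows identical", {
  ds <- tiny_dataset(seed = 2, noise = 0)
  for (id in unique(ds$spectra$sample_id)[1:4]) {
    rows <- ds$spectra$reflectance[ds$spectra$sample_id == id, ]
    expect_equal(rows[1, ], rows[2, ])
    expect_equal(rows[1, ], rows[3, ])
  }
})

test_that("without coupling (and flat modes) no band correlates with tannin", {
  ds <- generate_dataset(generator_config(
    n_samples = 300, replicates_per_sample = 1, n_bands = 120,
    management_modes = modes_flat(), coupling_strength = 0,
    scan_noise_sd = 0.004, seed = 31))
  avg <- average_replicates(ds$spectra)
  prof <- pearson_profile(avg$reflectance, ds$tannins$tannin)
  expect_gte(mean(!prof$selected), 0.95)
})

test_that("tannin-coupled absorption depth grows linearly with tannin", {
  cfg <- generator_config(n_samples = 40, replicates_per_sample = 1,
                          n_bands = 400, management_modes = modes_flat(),
                          scan_noise_sd = 0, seed = 6)
  ds <- generate_dataset(cfg)
  band <- which.min(abs(ds$spectra$wavenumbers - 7050))
  # depth at the coupled band center relative to a clean reference band
  ref_band <- which.min(abs(ds$spectra$wavenumbers - 6300))
  depth <- ds$spectra$reflectance[, ref_band] -
    ds$spectra$reflectance[, band]
  fit <- lm(depth ~ ds$tannins$tannin)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_gt(coef(fit)[2], 0)
})

test_that("mode-average curves are ordered and near-parallel without noise", {
  ds <- generate_dataset(generator_config(
    n_samples = 30, replicates_per_sample = 1, n_bands = 200,
    scan_noise_sd = 0, seed = 8))
  avg <- average_replicates(ds$spectra)
  curves <- sapply(split(seq_along(avg$sample_id), avg$mode), function(i) {
    colMeans(avg$reflectance[i, , drop = FALSE])
  })
  # offsets: high_yield (0.04) > medium (0.02) > low (0)
  expect_true(all(curves[, "high_yield"] > curves[, "medium_yield"]))
  expect_true(all(curves[, "medium_yield"] > curves[, "low_yield"]))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_lt(sd(curves[, pair[1]] - curves[, pair[2]]), 0.02)
  }
})

test_that("tannin values always fall inside the clip range", {
  for (seed in 1:5) {
    ds <- generate_dataset(generator_config(n_samples = 25, n_bands = 16,
                                            seed = seed))
    expect_true(all(ds$tannins$tannin >= 4.73 &
                      ds$tannins$tannin <= 20.17))
  }
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(n_samples = 0), "n_samples")
  expect_error(generator_config(n_bands = 1), "n_bands")
  expect_error(generator_config(wavenumber_min = 9000,
                                wavenumber_max = 5000), "wavenumber")
  expect_error(generator_config(tannin_clip = c(10, 5)), "tannin_clip")
  expect_error(generator_config(coupling_strength = -1), "coupling")
})

test_that("inject_outliers perturbs exactly the listed samples", {
  ds <- tiny_dataset(seed = 3, n_samples = 20)
  ids <- sprintf("S%03d", c(2, 5, 7, 9, 11, 13, 15, 17, 19))
  out <- inject_outliers(ds$spectra, ds$tannins, ids,
                         y_shift = 4, spectral_shift = 0.05)
  changed_y <- which(out$tannins$tannin != ds$tannins$tannin)
  expect_equal(out$tannins$sample_id[changed_y], ids)
  row_changed <- rowSums(out$spectra$reflectance !=
                           ds$spectra$reflectance) > 0
  expect_setequal(unique(out$spectra$sample_id[row_changed]), ids)
  expect_equal(sum(!row_changed),
               sum(!(ds$spectra$sample_id %in% ids)))
})

test_that("inject_outliers with zero shifts is the identity", {
  ds <- tiny_dataset(seed = 4)
  out <- inject_outliers(ds$spectra, ds$tannins, "S001",
                         y_shift = 0, spectral_shift = 0)
  expect_identical(out$spectra, ds$spectra)
  expect_identical(out$tannins, ds$tannins)
  expect_error(inject_outliers(ds$spectra, ds$tannins, "nope"),
               "unknown sample_id")
})

test_that("assay formula follows the printed arithmetic", {
  expect_equal(tannin_from_assay(C = 0, V1 = 100, N = 25, M = 1), 0)
  expect_equal(tannin_from_assay(C = 1, V1 = 100, N = 25, M = 1), 2.5)
  # doubling the sample mass halves the result
  for (C in c(0.5, 2)) {
    expect_equal(tannin_from_assay(C, 100, 25, 2),
                 tannin_from_assay(C, 100, 25, 1) / 2)
  }
  expect_error(tannin_from_assay(1, 100, 25, 0), "M must be > 0")
})
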