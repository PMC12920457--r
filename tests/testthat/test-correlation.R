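test_that("r and p match a direct formula evaluation on a hand dataset", {
  x <- c(2.1, 3.4, 1.2, 5.6, 4.4, 2.2, 6.1, 0.4, 3.3, 5.0)
  y <- c(1.0, 2.2, 0.8, 4.9, 3.6, 2.5, 5.2, 0.2, 2.9, 4.1)
  # brute-force oracle: explicit sums
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_oracle <- r_oracle * sqrt((10 - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * (1 - pt(abs(t_oracle), 8))
  prof <- pearson_profile(cbind(x), y)
  expect_lt(abs(prof$r - r_oracle), 1e-10)
  expect_lt(abs(prof$p - p_oracle), 1e-10)
})

test_that("perfect and negated features behave as expected", {
  tanninspec:::with_seed(61, y <- rnorm(30) + 10)
  X <- cbind(a = y, b = -y + 0, c = rnorm(30))
  prof <- pearson_profile(X, y)
  expect_equal(prof$r[1], 1)
  expect_true(prof$selected[1])
  expect_equal(prof$r[2], -prof$r[1])
  expect_equal(abs(prof$r[2]), abs(prof$r[1]))
  expect_equal(prof$selected[2], prof$selected[1])
  expect_error(pearson_profile(X, rep(1, 30)), "constant")
})

test_that("the critical r threshold inverts the t relation", {
  expect_equal(critical_r_threshold(440), 0.1226826, tolerance = 1e-6)
  expect_equal(critical_r_threshold(171), 0.1964956, tolerance = 1e-6)
  # strictly decreasing in n
  ns <- c(10, 50, 171, 440, 1000)
  th <- vapply(ns, critical_r_threshold, numeric(1))
  expect_true(all(diff(th) < 0))
  expect_error(critical_r_threshold(2), "n >= 3")
})

test_that("selection masks nest across alpha and ignore affine scaling", {
  ds <- tiny_dataset(seed = 62, n_samples = 40, n_bands = 60)
  avg <- average_replicates(ds$spectra)
  y <- ds$tannins$tannin
  p01 <- pearson_profile(avg$reflectance, y, alpha = 0.01)
  p05 <- pearson_profile(avg$reflectance, y, alpha = 0.05)
  expect_true(all(!p01$selected | p05$selected))
  scaled <- pearson_profile(avg$reflectance * 3 - 1, 2 * y + 5,
                            alpha = 0.01)
  expect_identical(scaled$selected, p01$selected)
  expect_equal(scaled$r, p01$r, tolerance = 1e-12)
})

test_that("mirrored transform pairs mirror their profile summaries", {
  ds <- tiny_dataset(seed = 63, n_samples = 40, n_bands = 80)
  avg <- average_replicates(ds$spectra)
  y <- ds$tannins$tannin
  bank <- transform_bank(avg)
  s1 <- summarize_profile(pearson_profile(bank[["lg'R"]]$values, y))
  s2 <- summarize_profile(pearson_profile(bank[["lg'(1/R)"]]$values, y))
  expect_equal(s1$NFB, s2$NFB)
  expect_equal(s1$mean_abs_r, s2$mean_abs_r)
  expect_equal(s1$pos_extremum, -s2$neg_extremum)
  expect_equal(s1$neg_extremum, -s2$pos_extremum)
})

test_that("profile summaries match brute-force recomputation", {
  ds <- tiny_dataset(seed = 64, n_samples = 30, n_bands = 50)
  avg <- average_replicates(ds$spectra)
  prof <- pearson_profile(avg$reflectance, ds$tannins$tannin)
  s <- summarize_profile(prof)
  sel_r <- prof$r[prof$selected]
  expect_equal(s$NFB, sum(prof$selected))
  if (any(sel_r > 0)) expect_equal(s$pos_extremum, max(sel_r[sel_r > 0]))
  if (any(sel_r < 0)) expect_equal(s$neg_extremum, min(sel_r[sel_r < 0]))
  if (length(sel_r)) expect_equal(s$mean_abs_r, mean(abs(sel_r)))
  # empty selection
  empty <- prof
  empty$selected <- rep(FALSE, nrow(prof))
  s0 <- summarize_profile(empty)
  expect_equal(s0$NFB, 0)
  expect_true(is.na(s0$pos_extremum) && is.na(s0$neg_extremum))
})

test_that("scale selection maximises mean |r| with small-scale ties", {
  mk_prof <- function(rs, sel = rep(TRUE, length(rs))) {
    structure(data.frame(axis = seq_along(rs), r = rs,
                         p = rep(0.001, length(rs)), selected = sel),
              class = c("correlation_profile", "data.frame"))
  }
  profs <- list(`2` = mk_prof(c(0.2, 0.1)), `8` = mk_prof(c(0.5, 0.4)),
                `32` = mk_prof(c(0.9, 0.8)), `128` = mk_prof(c(0.3, 0.2)))
  expect_equal(select_optimal_scale(profs)$scale, 32)
  tie <- list(`8` = mk_prof(c(0.6, 0.4)), `2` = mk_prof(c(0.5, 0.5)))
  expect_equal(select_optimal_scale(tie)$scale, 2)
  none <- list(`2` = mk_prof(0.2, sel = FALSE))
  expect_error(select_optimal_scale(none), "empty")
})

test_that("a mid-width coupled bump selects an interior scale", {
  ab1 <- data.frame(center = 7000, width = 150, tannin_coupled = TRUE,
                    base_depth = 0)
  picks <- vapply(0:9, function(s) {
    ds <- generate_dataset(generator_config(
      n_samples = 60, replicates_per_sample = 1, n_bands = 1100,
      management_modes = modes_flat(), absorption_bands = ab1,
      coupling_strength = 0.006, scan_noise_sd = 0.01,
      noise_ar1_rho = 0.9, seed = s))
    avg <- average_replicates(ds$spectra)
    wf <- cwt_features(avg, scales = 2^(1:10))
    profs <- lapply(wf$coefficients, function(m) {
      pearson_profile(m, ds$tannins$tannin, axis = wf$wavenumbers)
    })
    select_optimal_scale(profs, scales = wf$scales)$scale
  }, numeric(1))
  expect_gte(sum(picks > 2 & picks < 1024), 8)
})
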