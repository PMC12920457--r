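#' Critical Pearson correlation at a given significance level
#'
#' The smallest absolute correlation whose two-sided p-value equals
#' `alpha` at `n - 2` degrees of freedom, obtained by inverting the exact
#' relation `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param n Sample count (>= 3).
#' @param alpha Two-sided significance level (default 0.01).
#' @return The critical |r| threshold.
#' @examples
#' critical_r_threshold(171)  # ~0.196
#' @export
critical_r_threshold <- function(n, alpha = 0.01) {
  if (n < 3) stopf("need n >= 3 for a correlation threshold")
  df <- n - 2
  tq <- stats::qt(1 - alpha / 2, df)
  tq / sqrt(tq^2 + df)
}

#' Per-feature Pearson correlation profile against tannin
#'
#' Computes each feature's Pearson correlation with the response, its
#' two-sided p-value from the t-statistic
#' `t = r sqrt((n-2)/(1-r^2))`, and the characteristic-feature mask
#' `selected = (p < alpha) & (|r| > critical_r)`.  With `critical_r`
#' derived from the same `alpha` and `n` (the default) the two gates
#' coincide; supplying `critical_r` explicitly reproduces workflows whose
#' printed critical value corresponds to a different effective n.
#'
#' @param features Numeric matrix (samples x features); the feature axis
#'   is taken from `axis` or the column names.
#' @param y Response vector (tannin, mg/g).
#' @param alpha Significance level (default 0.01).
#' @param critical_r Optional explicit |r| cutoff; defaults to
#'   [critical_r_threshold()] at (`nrow(features)`, `alpha`).
#' @param axis Optional numeric feature axis (e.g. wavenumbers).
#' @param verbose Message the number of constant features (r set to 0,
#'   p to 1).
#' @return A `correlation_profile`: data frame with `axis`, `r`, `p`,
#'   `selected`; attributes `alpha`, `critical_r`, `n`.
#' @export
pearson_profile <- function(features, y, alpha = 0.01, critical_r = NULL,
                            axis = NULL, verbose = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) stopf("need at least 3 samples")
  if (length(y) != n) stopf("length(y) != nrow(features)")
  if (stats::var(y) == 0) stopf("response is constant")
  if (is.null(axis)) {
    axis <- suppressWarnings(as.numeric(colnames(features)))
    if (length(axis) == 0 || anyNA(axis)) axis <- seq_len(ncol(features))
  }
  sds <- apply(features, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    msgf(verbose, "%d constant feature(s): r set to 0, p to 1", sum(const))
  }
  r <- rep(0, ncol(features))
  r[!const] <- drop(stats::cor(features[, !const, drop = FALSE], y))
  # guard tiny numerical overshoot
  r <- pmin(1, pmax(-1, r))
  p <- rep(1, ncol(features))
  nz <- !const
  tstat <- r[nz] * sqrt((n - 2) / pmax(1e-300, 1 - r[nz]^2))
  p[nz] <- 2 * stats::pt(-abs(tstat), n - 2)
  p[nz][abs(r[nz]) == 1] <- 0
  if (is.null(critical_r)) critical_r <- critical_r_threshold(n, alpha)
  prof <- data.frame(axis = axis, r = r, p = p,
                     selected = p < alpha & abs(r) > critical_r)
  attr(prof, "alpha") <- alpha
  attr(prof, "critical_r") <- critical_r
  attr(prof, "n") <- n
  class(prof) <- c("correlation_profile", "data.frame")
  prof
}

#' Summarise a correlation profile
#'
#' Table-style summary of a profile: the number of characteristic
#' features (NFB), the positive and negative correlation extrema among
#' selected features, and the mean absolute correlation.
#'
#' @param profile A `correlation_profile`.
#' @param over `"selected"` (default) computes the extrema and mean |r|
#'   over selected features only; `"all"` uses every feature.
#' @return A one-row data frame `NFB`, `pos_extremum`, `neg_extremum`,
#'   `mean_abs_r`; extrema are `NA` when no selected feature of that sign
#'   exists.
#' @export
summarize_profile <- function(profile, over = c("selected", "all")) {
  over <- match.arg(over)
  sel <- if (over == "selected") profile$selected else
    rep(TRUE, nrow(profile))
  rs <- profile$r[sel]
  data.frame(
    NFB = sum(profile$selected),
    pos_extremum = if (any(rs > 0)) max(rs) else NA_real_,
    neg_extremum = if (any(rs < 0)) min(rs) else NA_real_,
    mean_abs_r = if (length(rs) > 0) mean(abs(rs)) else NA_real_
  )
}

#' Pick the optimal wavelet scale by mean absolute correlation
#'
#' Given one correlation profile per decomposition scale, returns the
#' scale whose selected features have the largest mean |r|; ties are
#' broken toward the smaller scale.  Scales with an empty selection are
#' skipped.
#'
#' @param profiles Named list of `correlation_profile`s; names (or the
#'   `scales` argument) give the numeric scale factors.
#' @param scales Optional numeric scale factors, defaulting to
#'   `as.numeric(names(profiles))`.
#' @return List with `scale` (the winner) and `table`, a per-scale data
#'   frame of [summarize_profile()] rows.
#' @export
select_optimal_scale <- function(profiles, scales = NULL) {
  if (length(profiles) == 0) stopf("no profiles supplied")
  if (is.null(scales)) scales <- as.numeric(names(profiles))
  if (anyNA(scales)) stopf("profiles must be named by numeric scale")
  tab <- do.call(rbind, lapply(profiles, summarize_profile))
  tab <- cbind(scale = scales, tab)
  rownames(tab) <- NULL
  ok <- tab$NFB > 0 & !is.na(tab$mean_abs_r)
  if (!any(ok)) stopf("every scale has an empty characteristic-band selection")
  cand <- tab[ok, ]
  cand <- cand[order(cand$scale), ]
  best <- cand$scale[which.max(cand$mean_abs_r)]  # which.max -> first max
  list(scale = best, table = tab)
}
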