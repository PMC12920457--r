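#' Configuration for the Monte-Carlo outlier screen
#'
#' @param n_iterations Number of random-split iterations (default 2000).
#' @param train_fraction Fraction of samples in each random training set
#'   (default 0.6).
#' @param n_components PLS latent variables per iteration (default 20;
#'   capped automatically when the training set is small).
#' @param mean_threshold Flagging cutoff on the per-sample mean absolute
#'   prediction error, in response units (mg/g; default 10).
#' @param sd_threshold Flagging cutoff on the per-sample standard
#'   deviation of prediction errors (mg/g; default 2).
#' @param rule `"or"` (default) flags a sample when either statistic
#'   exceeds its cutoff; `"and"` requires both.
#' @param seed RNG seed driving all split draws.
#'
#' @details The default cutoffs (mean > 10, SD > 2) are stated in
#' response units and are appropriate for tannin references spanning
#' roughly 5--20 mg/g; for other response scales or much cleaner data
#' they should be re-tuned.
#'
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 2000,
                      train_fraction = 0.6,
                      n_components = 20,
                      mean_threshold = 10,
                      sd_threshold = 2,
                      rule = c("or", "and"),
                      seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  if (mean_threshold <= 0 || sd_threshold <= 0) {
    stopf("thresholds must be > 0")
  }
  structure(list(
    n_iterations = as.integer(n_iterations),
    train_fraction = train_fraction,
    n_components = as.integer(n_components),
    mean_threshold = mean_threshold,
    sd_threshold = sd_threshold,
    rule = match.arg(rule),
    seed = as.integer(seed)
  ), class = "mc_config")
}

#' Monte-Carlo cross-validation outlier screen
#'
#' Repeatedly draws a random training subset, fits a mean-centered PLS
#' regression of tannin on the spectra, predicts the held-out samples and
#' accumulates each sample's absolute prediction errors across its
#' validation appearances.  A sample whose mean error or error SD exceeds
#' the configured cutoffs is flagged as an outlier.
#'
#' @param spectra A `sample_spectra` object (one spectrum per sample) or a
#'   plain samples x bands matrix with rownames as sample ids.
#' @param tannins Reference table (`sample_id`, `tannin`).
#' @param cfg An [mc_config()].
#' @param verbose Message progress (default FALSE).
#' @return An `outlier_report`: data frame with per-sample `sample_id`,
#'   `n_val` (validation appearances), `mean_err`, `sd_err`, `flagged`,
#'   plus the config as attribute `config`.
#' @export
mc_outlier_scan <- function(spectra, tannins, cfg = mc_config(),
                            verbose = FALSE) {
  X <- spectra_matrix(spectra)
  ids <- rownames(X)
  y <- tannins$tannin[match(ids, tannins$sample_id)]
  if (anyNA(y)) {
    stopf("tannin table missing sample(s): %s",
          paste(ids[is.na(y)][1:min(3, sum(is.na(y)))], collapse = ", "))
  }
  n <- nrow(X)
  if (n < 5) stopf("need at least 5 samples for the Monte-Carlo screen")
  n_train <- max(3L, floor(cfg$train_fraction * n))
  if (n_train >= n) stopf("train_fraction leaves no validation samples")
  a <- min(cfg$n_components, n_train - 1L, ncol(X))
  if (a < cfg$n_components && verbose) {
    msgf(TRUE, "latent variables capped at %d (train size %d)", a, n_train)
  }
  err_sum <- numeric(n)
  err_sum2 <- numeric(n)
  n_val <- integer(n)
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$n_iterations)) {
      tr <- sample.int(n, n_train)
      fit <- suppressWarnings(pls_fit(X[tr, , drop = FALSE], y[tr], a))
      va <- setdiff(seq_len(n), tr)
      e <- abs(predict(fit, X[va, , drop = FALSE]) - y[va])
      err_sum[va] <- err_sum[va] + e
      err_sum2[va] <- err_sum2[va] + e^2
      n_val[va] <- n_val[va] + 1L
    }
  })
  if (any(n_val == 0)) {
    stopf("sample(s) never appeared in validation (e.g. %s); increase n_iterations",
          ids[which(n_val == 0)[1]])
  }
  mean_err <- err_sum / n_val
  sd_err <- sqrt(pmax(0, (err_sum2 - n_val * mean_err^2) /
                         pmax(1, n_val - 1)))
  flagged <- if (cfg$rule == "or") {
    mean_err > cfg$mean_threshold | sd_err > cfg$sd_threshold
  } else {
    mean_err > cfg$mean_threshold & sd_err > cfg$sd_threshold
  }
  rep <- data.frame(sample_id = ids, n_val = n_val, mean_err = mean_err,
                    sd_err = sd_err, flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(rep, "config") <- cfg
  class(rep) <- c("outlier_report", "data.frame")
  rep
}

#' Remove flagged or listed samples from spectra and tannin tables
#'
#' @param spectra A `sample_spectra` object.
#' @param tannins Reference table (`sample_id`, `tannin`).
#' @param ids_or_report Character vector of sample ids, or an
#'   `outlier_report` whose flagged ids are removed.
#' @return List with filtered `spectra` and `tannins`; removal is
#'   idempotent and an empty list is the identity.
#' @export
apply_outlier_removal <- function(spectra, tannins, ids_or_report) {
  ids <- if (inherits(ids_or_report, "outlier_report")) {
    ids_or_report$sample_id[ids_or_report$flagged]
  } else {
    as.character(ids_or_report)
  }
  if (!setequal(spectra$sample_id, tannins$sample_id)) {
    stopf("sample ids of spectra and tannin table do not match")
  }
  # ids already absent are ignored (set semantics: removal is idempotent)
  keep <- !(spectra$sample_id %in% ids)
  spectra$reflectance <- spectra$reflectance[keep, , drop = FALSE]
  spectra$sample_id <- spectra$sample_id[keep]
  if (!is.null(spectra$mode)) spectra$mode <- spectra$mode[keep]
  if (!is.null(spectra$replicate)) {
    spectra$replicate <- spectra$replicate[keep]
  }
  tannins <- tannins[!(tannins$sample_id %in% ids), , drop = FALSE]
  rownames(tannins) <- NULL
  list(spectra = spectra, tannins = tannins)
}

# coerce spectra-like inputs to a samples x bands matrix with id rownames
spectra_matrix <- function(spectra) {
  if (inherits(spectra, "spectrum_set")) {
    X <- spectra$reflectance
    rownames(X) <- spectra$sample_id
    if (anyDuplicated(spectra$sample_id)) {
      stopf("expected one spectrum per sample; average replicates first")
    }
    X
  } else if (is.matrix(spectra)) {
    if (is.null(rownames(spectra))) {
      rownames(spectra) <- sprintf("S%03d", seq_len(nrow(spectra)))
    }
    spectra
  } else {
    stopf("spectra must be a sample_spectra object or a matrix")
  }
}
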