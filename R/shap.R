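#' Shapley-value attribution of model predictions
#'
#' Decomposes each explained prediction into additive per-feature
#' contributions using the interventional (marginal) value function:
#' `v(S)` is the mean model output over the background rows with the
#' features in `S` replaced by the explained sample's values.  The
#' `"exact"` method enumerates all feature subsets (allowed up to 12
#' features); the `"sampling"` method averages marginal contributions
#' along seeded random feature permutations.  Both satisfy the
#' efficiency axiom exactly: `base_value + sum(phi) = f(x)` for every
#' explained row.
#'
#' @param model A fitted model accepted by `predict_fun`.
#' @param background Matrix of background rows (typically the training
#'   set, subsampled); defines the baseline expectation.
#' @param explain Matrix of rows to explain (same columns as background).
#' @param method `"auto"` (exact when <= 12 features, else sampling),
#'   `"exact"`, or `"sampling"`.
#' @param n_permutations Permutations for the sampling method
#'   (default 500).
#' @param max_background Background rows are subsampled (seeded) to at
#'   most this many (default 100).
#' @param seed RNG seed for permutation draws and subsampling.
#' @param predict_fun Function `(model, X) -> numeric`; defaults to
#'   `predict`.
#' @return An `attribution_result`: list with `base_value` (mg/g),
#'   `phi` (explained x feature matrix, mg/g), `feature_names`,
#'   `predictions`, `method`, `n_background`, `n_permutations`, `seed`.
#' @export
shapley_attribute <- function(model, background, explain,
                              method = c("auto", "exact", "sampling"),
                              n_permutations = 500,
                              max_background = 100,
                              seed = 1L,
                              predict_fun = function(m, X) predict(m, X)) {
  method <- match.arg(method)
  background <- as.matrix(background)
  explain <- as.matrix(explain)
  if (nrow(background) == 0) stopf("background must be nonempty")
  if (ncol(background) != ncol(explain)) {
    stopf("background and explain must share columns")
  }
  p <- ncol(explain)
  if (method == "auto") method <- if (p <= 12) "exact" else "sampling"
  if (method == "exact" && p > 12) {
    stopf("exact enumeration limited to 12 features (got %d); use method='sampling'",
          p)
  }
  if (nrow(background) > max_background) {
    keep <- with_seed(derive_seed(seed, 11),
                      sample.int(nrow(background), max_background))
    background <- background[keep, , drop = FALSE]
  }
  nb <- nrow(background)
  base_value <- mean(predict_fun(model, background))
  fx <- predict_fun(model, explain)
  phi <- matrix(0, nrow(explain), p)

  if (method == "exact") {
    n_sub <- bitwShiftL(1L, p)
    # subset weights |S|! (p-|S|-1)! / p!
    lf <- lgamma(seq_len(p + 1))  # lf[k+1] = log(k!)
    w_size <- exp(lf[seq_len(p)] + lf[p - seq_len(p) + 1] - lf[p + 1])
    # w_size[s+1] applies to |S| = s, s = 0..p-1
    for (i in seq_len(nrow(explain))) {
      x <- explain[i, ]
      # v(S) for every subset, batched prediction
      v <- numeric(n_sub)
      big <- matrix(0, n_sub * nb, p)
      for (s in 0:(n_sub - 1L)) {
        hyb <- background
        in_s <- which(bitwAnd(bitwShiftR(s, 0:(p - 1L)), 1L) == 1L)
        if (length(in_s) > 0) {
          hyb[, in_s] <- rep(x[in_s], each = nb)
        }
        big[s * nb + seq_len(nb), ] <- hyb
      }
      colnames(big) <- colnames(background)
      pred <- predict_fun(model, big)
      v <- colMeans(matrix(pred, nb, n_sub))
      for (j in seq_len(p)) {
        bit <- bitwShiftL(1L, j - 1L)
        s_all <- 0:(n_sub - 1L)
        no_j <- s_all[bitwAnd(s_all, bit) == 0L]
        sizes <- vapply(no_j, function(s) popcount(s), integer(1))
        phi[i, j] <- sum(w_size[sizes + 1] * (v[no_j + bit + 1] - v[no_j + 1]))
      }
    }
  } else {
    perms <- with_seed(derive_seed(seed, 13), {
      lapply(seq_len(n_permutations), function(k) sample.int(p))
    })
    for (i in seq_len(nrow(explain))) {
      x <- explain[i, ]
      acc <- numeric(p)
      for (perm in perms) {
        # stage t = background with the first t features of `perm`
        # replaced; stages 0..p stacked for one batched prediction
        big <- matrix(0, (p + 1) * nb, p)
        hyb <- background
        big[seq_len(nb), ] <- hyb
        for (t in seq_len(p)) {
          hyb[, perm[t]] <- x[perm[t]]
          big[t * nb + seq_len(nb), ] <- hyb
        }
        colnames(big) <- colnames(background)
        v_stage <- colMeans(matrix(predict_fun(model, big), nb, p + 1))
        acc[perm] <- acc[perm] + diff(v_stage)
      }
      phi[i, ] <- acc / n_permutations
    }
  }
  colnames(phi) <- colnames(explain) %||% sprintf("f%04d", seq_len(p))
  structure(list(
    base_value = base_value,
    phi = phi,
    feature_names = colnames(phi),
    predictions = fx,
    method = method,
    n_background = nb,
    n_permutations = if (method == "sampling") n_permutations else NA_integer_,
    seed = as.integer(seed)
  ), class = "attribution_result")
}

popcount <- function(x) {
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Rank attributions and export plot-ready tables
#'
#' @param result An `attribution_result`.
#' @param top_k Number of top features to report (default 10; clipped to
#'   the feature count with a warning).
#' @param n_waterfall Number of explained samples (seeded draw) whose
#'   per-feature signed contributions are exported for waterfall plots
#'   (default 2).
#' @param seed Seed for the waterfall sample draw.
#' @param feature_values Optional matrix (same shape as `result$phi`) of
#'   the explained samples' feature values for the beeswarm export;
#'   defaults to NA values.
#' @return List with `ranking` (feature, mean_abs_phi, rank; top_k rows),
#'   `beeswarm` (feature, phi, feature_value triples over all explained
#'   samples, top_k features) and `waterfall` (per chosen sample, each
#'   feature's signed contribution, largest |phi| first).
#' @export
rank_and_export <- function(result, top_k = 10, n_waterfall = 2,
                            seed = 1L, feature_values = NULL) {
  stopifnot(inherits(result, "attribution_result"))
  p <- ncol(result$phi)
  if (top_k > p) {
    warning(sprintf("top_k clipped from %d to %d features", top_k, p),
            call. = FALSE)
    top_k <- p
  }
  mean_abs <- colMeans(abs(result$phi))
  ord <- order(mean_abs, decreasing = TRUE)
  ranking <- data.frame(
    feature = result$feature_names[ord][seq_len(top_k)],
    mean_abs_phi = mean_abs[ord][seq_len(top_k)],
    rank = seq_len(top_k), row.names = NULL)
  top_idx <- ord[seq_len(top_k)]
  if (is.null(feature_values)) {
    feature_values <- matrix(NA_real_, nrow(result$phi), p)
  }
  beeswarm <- do.call(rbind, lapply(top_idx, function(j) {
    data.frame(feature = result$feature_names[j],
               phi = result$phi[, j],
               feature_value = feature_values[, j], row.names = NULL)
  }))
  n_wf <- min(n_waterfall, nrow(result$phi))
  wf_rows <- with_seed(derive_seed(seed, 17),
                       sample.int(nrow(result$phi), n_wf))
  waterfall <- do.call(rbind, lapply(wf_rows, function(i) {
    o <- order(abs(result$phi[i, ]), decreasing = TRUE)
    data.frame(sample_row = i,
               feature = result$feature_names[o],
               phi = result$phi[i, o],
               base_value = result$base_value,
               prediction = result$predictions[i], row.names = NULL)
  }))
  list(ranking = ranking, beeswarm = beeswarm, waterfall = waterfall)
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf(
    "attribution_result [%s]: %d samples x %d features, base %.3f mg/g\n",
    x$method, nrow(x$phi), ncol(x$phi), x$base_value))
  invisible(x)
}
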