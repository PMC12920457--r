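#' Fit a PLS1 regression by NIPALS
#'
#' Sequential NIPALS extraction of latent variables on mean-centered
#' predictors and response.  For a single response the NIPALS weight
#' update is closed-form per component: `w = X'y / ||X'y||`, scores
#' `t = Xw`, loadings `p = X't / t't`, `q = y't / t't`, followed by
#' deflation of `X` (and `y`).  Regression coefficients are recovered as
#' `B = W (P'W)^-1 q`.
#'
#' @param X Numeric predictor matrix (samples x bands).
#' @param y Numeric response vector.
#' @param n_components Number of latent variables requested; silently
#'   capped at `min(n - 1, ncol(X))` with a warning when reduced.
#' @param tol Component is stopped early when the residual predictor or
#'   response energy falls below `tol` (default 1e-12).
#' @return An object of class `pls_model` with centering means, weights,
#'   loadings and the regression coefficient vector.
#' @export
pls_fit <- function(X, y, n_components, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) stopf("need at least 3 training samples, got %d", n)
  if (length(y) != n) stopf("length(y) != nrow(X)")
  if (stats::var(y) == 0) stopf("response has zero variance")
  a_max <- min(n - 1L, p)
  if (n_components > a_max) {
    warning(sprintf("n_components reduced from %d to %d (n=%d, p=%d)",
                    n_components, a_max, n, p), call. = FALSE)
    n_components <- a_max
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)  # p x 1
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    tt <- Xc %*% w
    tt2 <- sum(tt^2)
    if (tt2 < tol) break
    pp <- crossprod(Xc, tt) / tt2
    qq <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pp)
    yc <- yc - qq * tt
    W[, a] <- w
    P[, a] <- pp
    q[a] <- qq
    a_used <- a
  }
  if (a_used == 0L) stopf("no PLS component could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  # B = W (P'W)^-1 q
  B <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(
    n_components = a_used,
    x_mean = x_mean,
    y_mean = y_mean,
    weights = W,
    loadings = P,
    y_loadings = q,
    coefficients = B
  ), class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix of predictors on the same band axis.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(sweep(newdata, 2, object$x_mean) %*% object$coefficients) +
    object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variables, %d bands\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}
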