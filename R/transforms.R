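#' @name transforms
#' @title Spectral transform bank
#'
#' @description
#' Twelve spectral forms are supported: raw reflectance `R`, its
#' reciprocal `1/R`, base-10 logarithms `lgR` and `lg(1/R)` (the latter is
#' apparent absorbance), and first/second divided-difference derivatives of
#' each point form: `R'`, `(1/R)'`, `lg'R`, `lg'(1/R)`, `R''`, `(1/R)''`,
#' `lg''R`, `lg''(1/R)`.
#'
#' Derivatives are divided differences along the wavenumber axis
#' (delta-value / delta-wavenumber), so the grid need not be uniform; each
#' derivative order shortens the axis by one point and places the output on
#' midpoints of consecutive wavenumbers.  Note the exact mirror identities
#' `lg(1/R) = -lgR` and hence `lg'(1/R) = -lg'R`, `lg''(1/R) = -lg''R`:
#' mirrored pairs carry identical absolute-correlation structure
#' downstream.
NULL

#' The twelve supported transform tags
#' @return Character vector of tags in canonical order.
#' @export
transform_tags <- function() {
  c("R", "1/R", "lgR", "lg(1/R)",
    "R'", "(1/R)'", "lg'R", "lg'(1/R)",
    "R''", "(1/R)''", "lg''R", "lg''(1/R)")
}

# tag -> (point transform, derivative order)
parse_tag <- function(tag) {
  tags <- transform_tags()
  if (!tag %in% tags) {
    stopf("unknown transform tag '%s'; supported: %s", tag,
          paste(tags, collapse = ", "))
  }
  base <- switch(tag,
    "R" = , "R'" = , "R''" = "R",
    "1/R" = , "(1/R)'" = , "(1/R)''" = "1/R",
    "lgR" = , "lg'R" = , "lg''R" = "lgR",
    "lg(1/R)" = , "lg'(1/R)" = , "lg''(1/R)" = "lg(1/R)")
  order <- if (grepl("''", tag)) 2L else if (grepl("'", tag)) 1L else 0L
  list(base = base, order = order)
}

# one divided-difference derivative step; axis moves to interval midpoints
divided_diff <- function(values, axis) {
  p <- length(axis)
  d_axis <- diff(axis)
  dv <- (values[, -1, drop = FALSE] - values[, -p, drop = FALSE]) /
    rep(d_axis, each = nrow(values))
  list(values = dv, axis = (axis[-1] + axis[-p]) / 2)
}

#' Apply one spectral transform
#'
#' @param set A `sample_spectra` (or `spectrum_set`) object.
#' @param tag One of [transform_tags()].
#' @param epsilon Clamp floor applied before reciprocal/log forms
#'   (default 1e-9); the number of clamped cells is reported.
#' @param verbose Message clamp counts (default TRUE).
#' @return A `transformed_spectra` object: list with `tag`, `values`
#'   (sample x band matrix), `wavenumbers` (shortened by one per
#'   derivative order), `sample_id`.
#' @export
apply_transform <- function(set, tag, epsilon = 1e-9, verbose = TRUE) {
  stopifnot(inherits(set, "spectrum_set"))
  spec <- parse_tag(tag)
  v <- set$reflectance
  n_clamped <- sum(v < epsilon)
  if (n_clamped > 0) {
    msgf(verbose, "transform %s: clamped %d cells below epsilon=%g",
         tag, n_clamped, epsilon)
    v[v < epsilon] <- epsilon
  }
  v <- switch(spec$base,
    "R" = v,
    "1/R" = 1 / v,
    "lgR" = log10(v),
    "lg(1/R)" = -log10(v))
  axis <- set$wavenumbers
  for (k in seq_len(spec$order)) {
    d <- divided_diff(v, axis)
    v <- d$values
    axis <- d$axis
  }
  if (any(!is.finite(v))) stopf("transform %s produced non-finite values", tag)
  structure(list(tag = tag, values = unname(v), wavenumbers = axis,
                 sample_id = set$sample_id, n_clamped = n_clamped),
            class = "transformed_spectra")
}

#' Apply the full 12-form transform bank
#'
#' @inheritParams apply_transform
#' @return Named list of 12 `transformed_spectra`, in canonical tag order.
#' @export
transform_bank <- function(set, epsilon = 1e-9, verbose = FALSE) {
  out <- lapply(transform_tags(), function(tag) {
    apply_transform(set, tag, epsilon = epsilon, verbose = verbose)
  })
  names(out) <- transform_tags()
  out
}

#' @export
print.transformed_spectra <- function(x, ...) {
  cat(sprintf("transformed_spectra [%s]: %d samples x %d bands\n",
              x$tag, nrow(x$values), length(x$wavenumbers)))
  invisible(x)
}
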