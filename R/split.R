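#' Random train/validation partition of sample ids
#'
#' Draws `floor(ratio * n)` ids without replacement into the training set;
#' the remainder form the validation set.  Deterministic per seed.
#'
#' @param ids Character vector of sample ids.
#' @param ratio Training fraction (default 0.6, i.e. a 6:4 split).
#' @param seed RNG seed.
#' @param stratify_by Optional factor of length `length(ids)`; when given,
#'   the draw is stratified within its levels (default NULL, plain random).
#' @return A `split_result`: list with `train_ids`, `val_ids`, `ratio`,
#'   `seed`.
#' @examples
#' s <- split_samples(sprintf("S%03d", 1:171), seed = 7)
#' lengths(s[c("train_ids", "val_ids")])  # 102, 69
#' @export
split_samples <- function(ids, ratio = 0.6, seed = 1L, stratify_by = NULL) {
  n <- length(ids)
  if (n < 2) stopf("need at least 2 ids to split")
  if (ratio <= 0 || ratio >= 1) stopf("ratio must be in (0, 1)")
  if (anyDuplicated(ids)) stopf("ids must be unique")
  train <- with_seed(seed, {
    if (is.null(stratify_by)) {
      sample(ids, floor(ratio * n))
    } else {
      unlist(lapply(split(ids, stratify_by), function(g) {
        sample(g, floor(ratio * length(g)))
      }), use.names = FALSE)
    }
  })
  structure(list(
    train_ids = train,
    val_ids = setdiff(ids, train),
    ratio = ratio,
    seed = as.integer(seed)
  ), class = "split_result")
}

#' Descriptive statistics of tannin across the full/train/validation sets
#'
#' @param tannins Reference table (`sample_id`, `tannin`).
#' @param split A `split_result`.
#' @return Data frame with one row per set (`full`, `train`, `validation`)
#'   and columns `n`, `mean`, `median`, `sd` (sample SD, n-1 denominator)
#'   and `cv_percent` (100 * sd / mean).
#' @export
describe_sets <- function(tannins, split) {
  sets <- list(
    full = tannins$tannin,
    train = tannins$tannin[tannins$sample_id %in% split$train_ids],
    validation = tannins$tannin[tannins$sample_id %in% split$val_ids]
  )
  if (any(lengths(sets) == 0)) stopf("empty set in split")
  out <- do.call(rbind, lapply(names(sets), function(nm) {
    v <- sets[[nm]]
    data.frame(set = nm, n = length(v), mean = mean(v),
               median = stats::median(v), sd = stats::sd(v),
               cv_percent = 100 * stats::sd(v) / mean(v))
  }))
  rownames(out) <- NULL
  out
}
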