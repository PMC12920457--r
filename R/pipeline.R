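#' Configuration for the end-to-end calibration pipeline
#'
#' Bundles the stage configurations and the pipeline-level choices: which
#' transform forms are carried into wavelet decomposition, which dyadic
#' scales are scanned, and how the best model is chosen for attribution.
#' A single global `seed` drives every stochastic stage through derived
#' per-stage seeds.
#'
#' @param generator A [generator_config()] used when `spectra` are not
#'   supplied to [run_pipeline()].
#' @param mc An [mc_config()] for the outlier screen.
#' @param rf An [rf_config()] for every calibration fit.
#' @param cwt_sources Transform tags decomposed by CWT
#'   (default `c("R", "R'", "lg'R", "lg'(1/R)")`).
#' @param model_sources Transform tags entering the model comparison
#'   directly (default the same four tags).
#' @param scales Dyadic scale ladder (default `2^(1:10)`); scales
#'   exceeding the band count are dropped with a notice.
#' @param wavelet_id Mother wavelet (default `"gaus4"`).
#' @param alpha Significance level of the characteristic-band filter
#'   (default 0.01).
#' @param critical_r Optional explicit |r| cutoff override.
#' @param split_ratio Training fraction of the shared split (default 0.6).
#' @param overfit_margin Train-validation R2 gap above which a model is
#'   excluded from best-model selection (default 0.2).
#' @param shap_n_permutations,shap_max_background,shap_n_explain,shap_top_k
#'   Attribution-stage sizes: permutations (default 30), background rows
#'   (default 50), explained validation rows (default 30), reported top
#'   features (default 10).
#' @param output_dir Optional directory; when set, every stage writes its
#'   CSV artifacts there.
#' @param seed Global seed.
#' @param verbose Log stage progress (default TRUE).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            mc = mc_config(),
                            rf = rf_config(),
                            cwt_sources = c("R", "R'", "lg'R", "lg'(1/R)"),
                            model_sources = c("R", "R'", "lg'R", "lg'(1/R)"),
                            scales = 2^(1:10),
                            wavelet_id = "gaus4",
                            alpha = 0.01,
                            critical_r = NULL,
                            split_ratio = 0.6,
                            overfit_margin = 0.2,
                            shap_n_permutations = 30,
                            shap_max_background = 50,
                            shap_n_explain = 30,
                            shap_top_k = 10,
                            output_dir = NULL,
                            seed = 1L,
                            verbose = TRUE) {
  bad <- setdiff(c(cwt_sources, model_sources), transform_tags())
  if (length(bad) > 0) {
    stopf("unknown transform tag(s): %s", paste(bad, collapse = ", "))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full tannin-calibration pipeline
#'
#' Stages: load or generate scans -> average replicates -> Monte-Carlo
#' outlier screen and removal -> transform bank and per-transform
#' correlation summaries -> continuous wavelet decomposition of the
#' configured sources with per-scale correlation profiling and optimal
#' scale selection -> shared 6:4 split -> random-forest calibrations for
#' every (input definition, full/characteristic band mode) -> metric
#' comparison -> Shapley attribution of the best validation model.
#' Deterministic per global seed.
#'
#' @param config A [pipeline_config()].
#' @param spectra Optional pre-loaded `spectrum_set` of raw scans; by
#'   default the synthetic generator is run.
#' @param tannins Reference table matching `spectra` (required when
#'   `spectra` given).
#' @return A `pipeline_report` list with the per-stage artifacts:
#'   `outliers`, `transform_summary`, `scale_selection`, `split`,
#'   `set_description`, `comparison`, `best_input`, `attribution`,
#'   `attribution_tables`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), spectra = NULL,
                         tannins = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$verbose
  out <- config$output_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  save_csv <- function(df, name) {
    if (!is.null(out)) {
      utils::write.csv(df, file.path(out, name), row.names = FALSE)
    }
  }

  # --- stage 1: data ---
  if (is.null(spectra)) {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, 1)
    ds <- generate_dataset(gen)
    spectra <- ds$spectra
    tannins <- ds$tannins
    msgf(v, "[data] generated %d scans x %d bands",
         nrow(spectra$reflectance), length(spectra$wavenumbers))
  } else if (is.null(tannins)) {
    stopf("tannins must accompany supplied spectra")
  }
  avg <- average_replicates(spectra)
  msgf(v, "[average] %d samples x %d bands",
       nrow(avg$reflectance), length(avg$wavenumbers))

  # --- stage 2: Monte-Carlo outlier screen ---
  mc <- config$mc
  mc$seed <- derive_seed(config$seed, 2)
  outrep <- mc_outlier_scan(avg, tannins, mc)
  n_flagged <- sum(outrep$flagged)
  msgf(v, "[outliers] %d of %d samples flagged", n_flagged, nrow(outrep))
  save_csv(outrep, "outlier_report.csv")
  cleaned <- apply_outlier_removal(avg, tannins, outrep)
  avg <- cleaned$spectra
  tannins <- cleaned$tannins

  # --- stage 3: transform bank + per-transform correlation summaries ---
  bank <- transform_bank(avg)
  y <- tannins$tannin[match(avg$sample_id, tannins$sample_id)]
  profiles <- lapply(bank, function(tr) {
    pearson_profile(tr$values, y, alpha = config$alpha,
                    critical_r = config$critical_r, axis = tr$wavenumbers)
  })
  tr_summary <- do.call(rbind, lapply(names(profiles), function(tag) {
    cbind(transform = tag, summarize_profile(profiles[[tag]]))
  }))
  rownames(tr_summary) <- NULL
  msgf(v, "[transforms] 12-form bank profiled; NFB range %d..%d",
       min(tr_summary$NFB), max(tr_summary$NFB))
  save_csv(tr_summary, "transform_summary.csv")

  # --- stage 4: CWT + per-scale profiling + optimal scale ---
  n_bands_min <- min(vapply(bank[config$cwt_sources], function(tr)
    length(tr$wavenumbers), integer(1)))
  scales <- config$scales[config$scales <= n_bands_min]
  if (length(scales) < length(config$scales)) {
    msgf(v, "[cwt] dropped %d scale(s) exceeding the band count",
         length(config$scales) - length(scales))
  }
  cwt_stage <- lapply(config$cwt_sources, function(tag) {
    wf <- cwt_features(bank[[tag]], scales = scales,
                       wavelet_id = config$wavelet_id)
    profs <- lapply(wf$coefficients, function(mat) {
      pearson_profile(mat, y, alpha = config$alpha,
                      critical_r = config$critical_r,
                      axis = wf$wavenumbers)
    })
    sel <- select_optimal_scale(profs, scales = scales)
    msgf(v, "[cwt] %s_CWT optimal scale %d (mean |r| %.3f over %d bands)",
         tag, sel$scale,
         sel$table$mean_abs_r[sel$table$scale == sel$scale],
         sel$table$NFB[sel$table$scale == sel$scale])
    list(tag = tag, features = wf, profiles = profs, selection = sel)
  })
  names(cwt_stage) <- config$cwt_sources
  scale_tab <- do.call(rbind, lapply(cwt_stage, function(cs) {
    cbind(source = paste0(cs$tag, "_CWT"), cs$selection$table,
          optimal = cs$selection$table$scale == cs$selection$scale)
  }))
  rownames(scale_tab) <- NULL
  save_csv(scale_tab, "scale_selection.csv")

  # --- stage 5: shared split + set description ---
  split <- split_samples(avg$sample_id, ratio = config$split_ratio,
                         seed = derive_seed(config$seed, 3))
  setdesc <- describe_sets(tannins, split)
  msgf(v, "[split] %d train / %d validation",
       length(split$train_ids), length(split$val_ids))
  save_csv(setdesc, "set_description.csv")

  # --- stage 6: feature sets (input definition x band mode) ---
  feature_sets <- list()
  char_axes <- list()
  add_set <- function(name, mat, axis, mask) {
    colnames(mat) <- sprintf("wn%.1f", axis)
    rownames(mat) <- avg$sample_id
    feature_sets[[paste(name, "full")]] <<- mat
    if (sum(mask) > 0) {
      feature_sets[[paste(name, "characteristic")]] <<-
        mat[, mask, drop = FALSE]
      char_axes[[paste(name, "characteristic")]] <<- axis[mask]
    } else {
      msgf(v, "[features] %s: empty characteristic selection, skipped", name)
    }
    char_axes[[paste(name, "full")]] <<- axis
  }
  for (tag in config$model_sources) {
    add_set(tag, bank[[tag]]$values, bank[[tag]]$wavenumbers,
            profiles[[tag]]$selected)
  }
  for (tag in config$cwt_sources) {
    cs <- cwt_stage[[tag]]
    a <- cs$selection$scale
    prof <- cs$profiles[[as.character(a)]]
    add_set(sprintf("%s_CWT_%d", tag, a),
            cs$features$coefficients[[as.character(a)]],
            cs$features$wavenumbers, prof$selected)
  }

  # --- stage 7: model comparison ---
  rf <- config$rf
  rf$seed <- derive_seed(config$seed, 4)
  comparison <- compare_inputs(feature_sets, tannins, split, rf,
                               overfit_margin = config$overfit_margin,
                               verbose = v)
  save_csv(comparison$table, "model_comparison.csv")
  if (!is.null(out)) {
    for (nm in names(comparison$predictions)) {
      save_csv(comparison$predictions[[nm]],
               sprintf("predictions_%s.csv", gsub("[^A-Za-z0-9_]+", "_", nm)))
    }
  }

  # --- stage 8: best model + Shapley attribution ---
  val <- comparison$table[comparison$table$set == "validation", ]
  eligible <- val[!val$overfit, ]
  if (nrow(eligible) == 0) {
    msgf(v, "[best] every model exceeds the overfit margin; using all")
    eligible <- val
  }
  best_input <- eligible$input[which.max(eligible$RPD)]
  msgf(v, "[best] %s (validation RPD %.2f)", best_input,
       max(eligible$RPD))
  best_X <- feature_sets[[best_input]]
  bg_rows <- match(split$train_ids, rownames(best_X))
  ex_rows <- match(split$val_ids, rownames(best_X))
  n_ex <- min(config$shap_n_explain, length(ex_rows))
  ex_rows <- with_seed(derive_seed(config$seed, 5),
                       sample(ex_rows, n_ex))
  attribution <- shapley_attribute(
    comparison$models[[best_input]],
    background = best_X[bg_rows, , drop = FALSE],
    explain = best_X[ex_rows, , drop = FALSE],
    method = if (ncol(best_X) <= 12) "exact" else "sampling",
    n_permutations = config$shap_n_permutations,
    max_background = config$shap_max_background,
    seed = derive_seed(config$seed, 6))
  tables <- rank_and_export(attribution, top_k = config$shap_top_k,
                            seed = derive_seed(config$seed, 7),
                            feature_values = best_X[ex_rows, , drop = FALSE])
  save_csv(tables$ranking, "shap_ranking.csv")
  save_csv(tables$beeswarm, "shap_beeswarm.csv")
  save_csv(tables$waterfall, "shap_waterfall.csv")

  structure(list(
    outliers = outrep,
    transform_summary = tr_summary,
    scale_selection = scale_tab,
    split = split,
    set_description = setdesc,
    comparison = comparison,
    best_input = best_input,
    best_feature_axis = char_axes[[best_input]],
    attribution = attribution,
    attribution_tables = tables,
    n_samples_retained = nrow(avg$reflectance),
    config = config
  ), class = "pipeline_report")
}

#' Human-readable summary of a pipeline run
#'
#' Prints the per-transform characteristic-band table, the per-scale
#' mean |r| table with the chosen scales, the full model comparison and
#' the top attributed features, and returns them invisibly.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @return The list of summary tables, invisibly.
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  cat("== Outlier screen ==\n")
  cat(sprintf("%d of %d samples flagged and removed\n\n",
              sum(report$outliers$flagged), nrow(report$outliers)))
  cat("== Characteristic bands per transform ==\n")
  print(report$transform_summary, digits = 3)
  cat("\n== Wavelet scale selection (mean |r| criterion) ==\n")
  print(report$scale_selection[, c("source", "scale", "NFB",
                                   "mean_abs_r", "optimal")], digits = 3)
  cat("\n== Tannin distribution across sets ==\n")
  print(report$set_description, digits = 4)
  cat("\n== Model comparison ==\n")
  print(report$comparison$table, digits = 3)
  cat(sprintf("\nBest input: %s\n", report$best_input))
  cat("\n== Top attributed features (mean |phi|, mg/g) ==\n")
  print(report$attribution_tables$ranking, digits = 3)
  invisible(list(
    transform_summary = report$transform_summary,
    scale_selection = report$scale_selection,
    comparison = report$comparison$table,
    ranking = report$attribution_tables$ranking
  ))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "pipeline_report: %d samples retained, best input '%s'\n",
    x$n_samples_retained, x$best_input))
  invisible(x)
}
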