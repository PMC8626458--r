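#' Run a (feature set x model grid x split) experiment
#'
#' Features are extracted once per dataset, standardised, and every
#' requested classifier variant is trained and evaluated on every fold of
#' the split plan. Standardisation is leakage-free by default (fitted on
#' each fold's training rows and applied to its test rows); the `"global"`
#' mode standardises the whole feature table before splitting, matching the
#' protocol in which normalisation precedes the train/test split.
#'
#' @param ds An `fds_dataset`.
#' @param plan A `split_plan`; audited before use (a violation aborts the
#'   run).
#' @param models List of `model_spec`s (default: the full 30-variant
#'   [model_grid()]).
#' @param standardize `"train"` (default, leakage-free) or `"global"`.
#' @param feature_table Optional precomputed feature table (as from
#'   [featurize_dataset()], or an external extractor's output) with
#'   `trial_id`, `klass` and numeric feature columns; computed when `NULL`.
#' @param out_dir Optional directory; when given, the per-model results CSV
#'   and a run-metadata text file are written there (byte-reproducible
#'   under identical inputs).
#' @return List of class `fds_experiment`: `results` (one row per model
#'   with fold-mean Se/Sp, per-fold and pooled geometric means and the
#'   per-fold sd), `best` (highest pooled geometric mean, ties broken by
#'   grid order), `reports` (named list of `metrics_report`s) and the run
#'   settings.
#' @export
run_experiment <- function(ds, plan, models = model_grid(),
                           standardize = c("train", "global"),
                           feature_table = NULL, out_dir = NULL) {
  standardize <- match.arg(standardize)
  audit_split_plan(plan, ds)
  if (is.null(feature_table)) feature_table <- featurize_dataset(ds)
  meta_cols <- intersect(c("trial_id", "subject_id", "activity_code",
                           "klass", "category"), names(feature_table))
  fcols <- setdiff(names(feature_table), meta_cols)
  X <- as.matrix(feature_table[, fcols, drop = FALSE])
  rownames(X) <- feature_table$trial_id
  y <- stats::setNames(as_binary_labels(feature_table$klass),
                       feature_table$trial_id)

  if (standardize == "global") {
    Xg <- suppressWarnings(
      apply_standardization(X, fit_standardization(X)))
  }

  fold_sets <- lapply(plan$folds, function(f) {
    if (standardize == "train") {
      st <- suppressWarnings(fit_standardization(X[f$train, ,
                                                   drop = FALSE]))
      list(xtr = apply_standardization(X[f$train, , drop = FALSE], st),
           xte = apply_standardization(X[f$test, , drop = FALSE], st),
           ytr = y[f$train], yte = y[f$test])
    } else {
      list(xtr = Xg[f$train, , drop = FALSE],
           xte = Xg[f$test, , drop = FALSE],
           ytr = y[f$train], yte = y[f$test])
    }
  })

  reports <- list()
  rows <- list()
  for (mi in seq_along(models)) {
    spec <- models[[mi]]
    fold_metrics <- lapply(fold_sets, function(fs) {
      model <- suppressWarnings(fds_train(spec, fs$xtr, fs$ytr))
      evaluate_fold(fs$yte, predict(model, fs$xte))
    })
    rep <- aggregate_folds(fold_metrics)
    reports[[spec$id]] <- rep
    rows[[mi]] <- data.frame(
      model_id = spec$id, family = spec$family, label = spec$label,
      se = rep$se, sp = rep$sp, gmean_perfold = rep$gmean_perfold,
      gmean_pooled = rep$gmean_pooled, gmean_sd = rep$gmean_sd,
      n_undefined = rep$n_undefined, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  gp <- results$gmean_pooled
  best_i <- if (all(is.na(gp))) NA_integer_
            else which(gp == max(gp, na.rm = TRUE))[1]
  out <- structure(list(
    results = results,
    best = if (is.na(best_i)) NULL else results[best_i, ],
    best_spec = if (is.na(best_i)) NULL else models[[best_i]],
    reports = reports, strategy = plan$strategy,
    standardize = standardize, plan_metadata = plan$metadata),
    class = "fds_experiment")
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- exp$results
  for (col in c("se", "sp", "gmean_perfold", "gmean_pooled", "gmean_sd"))
    res[[col]] <- format_metric(res[[col]])
  utils::write.csv(res,
                   file.path(out_dir, sprintf("results_%s.csv",
                                              exp$strategy)),
                   row.names = FALSE, quote = FALSE)
  meta <- c(sprintf("strategy: %s", exp$strategy),
            sprintf("standardize: %s", exp$standardize),
            sprintf("%s: %s", names(exp$plan_metadata),
                    vapply(exp$plan_metadata, function(x)
                      paste(format(x), collapse = ","), "")))
  writeLines(meta, file.path(out_dir, sprintf("metadata_%s.txt",
                                              exp$strategy)))
  invisible(out_dir)
}

#' @export
print.fds_experiment <- function(x, ...) {
  cat(sprintf("<fds_experiment '%s': %d models>\n", x$strategy,
              nrow(x$results)))
  if (!is.null(x$best))
    cat(sprintf("  best: %s  Se %s  Sp %s  sqrt(Se*Sp) %s\n",
                x$best$label, format_metric(x$best$se),
                format_metric(x$best$sp),
                format_metric(x$best$gmean_pooled)))
  invisible(x)
}

#' Compare partition strategies on one dataset
#'
#' Runs the same model set under several split plans of the same dataset
#' and returns one row per strategy ranked by the best model's pooled
#' geometric mean — the comparison shape used to judge whether subject-wise
#' or characteristic-sorted partitions degrade a classifier relative to the
#' fair baseline.
#'
#' @param ds An `fds_dataset`.
#' @param plans Named list of `split_plan`s.
#' @param models List of `model_spec`s evaluated under every plan.
#' @param standardize Passed to [run_experiment()].
#' @return Data frame: strategy, best model label, Se, Sp, pooled and
#'   per-fold geometric means, sorted by decreasing pooled geometric mean.
#' @export
compare_strategies <- function(ds, plans, models = model_grid(),
                               standardize = "train") {
  if (is.null(names(plans)))
    names(plans) <- vapply(plans, `[[`, "", "strategy")
  rows <- lapply(names(plans), function(nm) {
    ex <- run_experiment(ds, plans[[nm]], models = models,
                         standardize = standardize)
    b <- ex$best
    data.frame(strategy = nm, model = b$label, se = b$se, sp = b$sp,
               gmean_pooled = b$gmean_pooled,
               gmean_perfold = b$gmean_perfold,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(-tab$gmean_pooled), , drop = FALSE]
}
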