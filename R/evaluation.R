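#' Confusion counts for fall detection
#'
#' Falls are the positive class: `tp` = falls detected, `fn` = falls
#' missed, `tn` = ADLs passed, `fp` = ADLs flagged as falls.
#'
#' @param y_true,y_pred Label vectors coercible to the `ADL`/`FALL` factor,
#'   equal length.
#' @return List of class `confusion_counts` with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as_binary_labels(y_true)
  y_pred <- as_binary_labels(y_pred)
  if (length(y_true) != length(y_pred))
    stop("confusion: label vectors differ in length")
  structure(list(
    tp = sum(y_true == "FALL" & y_pred == "FALL"),
    fn = sum(y_true == "FALL" & y_pred == "ADL"),
    tn = sum(y_true == "ADL" & y_pred == "ADL"),
    fp = sum(y_true == "ADL" & y_pred == "FALL")),
    class = "confusion_counts")
}

#' Sensitivity (recall on falls)
#'
#' The proportion of falls in the test subset that are correctly
#' identified, as a percentage. When the test set contains no falls the
#' metric is not computable and `NA` (rendered "n.c.") is returned — a
#' value, not an error.
#'
#' @param cc A `confusion_counts`.
#' @return Percentage in [0, 100], or `NA_real_`.
#' @export
sensitivity <- function(cc) {
  if (cc$tp + cc$fn == 0) return(NA_real_)
  100 * cc$tp / (cc$tp + cc$fn)
}

#' Specificity (true negative rate on ADLs)
#'
#' The ratio of ADLs not misinterpreted as falls, as a percentage;
#' `NA` ("n.c.") when the test set contains no ADLs.
#'
#' @param cc A `confusion_counts`.
#' @return Percentage in [0, 100], or `NA_real_`.
#' @export
specificity <- function(cc) {
  if (cc$tn + cc$fp == 0) return(NA_real_)
  100 * cc$tn / (cc$tn + cc$fp)
}

#' Geometric mean of sensitivity and specificity
#'
#' `sqrt(Se * Sp)`, on the same percent scale; the single global
#' performance figure balancing the two error types on unbalanced test
#' sets. Undefined inputs propagate.
#'
#' @param se,sp Percentages in [0, 100] or `NA`.
#' @return Percentage or `NA_real_`.
#' @export
geometric_mean <- function(se, sp) {
  if (is.na(se) || is.na(sp)) return(NA_real_)
  if (se < 0 || se > 100 || sp < 0 || sp > 100)
    stop("geometric_mean: inputs must lie in [0, 100]")
  sqrt(se * sp)
}

#' Metrics for one evaluated fold
#'
#' @param y_true,y_pred Test labels and predictions.
#' @return List with `se`, `sp`, `gmean` (possibly `NA`) and the
#'   `confusion` counts.
#' @export
evaluate_fold <- function(y_true, y_pred) {
  cc <- confusion(y_true, y_pred)
  se <- sensitivity(cc)
  sp <- specificity(cc)
  list(se = se, sp = sp, gmean = geometric_mean(se, sp), confusion = cc)
}

#' Aggregate per-fold metrics into a report
#'
#' Reports the arithmetic mean of per-fold Se, Sp and geometric mean, the
#' sample (n-1) standard deviation of the per-fold geometric means (0 for a
#' single fold, by convention), and the pooled convention
#' `sqrt(mean(Se) * mean(Sp))`. The two conventions generally differ
#' (Jensen gap); both are reported. Folds with an undefined metric are
#' excluded from that metric's aggregate and counted in `n_undefined`.
#'
#' @param fold_metrics List of per-fold results from [evaluate_fold()].
#' @return List of class `metrics_report`: `se`, `sp`, `gmean_perfold`,
#'   `gmean_pooled`, `gmean_sd`, `n_folds`, `n_undefined`, `per_fold`.
#' @export
aggregate_folds <- function(fold_metrics) {
  if (!length(fold_metrics)) stop("aggregate_folds: no folds")
  ses <- vapply(fold_metrics, `[[`, 0, "se")
  sps <- vapply(fold_metrics, `[[`, 0, "sp")
  gms <- vapply(fold_metrics, `[[`, 0, "gmean")
  mean_def <- function(x) if (all(is.na(x))) NA_real_
                          else mean(x, na.rm = TRUE)
  se <- mean_def(ses)
  sp <- mean_def(sps)
  gm_def <- gms[!is.na(gms)]
  gmean_sd <- if (length(gm_def) >= 2) stats::sd(gm_def)
              else if (length(gm_def) == 1) 0
              else NA_real_
  structure(list(
    se = se, sp = sp,
    gmean_perfold = mean_def(gms),
    gmean_pooled = if (is.na(se) || is.na(sp)) NA_real_
                   else geometric_mean(se, sp),
    gmean_sd = gmean_sd,
    n_folds = length(fold_metrics),
    n_undefined = sum(is.na(gms)),
    per_fold = fold_metrics),
    class = "metrics_report")
}

#' Render a metric with the "n.c." sentinel
#'
#' @param x Numeric (percent scale) possibly `NA`.
#' @param digits Decimal places (default 2, matching reported tables).
#' @return Character vector; `NA` renders as `"n.c."`.
#' @export
format_metric <- function(x, digits = 2) {
  ifelse(is.na(x), "n.c.", formatC(x, format = "f", digits = digits))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Se %s  Sp %s  sqrt(Se*Sp) %s (per-fold) / %s (pooled) +/- %s [%d fold(s), %d n.c.]\n",
    format_metric(x$se), format_metric(x$sp),
    format_metric(x$gmean_perfold), format_metric(x$gmean_pooled),
    format_metric(x$gmean_sd), x$n_folds, x$n_undefined))
  invisible(x)
}
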