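#' Confusion counts for +1/-1 labels
#'
#' @param y_true True labels (+1/-1).
#' @param y_pred Predicted labels (+1/-1).
#' @return Named integer vector `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred have different lengths")
  }
  stopifnot(all(y_true %in% c(-1, 1)), all(y_pred %in% c(-1, 1)))
  c(tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == -1 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == -1),
    tn = sum(y_true == -1 & y_pred == -1))
}

#' Precision, recall and F1 from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R). Any 0/0 yields `NaN`;
#' with `nan_to_zero = TRUE` (the default, and the convention used
#' throughout this package for fair comparison of classifiers that recall
#' no positives) `NaN` is reported as 0.
#'
#' @param counts Named vector from [confusion_counts()] (needs `tp`, `fp`,
#'   `fn`).
#' @param nan_to_zero Replace undefined values by 0.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts, nan_to_zero = TRUE) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f1 <- 2 * p * r / (p + r)
  out <- c(precision = p, recall = r, f1 = f1)
  if (nan_to_zero) out[is.nan(out)] <- 0
  out
}

#' Area under the ROC curve from decision values
#'
#' Rank-based (Mann-Whitney) AUC; tied scores contribute 1/2.
#'
#' @param y_true True labels (+1/-1), both classes present.
#' @param scores Real-valued decision scores (larger = more positive).
#' @return AUC in \[0, 1\]; `NaN` when only one class is present.
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(-1, 1)))
  np <- sum(y_true == 1)
  nn <- sum(y_true == -1)
  if (np == 0L || nn == 0L) return(NaN)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Aggregate per-term evaluation rows by annotation-size group
#'
#' Computes, per group: the number of terms whose F1 was undefined before
#' the NaN-to-zero substitution, the mean and variance of F1 (after
#' substitution) and the mean ROC score.
#'
#' @param per_term data.frame with columns `term`, `f1` (may contain
#'   `NaN`), `roc` (may contain `NA`/`NaN`), `group_label`.
#' @param var_type `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1).
#' @param group_levels Order of groups in the output; defaults to the
#'   order of first appearance.
#' @return data.frame with one row per group: `group_label`, `n`,
#'   `n_nan`, `mean_f1`, `var_f1`, `mean_roc`.
#' @export
aggregate_by_group <- function(per_term,
                               var_type = c("population", "sample"),
                               group_levels = NULL) {
  var_type <- match.arg(var_type)
  stopifnot(all(c("term", "f1", "group_label") %in% names(per_term)))
  if (is.null(per_term$roc)) per_term$roc <- NA_real_
  if (is.null(group_levels)) group_levels <- unique(per_term$group_label)
  rows <- lapply(group_levels, function(gl) {
    sub <- per_term[per_term$group_label == gl, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) {
      return(data.frame(group_label = gl, n = 0L, n_nan = 0L,
                        mean_f1 = NaN, var_f1 = NaN, mean_roc = NaN))
    }
    n_nan <- sum(is.nan(sub$f1))
    f1 <- ifelse(is.nan(sub$f1), 0, sub$f1)
    v <- if (var_type == "population") {
      mean((f1 - mean(f1))^2)
    } else if (n > 1L) {
      stats::var(f1)
    } else {
      NaN
    }
    data.frame(group_label = gl, n = n, n_nan = n_nan,
               mean_f1 = mean(f1), var_f1 = v,
               mean_roc = mean(sub$roc, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as TSV
#' @param report data.frame (per-term rows or grouped output of
#'   [aggregate_by_group()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
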