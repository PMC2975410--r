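#' Hold out a validation split from the enlarged positives and unlabeled set
#'
#' Draws `ceiling(fraction * |P|)` positives and `ceiling(fraction * |U|)`
#' unlabeled examples uniformly at random as the validation set used to
#' pick the representative negative set; the remainders are the training
#' portions.
#'
#' @param P Positive indices (typically the enlarged set, synthetics
#'   included).
#' @param U Unlabeled indices, disjoint from `P`.
#' @param fraction Held-out fraction in (0, 1); default 0.10.
#' @param seed Optional RNG seed.
#' @param exclude Indices (e.g. synthetic ids) never placed in the
#'   validation set; they stay in the training portion.
#' @return A `validation_split`: list with `v_pos`, `v_unl`, `train_pos`,
#'   `train_unl`.
#' @export
split_validation <- function(P, U, fraction = 0.1, seed = NULL,
                             exclude = integer()) {
  stopifnot(fraction > 0, fraction < 1, length(P) >= 2, length(U) >= 2,
            length(intersect(P, U)) == 0L)
  if (!is.null(seed)) set.seed(seed)
  pick <- function(set, n_total) {
    pool <- setdiff(set, exclude)
    n <- ceiling(fraction * n_total)
    if (n >= length(pool)) {
      stop("validation fraction leaves no training members")
    }
    sort(pool[sample.int(length(pool), n)])
  }
  v_pos <- pick(P, length(P))
  v_unl <- pick(U, length(U))
  structure(list(v_pos = v_pos, v_unl = v_unl,
                 train_pos = setdiff(P, v_pos),
                 train_unl = setdiff(U, v_unl)),
            class = "validation_split")
}

#' Initial negative set from a one-class boundary
#'
#' A one-class SVM is fit on the union of the (enlarged) positives and the
#' unlabeled training examples with outlier fraction `percent/100`
#' (default 10\%); the boundary covers most of the data, and unlabeled
#' points left outside it are far from the positive mass and taken as the
#' reliable initial negatives. If the boundary leaves no unlabeled point
#' outside, the fallback returns the `percent`\% of unlabeled points with
#' the smallest mean kernel similarity to the positives, with a warning.
#'
#' @param P Training positive indices.
#' @param U Training unlabeled indices.
#' @param K Kernel matrix covering `P` and `U`.
#' @param percent Target outlier percentage (one-class `nu` = percent/100).
#' @return Integer vector `N1` of initial negative indices, a nonempty
#'   subset of `U`.
#' @export
initial_negatives <- function(P, U, K, percent = 10) {
  stopifnot(percent > 0, percent < 100, length(U) >= 1)
  all_idx <- c(P, U)
  model <- train_one_class(K[all_idx, all_idx, drop = FALSE],
                           nu = percent / 100)
  dv <- decision_values(model, K[U, all_idx, drop = FALSE])
  n1 <- U[dv < 0]
  if (length(n1) == 0L) {
    warning("one-class boundary left no unlabeled point outside; ",
            "falling back to lowest mean similarity to positives")
    sim <- rowMeans(K[U, P, drop = FALSE])
    n_take <- max(1L, round(percent / 100 * length(U)))
    n1 <- U[order(sim, U)][seq_len(n_take)]
  }
  sort(n1)
}

#' Iteratively retrain the SVM to move the boundary toward the positives
#'
#' Starting from the initial negative set, repeatedly trains a two-class
#' SVM on positives vs current negatives, predicts the remaining unlabeled
#' examples, takes the most confidently negative ones (up to
#' `m * |P|`, keeping class sizes in check) as the next predicted-negative
#' set, and carries forward only the negative support vectors as
#' representatives of the earlier negatives. Iteration stops when the
#' remaining unlabeled pool shrinks below `stop_ratio * |P|` (few
#' remaining unlabeled examples are increasingly likely to be hidden
#' positives) or when no new negatives are predicted.
#'
#' @param P Training positive indices.
#' @param U Training unlabeled indices; must contain `N1`.
#' @param N1 Initial negative set (subset of `U`), e.g. from
#'   [initial_negatives()].
#' @param K Kernel matrix covering all indices.
#' @param m Cap multiplier: at most `m * |P|` newly predicted negatives
#'   per iteration (default 3).
#' @param stop_ratio Loop continues while `|U'| >= stop_ratio * |P|`
#'   (default 4).
#' @param C Soft-margin cost for the per-iteration classifiers (default
#'   1; hyperparameter search is deferred to the final training stage).
#' @return An `iteration_trace`: list of per-iteration records, each with
#'   `iteration`, `model`, `train_index` (order used to train),
#'   `negatives` (the set the classifier was trained against),
#'   `n_pred`, `n_svs`, `u_remaining` (pool size when the iteration
#'   started).
#' @export
iterate_negatives <- function(P, U, N1, K, m = 3, stop_ratio = 4, C = 1) {
  stopifnot(m >= 1, stop_ratio > 0, length(intersect(P, U)) == 0L,
            all(N1 %in% U))
  u <- setdiff(U, N1)
  negs <- N1
  records <- list()
  i <- 1L
  while (length(u) >= stop_ratio * length(P)) {
    tr <- c(P, negs)
    labels <- c(rep(1, length(P)), rep(-1, length(negs)))
    model <- tryCatch(
      train_binary(K[tr, tr, drop = FALSE], labels, C = C),
      error = function(e) e)
    if (inherits(model, "error")) {
      warning("classifier training failed at iteration ", i, ": ",
              conditionMessage(model), "; returning trace so far")
      break
    }
    dv <- decision_values(model, K[u, tr, drop = FALSE])
    neg_pred <- u[dv < 0]
    ord <- neg_pred[order(dv[dv < 0], neg_pred)]
    n2 <- utils::head(ord, floor(m * length(P)))
    neg_svs <- negs[model$sv_index[model$sv_labels == -1] - length(P)]
    records[[i]] <- list(iteration = i, model = model, train_index = tr,
                         negatives = negs, n_pred = length(n2),
                         n_svs = length(neg_svs),
                         u_remaining = length(u))
    if (length(n2) == 0L) break
    negs <- sort(union(n2, neg_svs))
    u <- setdiff(u, n2)
    i <- i + 1L
  }
  structure(list(records = records, P = P, U = U,
                 final_unlabeled = u, final_negatives = negs),
            class = "iteration_trace")
}

#' @export
print.iteration_trace <- function(x, ...) {
  cat("iteration_trace: ", length(x$records), " iterations, |P| = ",
      length(x$P), ", final |U'| = ", length(x$final_unlabeled), "\n",
      sep = "")
  invisible(x)
}

#' Export an iteration trace as a data.frame
#' @param trace An `iteration_trace`.
#' @param split Optional `validation_split`; when given together with
#'   `K`, a per-iteration validation F1 column is included.
#' @param K Kernel matrix (needed with `split`).
#' @return data.frame with one row per iteration.
#' @export
trace_summary <- function(trace, split = NULL, K = NULL) {
  stopifnot(inherits(trace, "iteration_trace"))
  df <- do.call(rbind, lapply(trace$records, function(r) {
    data.frame(iteration = r$iteration, n_negatives = length(r$negatives),
               n_pred = r$n_pred, n_svs = r$n_svs,
               u_remaining = r$u_remaining)
  }))
  if (!is.null(split) && !is.null(K) && length(trace$records) > 0L) {
    df$validation_f1 <- validation_f1s(trace, split, K)
  }
  df
}

validation_f1s <- function(trace, split, K) {
  v <- c(split$v_pos, split$v_unl)
  y <- c(rep(1, length(split$v_pos)), rep(-1, length(split$v_unl)))
  vapply(trace$records, function(r) {
    pred <- predict_labels(r$model, K[v, r$train_index, drop = FALSE])
    unname(precision_recall_f1(confusion_counts(y, pred))["f1"])
  }, numeric(1))
}

#' Select the representative negative set by validation F1
#'
#' Every classifier recorded during the iteration classifies the held-out
#' validation set (held-out positives labelled +1, held-out unlabeled
#' labelled -1); the negative set paired with the best-F1 classifier is
#' the representative negative set. Ties go to the earliest iteration; if
#' every F1 is 0, the last iteration's set is returned with a warning.
#'
#' @param trace A nonempty `iteration_trace`.
#' @param split A `validation_split`.
#' @param K Kernel matrix covering all indices.
#' @return List with `rn` (the representative negative index set),
#'   `best_iteration`, and `f1` (per-iteration validation F1 vector).
#' @export
select_representative_negatives <- function(trace, split, K) {
  stopifnot(inherits(trace, "iteration_trace"),
            inherits(split, "validation_split"))
  if (length(trace$records) == 0L) stop("iteration trace is empty")
  f1 <- validation_f1s(trace, split, K)
  if (all(f1 == 0)) {
    warning("all validation F1 are 0; returning the last iteration's set")
    best <- length(trace$records)
  } else {
    best <- which.max(f1)   # first maximum = earliest iteration
  }
  list(rn = trace$records[[best]]$negatives, best_iteration = best,
       f1 = f1)
}
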