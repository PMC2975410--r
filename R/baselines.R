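#' Baseline: all unlabeled examples treated as negatives
#'
#' Trains a two-class SVM with the labelled positives against the whole
#' unlabeled set labelled negative. With few positives this is heavily
#' imbalanced and the hidden positives inside the unlabeled set act as
#' label noise.
#'
#' @param P Positive indices.
#' @param U Unlabeled indices (disjoint from `P`).
#' @param K Kernel matrix covering `P` and `U`.
#' @param C Soft-margin cost.
#' @return A `pu_fit` (see [predict_unknowns()]).
#' @export
twoclass_train <- function(P, U, K, C = 1) {
  stopifnot(length(P) >= 1, length(U) >= 1,
            length(intersect(P, U)) == 0L)
  tr <- c(P, U)
  model <- train_binary(K[tr, tr, drop = FALSE],
                        c(rep(1, length(P)), rep(-1, length(U))), C = C)
  pu_fit("twoclass", model, tr, n_original = nrow(K))
}

#' Baseline: balanced random negatives
#'
#' Samples `|P|` unlabeled examples uniformly without replacement as the
#' negative class and trains on the balanced set. Avoids imbalance but
#' uses very few training examples, so it is prone to over-fitting and to
#' run-to-run variability.
#'
#' @inheritParams twoclass_train
#' @param seed Optional RNG seed for the negative sample.
#' @return A `pu_fit`.
#' @export
twoclassbal_train <- function(P, U, K, C = 1, seed = NULL) {
  stopifnot(length(U) >= length(P), length(P) >= 1,
            length(intersect(P, U)) == 0L)
  if (!is.null(seed)) set.seed(seed)
  negs <- sort(U[sample.int(length(U), length(P))])
  tr <- c(P, negs)
  model <- train_binary(K[tr, tr, drop = FALSE],
                        c(rep(1, length(P)), rep(-1, length(negs))),
                        C = C)
  fit <- pu_fit("twoclassbal", model, tr, n_original = nrow(K))
  fit$negatives <- negs
  fit
}

#' Greedy maximum-dispersion selection of initial negatives
#'
#' Greedy approximation of the (NP-hard) criterion of picking unlabeled
#' points that are far from the positives and far from each other: the
#' first pick maximizes the distance to the positive set (distance of a
#' point to a set = minimum over members); each later pick maximizes the
#' minimum distance to the positives plus the picks so far. Ties go to
#' the smaller index.
#'
#' @param distances Symmetric distance matrix covering `P` and `U`.
#' @param P Positive indices.
#' @param U Unlabeled candidate indices.
#' @param size Number of points to select.
#' @return Integer vector of selected indices (in pick order).
#' @export
max_min_dispersion_select <- function(distances, P, U, size) {
  stopifnot(size >= 1, size <= length(U))
  ref <- P
  sel <- integer(0)
  dmin <- apply(distances[U, ref, drop = FALSE], 1L, min)
  for (s in seq_len(size)) {
    pick <- U[order(-dmin, U)][1L]
    sel <- c(sel, pick)
    dmin <- pmin(dmin, distances[U, pick])
    dmin[U %in% sel] <- -Inf
  }
  sel
}

#' Baseline: positive-sample-only learning (simplified)
#'
#' A reduced form of the PSoL strategy: the initial negative set is a
#' greedy maximum-dispersion selection of unlabeled points far from the
#' positives and from each other, the negative set is then expanded by
#' the same iterative SVM retraining used by the main pipeline, and the
#' classifier of the last iteration is returned. This implements only
#' the two-step outline of the original method, not its full algorithm.
#'
#' @inheritParams twoclass_train
#' @param m Per-iteration cap multiplier (default 3).
#' @param stop_ratio Expansion stops when the remaining unlabeled pool is
#'   below `stop_ratio * |P|` (default 4).
#' @param init_size Size of the greedy initial negative set (default
#'   `|P|`).
#' @return A `pu_fit`; its `trace` element carries the expansion trace.
#' @export
psol_lite_train <- function(P, U, K, C = 1, m = 3, stop_ratio = 4,
                            init_size = NULL) {
  stopifnot(length(P) >= 1, length(U) >= 2,
            length(intersect(P, U)) == 0L)
  if (is.null(init_size)) init_size <- length(P)
  init_size <- min(init_size, length(U))
  D <- kernel_induced_distances(K)
  n0 <- sort(max_min_dispersion_select(D, P, U, init_size))
  trace <- iterate_negatives(P, U, n0, K, m = m, stop_ratio = stop_ratio,
                             C = C)
  if (length(trace$records) > 0L) {
    last <- trace$records[[length(trace$records)]]
    fit <- pu_fit("psol_lite", last$model, last$train_index,
                  n_original = nrow(K))
  } else {
    tr <- c(P, n0)
    model <- train_binary(K[tr, tr, drop = FALSE],
                          c(rep(1, length(P)), rep(-1, length(n0))),
                          C = C)
    fit <- pu_fit("psol_lite", model, tr, n_original = nrow(K))
  }
  fit$initial_negatives <- n0
  fit$trace <- trace
  fit
}

# Shared wrapper for a trained strategy: enough to score any point for
# which kernel rows against the original genes exist.
pu_fit <- function(strategy, model, train_index, n_original,
                   weights = NULL) {
  structure(list(strategy = strategy, model = model,
                 train_index = train_index, n_original = n_original,
                 weights = weights),
            class = "pu_fit")
}

#' @export
print.pu_fit <- function(x, ...) {
  cat("pu_fit: strategy '", x$strategy, "', ", length(x$train_index),
      " training examples\n", sep = "")
  invisible(x)
}
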