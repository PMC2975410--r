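#' Simulate a positive-unlabeled dataset
#'
#' Positives are drawn from a single Gaussian; negatives from a mixture of
#' `n_neg_components` Gaussian components whose centres sit at distance
#' `separation` from the positive centre in random directions, modelling
#' the diversity of the negative class. A random subset of the positives
#' is labelled; the rest hide among the unlabeled examples, reproducing
#' the annotation structure of gene-function data where most positives
#' are unrecorded.
#'
#' @param n_labeled_pos Number of labelled positives (>= 2 so neighbour
#'   steps work downstream).
#' @param n_hidden_pos Number of positives hidden in the unlabeled set.
#' @param n_neg Number of true negatives.
#' @param d Feature dimension.
#' @param separation Distance between the positive centre and each
#'   negative component centre (0 = indistinguishable classes).
#' @param noise_sd Within-component standard deviation (per coordinate).
#' @param n_neg_components Number of negative mixture components
#'   (default 3).
#' @param seed RNG seed; the whole draw is deterministic given it.
#' @return A `pu_dataset`: list with `features` (n x d matrix, rownames
#'   `g1..gn`), `truth` (+1/-1, hidden ground truth), `P` (labelled
#'   positive indices), `U` (all remaining indices), and the call
#'   parameters.
#' @export
simulate_pu_dataset <- function(n_labeled_pos = 20, n_hidden_pos = 80,
                                n_neg = 900, d = 10, separation = 4,
                                noise_sd = 1, n_neg_components = 3,
                                seed = 1) {
  stopifnot(n_labeled_pos >= 2, n_hidden_pos >= 0, n_neg >= 0, d >= 1,
            separation >= 0, noise_sd > 0, n_neg_components >= 1)
  set.seed(seed)
  n_pos <- n_labeled_pos + n_hidden_pos
  n <- n_pos + n_neg
  centers <- matrix(0, n_neg_components, d)
  for (cidx in seq_len(n_neg_components)) {
    dir <- stats::rnorm(d)
    centers[cidx, ] <- dir / sqrt(sum(dir^2)) * separation
  }
  X <- matrix(stats::rnorm(n * d, sd = noise_sd), n, d)
  comp <- rep_len(seq_len(n_neg_components), n_neg)
  if (n_neg > 0L) {
    X[n_pos + seq_len(n_neg), ] <-
      X[n_pos + seq_len(n_neg), , drop = FALSE] + centers[comp, , drop = FALSE]
  }
  dimnames(X) <- list(sprintf("g%d", seq_len(n)),
                      sprintf("f%d", seq_len(d)))
  truth <- c(rep(1, n_pos), rep(-1, n_neg))
  P <- sort(sample.int(n_pos, n_labeled_pos))
  structure(list(features = X, truth = truth, P = P,
                 U = setdiff(seq_len(n), P),
                 params = list(n_labeled_pos = n_labeled_pos,
                               n_hidden_pos = n_hidden_pos, n_neg = n_neg,
                               d = d, separation = separation,
                               noise_sd = noise_sd,
                               n_neg_components = n_neg_components,
                               seed = seed)),
            class = "pu_dataset")
}

#' @export
print.pu_dataset <- function(x, ...) {
  cat("pu_dataset: ", nrow(x$features), " examples (",
      length(x$P), " labelled positive, ",
      sum(x$truth == 1) - length(x$P), " hidden positive, ",
      sum(x$truth == -1), " negative), d = ", ncol(x$features), "\n",
      sep = "")
  invisible(x)
}

#' Linear Gram kernel of a feature matrix
#' @param X Feature matrix with row names.
#' @return `X %*% t(X)` with dimnames set.
#' @export
linear_kernel <- function(X) {
  K <- tcrossprod(X)
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' Simulate an Erdos-Renyi interaction graph
#'
#' @param n Number of nodes (ids `g1..gn`).
#' @param edge_prob Independent edge probability in \[0, 1\].
#' @param seed RNG seed.
#' @return An `interaction_graph`.
#' @export
simulate_interaction_graph <- function(n, edge_prob, seed = 1) {
  stopifnot(n >= 1, edge_prob >= 0, edge_prob <= 1)
  set.seed(seed)
  ids <- sprintf("g%d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < edge_prob
  interaction_graph(cbind(ids[pairs[keep, 1L]], ids[pairs[keep, 2L]]),
                    ids = ids)
}

#' Simulate an expression matrix with missing values
#'
#' iid standard-Gaussian entries with an iid Bernoulli missingness mask;
#' rows that come out fully missing are re-masked so every gene keeps at
#' least one observation.
#'
#' @param n Number of genes (rows, ids `g1..gn`).
#' @param d Number of conditions (columns `c1..cd`).
#' @param missing_rate Missingness probability in \[0, 1).
#' @param seed RNG seed.
#' @return Numeric matrix with `NA` for missing entries.
#' @export
simulate_expression_matrix <- function(n, d, missing_rate = 0, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1, n >= 1, d >= 1)
  set.seed(seed)
  x <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(sprintf("g%d", seq_len(n)),
                              sprintf("c%d", seq_len(d))))
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * d) < missing_rate, n, d)
    full <- which(rowSums(mask) == d)
    while (length(full) > 0L) {
      mask[full, ] <- matrix(stats::runif(length(full) * d) < missing_rate,
                             length(full), d)
      full <- full[rowSums(mask[full, , drop = FALSE]) == d]
    }
    x[mask] <- NA_real_
  }
  x
}

#' Write a simulated PU dataset to a directory as TSV files
#'
#' Writes `features.tsv` (genes x features), `truth.tsv` (gene, label),
#' `positives.txt` and `unlabeled.txt` (one gene id per line).
#'
#' @param ds A `pu_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pu_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "pu_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(ds$features, file.path(dir, "features.tsv"))
  utils::write.table(data.frame(gene = rownames(ds$features),
                                label = ds$truth),
                     file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(rownames(ds$features)[ds$P], file.path(dir, "positives.txt"))
  writeLines(rownames(ds$features)[ds$U], file.path(dir, "unlabeled.txt"))
  invisible(dir)
}
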