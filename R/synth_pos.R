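#' Distances induced by a kernel
#'
#' Treats the kernel as an inner product and returns the implied Euclidean
#' distances \eqn{d(i,j) = \sqrt{K_{ii} + K_{jj} - 2K_{ij}}} (clamped at
#' zero before the square root). Lets k-nearest-neighbour steps run when
#' only a kernel, not explicit coordinates, is available.
#'
#' @param K Square symmetric kernel matrix.
#' @param indices Optional index vector restricting the result.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
kernel_induced_distances <- function(K, indices = NULL) {
  validate_kernel_matrix(K)
  if (!is.null(indices)) K <- K[indices, indices, drop = FALSE]
  d <- diag(K)
  d2 <- outer(d, d, "+") - 2 * K
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  diag(D) <- 0
  D
}

#' Number of neighbours used for a given enlargement amount
#'
#' An enlargement amount of `p` percent creates `p/100` synthetic examples
#' per positive, one along the segment to each of `n = round(p/100)`
#' randomly chosen nearest neighbours; e.g. 500\% enlargement with k = 10
#' uses 5 of the 10 nearest neighbours. `n` is clamped to `[0, k]`.
#'
#' @param amount_percent Non-negative enlargement amount in percent
#'   (multiples of 100 in standard use).
#' @param k Neighbourhood size.
#' @return Integer number of neighbours, `0` meaning no synthesis.
#' @export
neighbor_count_for_amount <- function(amount_percent, k) {
  stopifnot(length(amount_percent) == 1L, length(k) == 1L, k >= 1)
  if (amount_percent < 0) stop("enlargement amount must be non-negative")
  n <- round(amount_percent / 100)
  as.integer(min(max(n, 0), k))
}

#' Create synthetic positive examples by convex combination
#'
#' For each positive example `e`, its `k` nearest neighbours within the
#' positive set are found (ties broken by ascending index), `n` of them
#' are chosen uniformly at random without replacement, and for each chosen
#' neighbour `e'` one synthetic example
#' \eqn{\tilde e = \alpha e + (1-\alpha)e'} with
#' \eqn{\alpha \sim U(0,1)} is recorded. Any point on the open segment
#' between two examples strictly inside the positive half-space of a
#' separating hyperplane is itself strictly inside it, so synthetic
#' examples are likely positives and carry little negative noise.
#'
#' @param P Integer vector of positive indices (into the rows of the
#'   kernel/feature matrix the distances were computed from).
#' @param distances Symmetric distance matrix covering all indices in `P`
#'   (e.g. from [kernel_induced_distances()] or `as.matrix(dist(X))`).
#' @param n Number of neighbours per positive (synthesis amount /100).
#' @param k Neighbourhood size (default 10); clamped to `|P| - 1` with a
#'   warning when larger.
#' @param seed Optional RNG seed; when `NULL` the current RNG state is
#'   used.
#' @return An `enlarged_positives` object: list with `original` (= `P`),
#'   and `combinations`, a data.frame with columns `synthetic_id`,
#'   `parent_a`, `parent_b`, `alpha` (exactly `n * |P|` rows).
#' @export
make_synthetic_examples <- function(P, distances, n, k = 10, seed = NULL) {
  P <- as.integer(P)
  stopifnot(n >= 0, k >= 1, !anyDuplicated(P))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    comb <- data.frame(synthetic_id = character(), parent_a = integer(),
                       parent_b = integer(), alpha = numeric(),
                       stringsAsFactors = FALSE)
    return(structure(list(original = P, combinations = comb),
                     class = "enlarged_positives"))
  }
  if (length(P) < 2L) stop("need at least 2 positives to synthesize")
  if (n > k) stop("n (", n, ") must not exceed k (", k, ")")
  if (k > length(P) - 1L) {
    warning("k = ", k, " exceeds |P| - 1 = ", length(P) - 1L,
            "; clamping")
    k <- length(P) - 1L
  }
  recs <- vector("list", length(P))
  for (ii in seq_along(P)) {
    e <- P[ii]
    others <- P[P != e]
    ord <- others[order(distances[e, others], others)]
    nn <- ord[seq_len(k)]
    if (n <= length(nn)) {
      sel <- nn[sample.int(length(nn), n)]
    } else {
      warning("requested ", n, " neighbours but only ", length(nn),
              " available; cycling with replacement")
      sel <- rep(nn[sample.int(length(nn))], length.out = n)
    }
    alpha <- stats::runif(n)
    while (any(alpha <= 0 | alpha >= 1)) {       # measure-zero guard
      bad <- alpha <= 0 | alpha >= 1
      alpha[bad] <- stats::runif(sum(bad))
    }
    recs[[ii]] <- data.frame(parent_a = rep(e, n), parent_b = sel,
                             alpha = alpha)
  }
  comb <- do.call(rbind, recs)
  comb <- data.frame(synthetic_id = sprintf("syn_%d", seq_len(nrow(comb))),
                     comb, stringsAsFactors = FALSE)
  rownames(comb) <- NULL
  structure(list(original = P, combinations = comb),
            class = "enlarged_positives")
}

#' @export
print.enlarged_positives <- function(x, ...) {
  cat("enlarged_positives: |P| = ", length(x$original), ", ",
      nrow(x$combinations), " synthetic combinations\n", sep = "")
  invisible(x)
}

# s x n0 weight matrix mapping original points to synthetic combinations
combination_weights <- function(enlarged, n_original) {
  comb <- enlarged$combinations
  W <- matrix(0, nrow(comb), n_original)
  if (nrow(comb) > 0L) {
    W[cbind(seq_len(nrow(comb)), comb$parent_a)] <- comb$alpha
    W[cbind(seq_len(nrow(comb)), comb$parent_b)] <-
      W[cbind(seq_len(nrow(comb)), comb$parent_b)] + (1 - comb$alpha)
  }
  rownames(W) <- comb$synthetic_id
  W
}

#' Explicit coordinates of synthetic examples
#'
#' @param X Feature matrix whose rows the combination parents index.
#' @param enlarged An `enlarged_positives` object.
#' @return Matrix of synthetic-example coordinates (one row per
#'   combination).
#' @export
synthetic_features <- function(X, enlarged) {
  stopifnot(inherits(enlarged, "enlarged_positives"), is.matrix(X))
  combination_weights(enlarged, nrow(X)) %*% X
}

#' Extend a kernel matrix with synthetic convex combinations
#'
#' Synthetic points exist only as feature-space combinations
#' \eqn{s = \alpha e + (1-\alpha)e'}; when the kernel represents an inner
#' product, rows and columns for them follow by bilinearity:
#' \eqn{K(s, x) = \alpha K(e, x) + (1-\alpha)K(e', x)} and likewise for
#' pairs of synthetic points. The extension of a PSD kernel stays PSD
#' (combinations live in the span of the original points).
#'
#' @param K Kernel matrix covering all parent indices.
#' @param enlarged An `enlarged_positives` object.
#' @param check_psd If `TRUE` (default), warn when the smallest eigenvalue
#'   of `K` is below `-1e-6` (the bilinear extension then has no
#'   inner-product reading), and proceed.
#' @return Kernel matrix of size `nrow(K) + n_synthetic`, original block
#'   unchanged, synthetic ids appended to the dimnames.
#' @export
extend_kernel_with_synthetics <- function(K, enlarged, check_psd = TRUE) {
  validate_kernel_matrix(K)
  stopifnot(inherits(enlarged, "enlarged_positives"))
  comb <- enlarged$combinations
  if (nrow(comb) == 0L) return(K)
  if (max(comb$parent_a, comb$parent_b) > nrow(K)) {
    stop("combination parents exceed kernel dimension")
  }
  if (check_psd) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6) {
      warning("kernel is not PSD (min eigenvalue ", format(min(ev)),
              "); bilinear extension proceeds anyway")
    }
  }
  W <- combination_weights(enlarged, nrow(K))
  cross <- W %*% K                       # s x n0
  syn <- cross %*% t(W)                  # s x s
  syn <- (syn + t(syn)) / 2
  out <- rbind(cbind(K, t(cross)), cbind(cross, syn))
  ids <- c(rownames(K), comb$synthetic_id)
  dimnames(out) <- list(ids, ids)
  out
}

#' Write a synthetic-combination manifest as TSV
#' @param enlarged An `enlarged_positives` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_manifest <- function(enlarged, path) {
  utils::write.table(enlarged$combinations, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
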