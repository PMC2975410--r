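#' Weighted k-nearest-neighbour imputation of missing expression values
#'
#' For each missing entry, the k nearest gene rows (Euclidean distance over
#' co-observed columns, scaled by the fraction of co-observed columns) that
#' have the entry's column observed contribute a weighted mean, weights
#' proportional to 1/distance. Observed entries are never altered. When no
#' candidate neighbour has the column observed, the column mean over all
#' observed genes is used.
#'
#' @param expr Numeric genes-x-conditions matrix, `NA` for missing entries;
#'   every row must have at least one observed value.
#' @param k Number of neighbours (default 10, the convention of the
#'   standard KNN-imputation tool for microarray data).
#' @return The matrix with all `NA` entries filled in.
#' @export
knn_impute <- function(expr, k = 10) {
  stopifnot(is.matrix(expr), is.numeric(expr), k >= 1)
  if (!anyNA(expr)) return(expr)
  obs <- !is.na(expr)
  if (any(rowSums(obs) == 0L)) {
    stop("row ", which(rowSums(obs) == 0L)[1L], " is entirely missing")
  }
  col_means <- colMeans(expr, na.rm = TRUE)
  out <- expr
  need <- which(rowSums(!obs) > 0L)
  n <- nrow(expr)
  for (i in need) {
    d <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      if (j == i) next
      co <- obs[i, ] & obs[j, ]
      nco <- sum(co)
      if (nco == 0L) next
      d[j] <- sqrt(sum((expr[i, co] - expr[j, co])^2) / (nco / ncol(expr)))
    }
    for (col in which(!obs[i, ])) {
      cand <- which(!is.na(d) & obs[, col])
      if (length(cand) == 0L) {
        out[i, col] <- col_means[col]
        next
      }
      ord <- cand[order(d[cand], cand)]
      nb <- utils::head(ord, k)
      dd <- d[nb]
      if (any(dd == 0)) {
        out[i, col] <- mean(expr[nb[dd == 0], col])
      } else {
        w <- 1 / dd
        out[i, col] <- sum(w * expr[nb, col]) / sum(w)
      }
    }
  }
  out
}

#' Gaussian (RBF) kernel on expression profiles
#'
#' \eqn{K_{ij} = \exp(-\gamma \lVert x_i - x_j \rVert^2)}. The default
#' width \eqn{\gamma = 2} follows the usual setting for fused genomic
#' kernels.
#'
#' @param expr Complete numeric matrix (genes x conditions); impute first
#'   if values are missing.
#' @param gamma Positive kernel width.
#' @param standardize If `TRUE`, columns are centred and scaled to unit
#'   variance before distances are computed (default `FALSE`: raw values).
#' @return Kernel matrix with unit diagonal, named by `rownames(expr)`.
#' @export
gaussian_kernel <- function(expr, gamma = 2, standardize = FALSE) {
  stopifnot(is.matrix(expr), gamma > 0)
  if (anyNA(expr)) stop("expression matrix contains missing values; impute first")
  if (standardize) expr <- scale(expr)
  sq <- rowSums(expr^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(expr)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(expr), rownames(expr))
  K
}

#' Diffusion kernel on an interaction graph
#'
#' \eqn{K = \exp(\beta H)} with \eqn{H = A - D} the negative graph
#' Laplacian, computed by dense symmetric eigendecomposition. Rows of the
#' result sum to 1 for any graph and \eqn{\beta}, and the kernel is
#' symmetric positive semi-definite.
#'
#' @param g An `interaction_graph` (see [interaction_graph()]) or a
#'   symmetric 0/1 adjacency matrix with dimnames.
#' @param beta Positive diffusion constant (default 2).
#' @return Kernel matrix over the graph's node ids.
#' @export
diffusion_kernel <- function(g, beta = 2) {
  stopifnot(beta > 0)
  A <- if (inherits(g, "interaction_graph")) graph_adjacency(g) else g
  validate_kernel_matrix(A)
  H <- A - diag(rowSums(A))
  eig <- eigen(H, symmetric = TRUE)
  K <- eig$vectors %*% (exp(beta * eig$values) * t(eig$vectors))
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(A)
  K
}

#' Double-centre a kernel matrix
#'
#' \eqn{K_c = K - 1\bar r - \bar c 1 + \bar g}, so all row and column sums
#' of the result are zero. Idempotent.
#'
#' @param K Square symmetric matrix.
#' @return Centred matrix of the same shape.
#' @export
center_kernel <- function(K) {
  validate_kernel_matrix(K)
  rm <- rowMeans(K)
  gm <- mean(K)
  Kc <- K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), rm) + gm
  dimnames(Kc) <- dimnames(K)
  Kc
}

#' Cosine-normalize a kernel matrix to unit diagonal
#'
#' \eqn{K_n[i,j] = K[i,j]/\sqrt{K[i,i]K[j,j]}}. Diagonal entries in
#' `(0, ridge]` are lifted to `ridge` before division; nonpositive
#' diagonals are an error.
#'
#' @param K Square symmetric matrix with positive diagonal.
#' @param ridge Small positive guard for near-zero diagonals.
#' @return Normalized matrix with unit diagonal.
#' @export
normalize_kernel <- function(K, ridge = 1e-10) {
  validate_kernel_matrix(K)
  d <- diag(K)
  d[d > 0 & d <= ridge] <- ridge
  if (any(d <= 0)) {
    bad <- rownames(K)[which(d <= 0)[1L]]
    stop("nonpositive self-similarity for gene '", bad,
         "'; cannot normalize")
  }
  s <- 1 / sqrt(d)
  Kn <- K * tcrossprod(s)
  diag(Kn) <- 1
  dimnames(Kn) <- dimnames(K)
  Kn
}

#' Combine per-source kernels into a sum kernel
#'
#' Each kernel is double-centred, then cosine-normalized, then the
#' processed kernels are summed entrywise. Centring removes per-source
#' offsets and normalization equalizes scale so no single data source
#' dominates the fused kernel.
#'
#' @param kernels List of square symmetric matrices over the same gene ids
#'   in the same order.
#' @param ridge Passed to [normalize_kernel()].
#' @return The summed kernel matrix.
#' @export
combine_kernels <- function(kernels, ridge = 1e-10) {
  stopifnot(is.list(kernels), length(kernels) >= 1L)
  ids <- rownames(kernels[[1L]])
  for (i in seq_along(kernels)) {
    validate_kernel_matrix(kernels[[i]])
    if (!identical(rownames(kernels[[i]]), ids)) {
      bad <- which(rownames(kernels[[i]]) != ids)[1L]
      stop("kernel ", i, " id mismatch at position ", bad, ": '",
           rownames(kernels[[i]])[bad], "' vs '", ids[bad], "'")
    }
  }
  proc <- lapply(kernels, function(K) normalize_kernel(center_kernel(K),
                                                       ridge = ridge))
  Reduce(`+`, proc)
}
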