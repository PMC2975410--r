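# Shared fixture builders; everything is generated in code at test time.

# named square matrix with gene ids g1..gn
named_matrix <- function(values, n = nrow(values)) {
  ids <- sprintf("g%d", seq_len(n))
  dimnames(values) <- list(ids, ids)
  values
}

random_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  named_matrix((A + t(A)) / 2)
}

random_psd_kernel <- function(n, d = n + 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n)
  named_matrix(tcrossprod(X))
}

# two well-separated 2-d clouds: n1 points near (0,0), n2 near `offset`
two_cloud_features <- function(n1, n2, offset = c(6, 6), sd = 0.5,
                               seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * 2, 0, sd), n1),
             sweep(matrix(rnorm(n2 * 2, 0, sd), n2), 2, offset, "+"))
  rownames(X) <- sprintf("g%d", seq_len(n1 + n2))
  X
}

# benchmark kernel used for the simulation suite
suite_kernel <- function(ds) {
  gaussian_kernel(ds$features, gamma = 1 / ncol(ds$features))
}

expect_symmetric <- function(K, tol = 1e-10) {
  expect_lt(max(abs(K - t(K))), tol)
}
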