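test_that("knn imputation recovers duplicates and leaves complete data alone", {
  x <- simulate_expression_matrix(5, 4, missing_rate = 0, seed = 1)
  expect_identical(knn_impute(x), x)

  # two identical rows, one masked entry, k=1: exact recovery
  y <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  y["b", 3] <- NA
  expect_equal(unname(knn_impute(y, k = 1)["b", 3]), 3)

  # fully missing row is an error
  z <- rbind(a = c(1, NA), b = c(NA, NA))
  expect_error(knn_impute(z), "missing")
})

# straightforward independent re-implementation: for each missing entry,
# recompute the scaled co-observed distance to every other row and take the
# 1/d-weighted mean over the k nearest rows observing that column
brute_knn_impute <- function(x, k) {
  out <- x
  d_tot <- ncol(x)
  for (i in seq_len(nrow(x))) for (col in seq_len(ncol(x))) {
    if (!is.na(x[i, col])) next
    ds <- sapply(seq_len(nrow(x)), function(j) {
      if (j == i) return(NA_real_)
      co <- !is.na(x[i, ]) & !is.na(x[j, ])
      if (!any(co)) return(NA_real_)
      sqrt(sum((x[i, co] - x[j, co])^2) / (sum(co) / d_tot))
    })
    cand <- which(!is.na(ds) & !is.na(x[, col]))
    if (length(cand) == 0) { out[i, col] <- mean(x[, col], na.rm = TRUE); next }
    nb <- cand[order(ds[cand], cand)][seq_len(min(k, length(cand)))]
    w <- 1 / ds[nb]
    out[i, col] <- if (any(ds[nb] == 0)) mean(x[nb[ds[nb] == 0], col]) else
      sum(w * x[nb, col]) / sum(w)
  }
  out
}

test_that("knn imputation matches a brute-force oracle entry by entry", {
  for (seed in 1:4) {
    x <- simulate_expression_matrix(5 + 3 * seed, 4 + seed,
                                    missing_rate = 0.15, seed = seed)
    for (k in c(2, 10)) {
      expect_equal(knn_impute(x, k = k), brute_knn_impute(x, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("gaussian kernel has the exponential form and is PSD", {
  X <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 0))
  K <- gaussian_kernel(X, gamma = 2)
  expect_equal(K["a", "c"], 1)           # identical points
  expect_equal(K["a", "b"], exp(-2))     # squared distance 1, gamma 2
  expect_symmetric(K)

  set.seed(3)
  Xr <- matrix(rnorm(18), 6, 3); rownames(Xr) <- sprintf("g%d", 1:6)
  Kr <- gaussian_kernel(Xr, gamma = 2)
  expect_gte(min(eigen(Kr, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_error(gaussian_kernel(rbind(a = c(1, NA))), "missing")
})

test_that("diffusion kernel matches the 2-node closed form and is stochastic", {
  # edgeless graph: exp(0) = I
  g0 <- interaction_graph(matrix(character(), 0, 2), ids = c("a", "b", "c"))
  expect_equal(unname(diffusion_kernel(g0, beta = 2)), diag(3))

  # single edge: eigendecomposition of H = [[-1,1],[1,-1]] gives
  # K = [[(1+e^-2b)/2, (1-e^-2b)/2], ...]
  g1 <- interaction_graph(matrix(c("a", "b"), 1, 2))
  for (beta in c(0.5, 1, 2)) {
    K <- diffusion_kernel(g1, beta = beta)
    expect_equal(K["a", "a"], (1 + exp(-2 * beta)) / 2, tolerance = 1e-10)
    expect_equal(K["a", "b"], (1 - exp(-2 * beta)) / 2, tolerance = 1e-10)
  }

  # rows sum to one and PSD on random graphs
  for (seed in 1:3) {
    g <- simulate_interaction_graph(12, 0.2, seed = seed)
    K <- diffusion_kernel(g, beta = 2)
    expect_equal(unname(rowSums(K)), rep(1, 12), tolerance = 1e-8)
    expect_symmetric(K, tol = 1e-8)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("kernel centring zeroes margins and is idempotent", {
  Kc <- center_kernel(named_matrix(matrix(7, 4, 4)))
  expect_equal(unname(Kc), matrix(0, 4, 4))

  K <- random_symmetric(5, seed = 9)
  C1 <- center_kernel(K)
  expect_lt(max(abs(rowSums(C1))), 1e-10)
  expect_lt(max(abs(colSums(C1))), 1e-10)
  expect_equal(center_kernel(C1), C1, tolerance = 1e-10)
})

test_that("kernel normalization yields unit diagonal and is idempotent", {
  expect_equal(normalize_kernel(named_matrix(diag(3))),
               named_matrix(diag(3)))
  K <- named_matrix(matrix(c(4, 2, 2, 1), 2))
  expect_equal(unname(normalize_kernel(K)), matrix(1, 2, 2))
  for (seed in 1:3) {
    Kr <- random_psd_kernel(6, seed = seed)
    Kn <- normalize_kernel(Kr)
    expect_equal(unname(diag(Kn)), rep(1, 6))
    expect_equal(normalize_kernel(Kn), Kn, tolerance = 1e-10)
  }
  bad <- named_matrix(diag(c(1, 0, 2)))
  expect_error(normalize_kernel(bad), "g2")
})

test_that("kernel combination centres, normalizes, then sums", {
  K <- random_psd_kernel(5, seed = 2)
  single <- combine_kernels(list(K))
  expect_equal(single, normalize_kernel(center_kernel(K)))
  expect_equal(combine_kernels(list(K, K)), 2 * single)

  ks <- lapply(1:3, function(s) random_psd_kernel(6, seed = s))
  comb <- combine_kernels(ks)
  expect_symmetric(comb)
  expect_gte(min(eigen(comb, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  K2 <- K
  rownames(K2) <- colnames(K2) <- rev(rownames(K))
  expect_error(combine_kernels(list(K, K2)), "mismatch")
})
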