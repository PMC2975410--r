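test_that("binary training separates a separable toy and flips with labels", {
  X <- two_cloud_features(10, 10, offset = c(8, 8), seed = 2)
  K <- linear_kernel(X)
  y <- c(rep(1, 10), rep(-1, 10))
  m <- train_binary(K, y, C = 1)
  expect_equal(unname(predict_labels(m, K)), y)  # zero training error

  m2 <- train_binary(K, -y, C = 1)
  expect_equal(decision_values(m2, K), -decision_values(m, K),
               tolerance = 1e-6)
  expect_error(train_binary(K, rep(1, 20)), "both classes")
})

test_that("stored duals reproduce the solver's decision values", {
  set.seed(4)
  X <- rbind(matrix(rnorm(30, 1), 15), matrix(rnorm(30, -1), 15))
  y <- c(rep(1, 15), rep(-1, 15))
  K <- tcrossprod(X); dimnames(K) <- list(NULL, NULL)
  Kn <- K; rownames(Kn) <- colnames(Kn) <- sprintf("g%d", 1:30)
  for (C in c(0.1, 1, 10)) {
    m <- train_binary(Kn, y, C = C)
    ours <- decision_values(m, Kn)
    # oracle: refit with the solver directly on the eigen-embedding and
    # read its decision values
    eig <- eigen(Kn, symmetric = TRUE)
    emb <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)))
    fit <- e1071::svm(emb, factor(y, levels = c(-1, 1)), kernel = "linear",
                      cost = C, scale = FALSE)
    dv <- attr(predict(fit, emb, decision.values = TRUE),
               "decision.values")
    s <- if (strsplit(colnames(dv), "/")[[1]][1] == "1") 1 else -1
    expect_equal(unname(ours), s * as.numeric(dv), tolerance = 1e-8)
  }
})

test_that("one-class boundary excludes roughly the nu fraction", {
  set.seed(6)
  X <- matrix(rnorm(200), 100, 2)
  rownames(X) <- sprintf("g%d", 1:100)
  K <- gaussian_kernel(X, gamma = 0.5)
  m <- train_one_class(K, nu = 0.1)
  out <- sum(decision_values(m, K) < 0)
  expect_gte(out, 5)
  expect_lte(out, 20)

  # outlier count is non-decreasing in nu
  outs <- sapply(c(0.05, 0.15, 0.3, 0.5),
                 function(nu) sum(decision_values(train_one_class(K, nu),
                                                  K) < 0))
  expect_true(all(diff(outs) >= 0))

  expect_error(train_one_class(named_matrix(matrix(1, 4, 4))), "degenerate")
})

test_that("duplicating the sample does not move the one-class boundary", {
  set.seed(8)
  X <- matrix(rnorm(80), 40, 2)
  rownames(X) <- sprintf("g%d", 1:40)
  K <- gaussian_kernel(X, gamma = 0.5)
  Kdup <- gaussian_kernel(rbind(X, X), gamma = 0.5)
  m1 <- train_one_class(K, nu = 0.2)
  m2 <- train_one_class(Kdup, nu = 0.2)
  d1 <- decision_values(m1, K)
  d2 <- decision_values(m2, Kdup[1:40, , drop = FALSE])
  # decisions agree to solver precision; inlier/outlier calls can only
  # differ inside the numerical boundary band
  expect_gt(stats::cor(d1, d2), 0.999)
  clear <- abs(d1) > 1e-3
  expect_true(all(sign(d1[clear]) == sign(d2[clear])))
})

test_that("grid search selects within the grid and nails separable data", {
  X <- two_cloud_features(12, 12, offset = c(9, 9), seed = 3)
  K <- linear_kernel(X)
  y <- c(rep(1, 12), rep(-1, 12))
  gs <- grid_search_train(K, y, C_grid = c(0.5, 2), folds = 3, seed = 1)
  expect_true(gs$best_params$C %in% c(0.5, 2))
  expect_equal(max(gs$cv_table$mean_f1), 1.0)

  # single-point grid is chosen trivially
  gs1 <- grid_search_train(K, y, C_grid = 4, folds = 3, seed = 1)
  expect_equal(gs1$best_params$C, 4)

  # invariant to grid ordering
  set.seed(9)
  gs_a <- grid_search_train(K, y, C_grid = c(8, 0.5, 2), folds = 3,
                            seed = 7)
  gs_b <- grid_search_train(K, y, C_grid = c(0.5, 2, 8), folds = 3,
                            seed = 7)
  expect_equal(gs_a$best_params, gs_b$best_params)
  expect_equal(gs_a$cv_table, gs_b$cv_table)
})

test_that("rbf mode grids both cost and width on explicit features", {
  X <- two_cloud_features(15, 15, offset = c(4, 4), sd = 0.8, seed = 5)
  y <- c(rep(1, 15), rep(-1, 15))
  gs <- grid_search_train(X, y, C_grid = c(1, 10),
                          gamma_grid = c(0.01, 0.1, 1), folds = 3,
                          mode = "rbf", seed = 2)
  expect_true(gs$best_params$gamma %in% c(0.01, 0.1, 1))
  expect_equal(nrow(gs$cv_table), 6L)
  expect_equal(gs$model$kernel_mode, "rbf")
  # decision values work from stored support features alone
  expect_length(decision_values(gs$model, X[1:3, , drop = FALSE]), 3L)
})

test_that("models survive a JSON round-trip", {
  X <- two_cloud_features(8, 8, offset = c(6, 6), seed = 10)
  K <- linear_kernel(X)
  y <- c(rep(1, 8), rep(-1, 8))
  m <- train_binary(K, y, C = 2)
  p <- withr::local_tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  expect_equal(decision_values(m2, K), decision_values(m, K),
               tolerance = 1e-10)
})
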