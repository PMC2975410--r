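test_that("validation split counts, determinism and partition", {
  P <- 1:50; U <- 51:550
  sp <- split_validation(P, U, fraction = 0.1, seed = 4)
  expect_length(sp$v_pos, 5L)
  expect_length(sp$v_unl, 50L)
  expect_setequal(c(sp$v_pos, sp$train_pos), P)
  expect_setequal(c(sp$v_unl, sp$train_unl), U)
  expect_length(intersect(sp$v_pos, sp$train_pos), 0L)

  sp2 <- split_validation(P, U, fraction = 0.1, seed = 4)
  expect_identical(sp, sp2)

  # excluded members never enter validation
  sp3 <- split_validation(P, U, fraction = 0.1, seed = 4, exclude = 1:40)
  expect_true(all(sp3$v_pos > 40))

  expect_error(split_validation(1:2, U, fraction = 0.9), "training")
})

test_that("one-class initial negatives are the points far from the positive mass", {
  # dense bounded cloud of positives plus unlabeled at the origin (a
  # uniform disk, so it has no stray tail points); 40 diffuse unlabeled
  # points scattered far away
  set.seed(12)
  disk <- t(replicate(160, {
    ang <- runif(1, 0, 2 * pi)
    1.5 * sqrt(runif(1)) * c(cos(ang), sin(ang))
  }))
  X <- rbind(disk,
             t(replicate(40, {
               ang <- runif(1, 0, 2 * pi)
               runif(1, 6, 12) * c(cos(ang), sin(ang))
             })))
  rownames(X) <- sprintf("g%d", 1:200)
  K <- gaussian_kernel(X, gamma = 0.25)
  P <- 1:60                       # labelled positives, origin cloud
  U <- 61:200                     # 100 origin-cloud + 40 scattered far
  n1 <- initial_negatives(P, U, K, percent = 10)
  expect_true(all(n1 %in% U))
  expect_length(intersect(n1, P), 0L)
  # picks live in the far scatter, up to boundary-grazing disk-edge
  # points whose decision value sits at solver precision
  expect_gte(mean(n1 > 160), 0.9)
  expect_gte(sum(n1 > 160), 10)
  expect_lte(length(n1), 30)
})

test_that("iteration respects the cap, shrinks the pool and terminates", {
  for (seed in 1:3) {
    ds <- simulate_pu_dataset(n_labeled_pos = 15, n_hidden_pos = 20,
                              n_neg = 265, d = 6, separation = 4,
                              seed = seed)
    K <- suite_kernel(ds)
    sp <- split_validation(ds$P, ds$U, 0.1, seed = seed)
    n1 <- initial_negatives(sp$train_pos, sp$train_unl, K)
    tr <- iterate_negatives(sp$train_pos, sp$train_unl, n1, K,
                            m = 3, stop_ratio = 4)
    expect_gt(length(tr$records), 0L)
    smry <- trace_summary(tr)
    expect_true(all(smry$n_pred <= 3 * length(sp$train_pos)))
    expect_true(all(diff(smry$u_remaining) < 0))
    for (r in tr$records) {
      expect_length(intersect(r$negatives, sp$train_pos), 0L)
      expect_true(all(r$negatives %in% ds$U))
    }
    # termination: final pool below the stop threshold or no progress
    expect_true(length(tr$final_unlabeled) <
                  4 * length(sp$train_pos) ||
                  tr$records[[length(tr$records)]]$n_pred == 0)
  }
})

test_that("iteration with an already-small pool records nothing", {
  ds <- simulate_pu_dataset(n_labeled_pos = 20, n_hidden_pos = 0,
                            n_neg = 60, d = 4, seed = 2)
  K <- suite_kernel(ds)
  n1 <- ds$U[1:10]
  tr <- iterate_negatives(ds$P, ds$U, n1, K, m = 3, stop_ratio = 4)
  expect_length(tr$records, 0L)  # 50 remaining < 4 * 20
})

test_that("representative set selection maximizes validation F1", {
  ds <- simulate_pu_dataset(n_labeled_pos = 15, n_hidden_pos = 20,
                            n_neg = 265, d = 6, separation = 5, seed = 7)
  K <- suite_kernel(ds)
  sp <- split_validation(ds$P, ds$U, 0.1, seed = 7)
  n1 <- initial_negatives(sp$train_pos, sp$train_unl, K)
  tr <- iterate_negatives(sp$train_pos, sp$train_unl, n1, K)
  sel <- select_representative_negatives(tr, sp, K)
  expect_equal(sel$best_iteration,
               which.max(sel$f1))  # earliest maximum
  expect_setequal(sel$rn, tr$records[[sel$best_iteration]]$negatives)
  expect_length(intersect(sel$rn, ds$P), 0L)
  expect_true(all(sel$rn %in% ds$U))

  # single-iteration trace returns its set
  tr1 <- tr; tr1$records <- tr$records[1]
  sel1 <- select_representative_negatives(tr1, sp, K)
  expect_setequal(sel1$rn, tr$records[[1]]$negatives)

  expect_error(select_representative_negatives(
    structure(list(records = list()), class = "iteration_trace"), sp, K),
    "empty")
})

test_that("iterations tighten the boundary without degrading the hidden-positive signal", {
  # as closer negatives enter the training set the boundary contracts
  # toward the enlarged positives, so hidden-positive decision values can
  # only drift downward; the ranking of hidden positives against true
  # negatives must survive that contraction
  tightened <- 0L
  ranking_kept <- 0L
  n_runs <- 10L
  for (seed in seq_len(n_runs)) {
    ds <- simulate_pu_dataset(n_labeled_pos = 15, n_hidden_pos = 30,
                              n_neg = 255, d = 2, separation = 5,
                              seed = seed)
    K <- suite_kernel(ds)
    sp <- split_validation(ds$P, ds$U, 0.1, seed = seed)
    n1 <- initial_negatives(sp$train_pos, sp$train_unl, K)
    tr <- iterate_negatives(sp$train_pos, sp$train_unl, n1, K,
                            m = 1, stop_ratio = 2)
    if (length(tr$records) < 2) { n_runs <- n_runs - 1L; next }
    hidden <- setdiff(which(ds$truth == 1), ds$P)
    negs <- which(ds$truth == -1)
    mh <- vapply(tr$records, function(r)
      mean(decision_values(r$model, K[hidden, r$train_index,
                                      drop = FALSE])),
      numeric(1))
    auc <- vapply(tr$records, function(r) {
      dv <- decision_values(r$model, K[c(hidden, negs), r$train_index,
                                       drop = FALSE])
      roc_auc(c(rep(1, length(hidden)), rep(-1, length(negs))), dv)
    }, numeric(1))
    if (mh[length(mh)] <= mh[1] + 1e-9) tightened <- tightened + 1L
    if (auc[length(auc)] >= auc[1] - 0.05) ranking_kept <- ranking_kept + 1L
  }
  expect_gte(tightened / n_runs, 0.8)
  expect_gte(ranking_kept / n_runs, 0.8)
})
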