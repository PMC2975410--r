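#' Configuration for the positive-unlabeled training pipeline
#'
#' Collects every tunable of the three training stages with its default:
#' the per-group enlargement schedule (number of synthetic examples per
#' positive, chosen by positive-set size), neighbourhood size `k`, the
#' one-class outlier percentage, the iteration cap multiplier `m`, the
#' stop ratio, the validation fraction, the hyperparameter grids of the
#' final stage, and the master seed.
#'
#' @param k Neighbourhood size for synthesis (default 10).
#' @param m Per-iteration cap multiplier (default 3).
#' @param stop_ratio Iteration stops when the unlabeled pool drops below
#'   `stop_ratio` times the positive-set size (default 4).
#' @param validation_fraction Held-out fraction for representative-set
#'   selection (default 0.10).
#' @param one_class_percent Outlier percentage of the initial one-class
#'   boundary (default 10).
#' @param iteration_C Soft-margin cost of the per-iteration classifiers
#'   (default 1).
#' @param C_grid,gamma_grid,folds Final-stage grid search (see
#'   [grid_search_train()]).
#' @param schedule data.frame with columns `min_positives` and `times`:
#'   enlargement times for a positive set whose size falls in
#'   `[min_positives[i], min_positives[i+1])`. The default follows the
#'   per-annotation-size-group schedule 4/2/1/0 for sizes `[0,60)`,
#'   `[60,100)`, `[100,300)`, `[300,Inf)`.
#' @param exclude_synthetics_from_validation If `TRUE`, the validation
#'   positives are drawn from the original positives only (guards against
#'   synthetic children of held-out parents leaking into validation);
#'   default `FALSE`: the validation set is drawn from the enlarged set.
#' @param seed Master RNG seed; every random step of a run derives from
#'   it.
#' @return A list of class `spe_rne_config`.
#' @export
spe_rne_config <- function(k = 10, m = 3, stop_ratio = 4,
                           validation_fraction = 0.1,
                           one_class_percent = 10,
                           iteration_C = 1,
                           C_grid = 2^seq(-5, 15, by = 2),
                           gamma_grid = 2^seq(-15, 3, by = 2),
                           folds = 5,
                           schedule = data.frame(
                             min_positives = c(0, 60, 100, 300),
                             times = c(4, 2, 1, 0)),
                           exclude_synthetics_from_validation = FALSE,
                           seed = 1) {
  stopifnot(is.data.frame(schedule),
            all(c("min_positives", "times") %in% names(schedule)),
            !is.unsorted(schedule$min_positives, strictly = TRUE))
  structure(list(k = k, m = m, stop_ratio = stop_ratio,
                 validation_fraction = validation_fraction,
                 one_class_percent = one_class_percent,
                 iteration_C = iteration_C,
                 C_grid = C_grid, gamma_grid = gamma_grid, folds = folds,
                 schedule = schedule,
                 exclude_synthetics_from_validation =
                   exclude_synthetics_from_validation,
                 seed = seed),
            class = "spe_rne_config")
}

#' Enlargement times for a positive-set size
#'
#' Looks up the schedule of a [spe_rne_config()]: by default 4 synthetic
#' examples per positive below 60 positives, 2 in `[60,100)`, 1 in
#' `[100,300)` and none at 300 or more.
#'
#' @param n_pos Number of positives.
#' @param schedule Schedule data.frame (see [spe_rne_config()]).
#' @return Integer number of synthetic examples per positive.
#' @export
enlargement_times <- function(n_pos, schedule = spe_rne_config()$schedule) {
  stopifnot(n_pos >= 0)
  as.integer(schedule$times[findInterval(n_pos, schedule$min_positives)])
}

#' Train a classifier from positives and unlabeled examples
#'
#' Runs the three stages on a precomputed kernel: (1) the positive set is
#' enlarged with synthetic convex combinations, the amount chosen from
#' the positive-set size via the configured schedule, and the kernel is
#' extended to the synthetic points by bilinearity; (2) a validation
#' split is held out, a one-class boundary yields the initial negatives,
#' the boundary is moved toward the positives by iterative retraining,
#' and the representative negative set RN is the one whose classifier
#' maximizes validation F1; (3) the final classifier is grid-searched on
#' the enlarged positives versus RN.
#'
#' @param K Kernel matrix over all genes (training and others).
#' @param P Labelled positive indices.
#' @param U Unlabeled indices used for negative extraction (disjoint from
#'   `P`).
#' @param config A [spe_rne_config()].
#' @return A `pu_fit` with extra elements: `enlarged`, `split`, `trace`,
#'   `rn` (representative negatives), `selection` (per-iteration
#'   validation F1), `best_params`, `cv_table` and `manifest` (named
#'   character vector recording every parameter and set size of the run).
#' @export
run_spe_rne <- function(K, P, U, config = spe_rne_config()) {
  stopifnot(inherits(config, "spe_rne_config"),
            length(P) >= 2, length(U) >= 2,
            length(intersect(P, U)) == 0L)
  validate_kernel_matrix(K)
  set.seed(config$seed)
  n0 <- nrow(K)

  # Stage 1: synthetic enlargement
  times <- enlargement_times(length(P), config$schedule)
  n_nb <- neighbor_count_for_amount(100 * times, config$k)
  if (n_nb > 0L) {
    D <- kernel_induced_distances(K)
    enlarged <- make_synthetic_examples(P, D, n_nb, k = config$k)
    K_ext <- extend_kernel_with_synthetics(K, enlarged, check_psd = FALSE)
    syn_idx <- n0 + seq_len(nrow(enlarged$combinations))
  } else {
    enlarged <- make_synthetic_examples(P, NULL, 0L)
    K_ext <- K
    syn_idx <- integer(0)
  }
  P_tilde <- c(P, syn_idx)

  # Stage 2: representative negative extraction
  split <- split_validation(P_tilde, U, config$validation_fraction,
                            exclude = if
                            (config$exclude_synthetics_from_validation)
                              syn_idx else integer())
  n1 <- initial_negatives(split$train_pos, split$train_unl, K_ext,
                          percent = config$one_class_percent)
  trace <- iterate_negatives(split$train_pos, split$train_unl, n1, K_ext,
                             m = config$m, stop_ratio = config$stop_ratio,
                             C = config$iteration_C)
  if (length(trace$records) > 0L) {
    sel <- select_representative_negatives(trace, split, K_ext)
    rn <- sel$rn
  } else {
    warning("unlabeled pool too small for iterative extraction; ",
            "using the initial one-class negatives")
    sel <- NULL
    rn <- n1
  }

  # Stage 3: grid-searched final classifier on enlarged positives vs RN
  tr <- c(P_tilde, rn)
  labels <- c(rep(1, length(P_tilde)), rep(-1, length(rn)))
  gs <- grid_search_train(K_ext[tr, tr, drop = FALSE], labels,
                          C_grid = config$C_grid, folds = config$folds,
                          mode = "precomputed")

  fit <- pu_fit("spe_rne", gs$model, tr, n_original = n0,
                weights = if (length(syn_idx) > 0L)
                  combination_weights(enlarged, n0) else NULL)
  fit$enlarged <- enlarged
  fit$split <- split
  fit$trace <- trace
  fit$rn <- rn
  fit$selection <- sel
  fit$best_params <- gs$best_params
  fit$cv_table <- gs$cv_table
  fit$manifest <- c(
    seed = config$seed, n_genes = n0, n_positives = length(P),
    enlargement_times = times, neighbors_used = n_nb, k = config$k,
    n_synthetic = length(syn_idx), n_enlarged = length(P_tilde),
    n_unlabeled = length(U),
    validation_fraction = config$validation_fraction,
    n_validation_pos = length(split$v_pos),
    n_validation_unl = length(split$v_unl),
    one_class_percent = config$one_class_percent,
    n_initial_negatives = length(n1), m = config$m,
    stop_ratio = config$stop_ratio, iteration_C = config$iteration_C,
    n_iterations = length(trace$records),
    best_iteration = if (is.null(sel)) NA else sel$best_iteration,
    n_representative_negatives = length(rn),
    folds = config$folds, best_C = gs$best_params$C,
    n_training = length(tr))
  fit
}

#' Score unknown genes with a trained strategy
#'
#' @param fit A `pu_fit` from [run_spe_rne()] or one of the baseline
#'   trainers.
#' @param K_rows Kernel rows of the query genes against all original
#'   genes (`n_query x n_original`); typically `K[query, , drop = FALSE]`.
#' @return data.frame with columns `decision` and `label` (+1/-1), one
#'   row per query gene (rownames preserved).
#' @export
predict_unknowns <- function(fit, K_rows) {
  stopifnot(inherits(fit, "pu_fit"), is.matrix(K_rows))
  if (ncol(K_rows) != fit$n_original) {
    stop("query kernel rows must cover all ", fit$n_original,
         " original genes")
  }
  full <- if (!is.null(fit$weights)) {
    cbind(K_rows, K_rows %*% t(fit$weights))
  } else {
    K_rows
  }
  dv <- decision_values(fit$model, full[, fit$train_index, drop = FALSE])
  data.frame(decision = dv, label = ifelse(dv > 0, 1, -1),
             row.names = rownames(K_rows))
}

#' Evaluate one strategy on one seed under the known-gene protocol
#'
#' Holds out 20\% of the positives and 20\% of the unlabeled examples,
#' trains the strategy on the remainder, and scores the held-out genes
#' (held-out positives labelled +1, held-out unlabeled -1) with F1 under
#' the NaN-to-zero convention. When hidden ground truth is supplied, a
#' ROC score over the held-out unlabeled genes (hidden positives vs true
#' negatives) is also computed from the decision values.
#'
#' @param K Kernel matrix.
#' @param P Labelled positive indices.
#' @param U Unlabeled indices.
#' @param strategy One of `"spe_rne"`, `"twoclass"`, `"twoclassbal"`,
#'   `"psol_lite"`.
#' @param seed Seed for the hold-out draw and all strategy randomness.
#' @param config A [spe_rne_config()] (supplies C and the pipeline
#'   settings; its `seed` is overridden by `seed`).
#' @param truth Optional +1/-1 hidden ground-truth vector over all genes.
#' @param holdout_fraction Fraction held out from each category
#'   (default 0.2).
#' @return One-row data.frame: `strategy`, `seed`, `f1`, `precision`,
#'   `recall`, `roc` (NA without truth), `f1_undefined` (logical: was F1
#'   0/0 before substitution).
#' @export
evaluate_strategy <- function(K, P, U, strategy, seed,
                              config = spe_rne_config(), truth = NULL,
                              holdout_fraction = 0.2) {
  set.seed(seed)
  hp <- sort(P[sample.int(length(P), ceiling(holdout_fraction * length(P)))])
  hu <- sort(U[sample.int(length(U), ceiling(holdout_fraction * length(U)))])
  P_tr <- setdiff(P, hp)
  U_tr <- setdiff(U, hu)
  cfg <- config
  cfg$seed <- seed
  fit <- switch(strategy,
    spe_rne = run_spe_rne(K, P_tr, U_tr, cfg),
    twoclass = twoclass_train(P_tr, U_tr, K, C = cfg$iteration_C),
    twoclassbal = twoclassbal_train(P_tr, U_tr, K, C = cfg$iteration_C,
                                    seed = seed),
    psol_lite = psol_lite_train(P_tr, U_tr, K, C = cfg$iteration_C,
                                m = cfg$m, stop_ratio = cfg$stop_ratio),
    stop("unknown strategy '", strategy, "'"))
  held <- c(hp, hu)
  y <- c(rep(1, length(hp)), rep(-1, length(hu)))
  pred <- predict_unknowns(fit, K[held, , drop = FALSE])
  cc <- confusion_counts(y, pred$label)
  prf_raw <- precision_recall_f1(cc, nan_to_zero = FALSE)
  prf <- precision_recall_f1(cc)
  roc <- NA_real_
  if (!is.null(truth)) {
    pu <- predict_unknowns(fit, K[hu, , drop = FALSE])
    roc <- roc_auc(truth[hu], pu$decision)
  }
  data.frame(strategy = strategy, seed = seed,
             f1 = unname(prf["f1"]), precision = unname(prf["precision"]),
             recall = unname(prf["recall"]), roc = roc,
             f1_undefined = is.nan(prf_raw[["f1"]]))
}

#' Compare negative-selection strategies across seeds
#'
#' Runs [evaluate_strategy()] for every strategy x seed combination on
#' one dataset and appends per-strategy summary statistics.
#'
#' @param K Kernel matrix.
#' @param P,U Labelled positive / unlabeled index sets.
#' @param strategies Character vector of strategy names.
#' @param seeds Integer vector of seeds.
#' @param config A [spe_rne_config()].
#' @param truth Optional hidden ground truth (+1/-1 over all genes).
#' @return List with `runs` (one row per strategy x seed) and `summary`
#'   (per strategy: mean/variance of F1, mean ROC, number of runs with
#'   undefined F1).
#' @export
compare_strategies <- function(K, P, U,
                               strategies = c("spe_rne", "twoclass",
                                              "twoclassbal", "psol_lite"),
                               seeds = 1:20,
                               config = spe_rne_config(), truth = NULL) {
  runs <- do.call(rbind, lapply(strategies, function(s) {
    do.call(rbind, lapply(seeds, function(sd) {
      evaluate_strategy(K, P, U, s, sd, config = config, truth = truth)
    }))
  }))
  summary <- do.call(rbind, lapply(strategies, function(s) {
    sub <- runs[runs$strategy == s, ]
    data.frame(strategy = s, n_runs = nrow(sub),
               mean_f1 = mean(sub$f1),
               var_f1 = mean((sub$f1 - mean(sub$f1))^2),
               mean_roc = mean(sub$roc),
               n_f1_undefined = sum(sub$f1_undefined))
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}

#' Serialize a trained strategy fit to JSON
#'
#' Stores the strategy name, the final model duals, the training index,
#' and the synthetic-combination weights, which is everything
#' [predict_unknowns()] needs.
#'
#' @param fit A `pu_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pu_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pu_fit"))
  obj <- list(strategy = fit$strategy, model = unclass(fit$model),
              train_index = fit$train_index,
              n_original = fit$n_original,
              weights = if (!is.null(fit$weights))
                as.data.frame(fit$weights) else NULL)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a strategy fit written by [write_pu_fit()]
#' @param path JSON path.
#' @return A `pu_fit`.
#' @export
read_pu_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- pu_fit(obj$strategy,
                structure(obj$model, class = "trained_model"),
                obj$train_index, obj$n_original,
                weights = if (!is.null(obj$weights))
                  as.matrix(obj$weights) else NULL)
  fit
}
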