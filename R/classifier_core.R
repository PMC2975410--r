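# Contract layer over the maximum-margin solver (libsvm via e1071).
# Precomputed kernels are handled through an exact empirical kernel map:
# a PSD kernel K factors as X X' with X = V sqrt(max(lambda, 0)) from its
# symmetric eigendecomposition, and a linear SVM on X is exactly the
# kernel SVM on K (decision functions live in the span of the data).

empirical_kernel_map <- function(K) {
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  eig$vectors %*% (sqrt(lam) * diag(length(lam)))
}

# libsvm's internal +1 class is the first label it encounters; normalize
# stored duals so that positive decision values always mean class "+1".
libsvm_sign <- function(fit) {
  if (fit$levels[fit$labels[1L]] == "1") 1 else -1
}

#' Train a soft-margin binary SVM on a precomputed kernel
#'
#' The returned model stores support indices, dual coefficients and bias,
#' so decision values are reproducible from the stored fields alone via
#' [decision_values()]; positive decision values correspond to the +1
#' class.
#'
#' @param K Square kernel matrix over the training points (training-set
#'   order defines the index space of the model). Must be symmetric;
#'   negative eigenvalues are clamped to zero.
#' @param labels Vector of +1/-1 labels, one per row of `K`.
#' @param C Soft-margin cost (default 1).
#' @return A `trained_model` (mode `"binary"`, kernel mode
#'   `"precomputed"`).
#' @export
train_binary <- function(K, labels, C = 1) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K), nrow(K) == length(labels),
            all(labels %in% c(-1, 1)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to train a binary SVM")
  }
  X <- empirical_kernel_map(K)
  y <- factor(labels, levels = c(-1, 1))
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  s <- libsvm_sign(fit)
  structure(list(mode = "binary", kernel_mode = "precomputed",
                 sv_index = fit$index,
                 coef = s * as.numeric(fit$coefs),
                 b = s * fit$rho,
                 sv_labels = labels[fit$index],
                 n_train = nrow(K),
                 params = list(C = C)),
            class = "trained_model")
}

#' Train a binary SVM with an RBF kernel on explicit features
#'
#' @param X Feature matrix (rows = examples).
#' @param labels Vector of +1/-1 labels.
#' @param C Soft-margin cost.
#' @param gamma RBF width; the kernel is
#'   \eqn{\exp(-\gamma\lVert x - y\rVert^2)}.
#' @return A `trained_model` (mode `"binary"`, kernel mode `"rbf"`); it
#'   stores the support-vector coordinates so decision values on new
#'   features need no training data.
#' @export
train_binary_rbf <- function(X, labels, C = 1, gamma = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(labels), gamma > 0)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to train a binary SVM")
  }
  y <- factor(labels, levels = c(-1, 1))
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  s <- libsvm_sign(fit)
  structure(list(mode = "binary", kernel_mode = "rbf",
                 sv_index = fit$index,
                 coef = s * as.numeric(fit$coefs),
                 b = s * fit$rho,
                 sv_labels = labels[fit$index],
                 sv_features = X[fit$index, , drop = FALSE],
                 n_train = nrow(X),
                 params = list(C = C, gamma = gamma)),
            class = "trained_model")
}

squared_distances <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Train a one-class SVM on a precomputed kernel
#'
#' Fits a boundary enclosing most of the sample, with `nu` controlling
#' the outlier fraction; points with negative decision value fall outside
#' it.
#'
#' @param K Square kernel matrix over the training points.
#' @param nu Outlier-fraction control in (0, 1).
#' @return A `trained_model` (mode `"one_class"`).
#' @export
train_one_class <- function(K, nu = 0.1) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K), nu > 0, nu < 1)
  if (nrow(unique(round(K, 12))) == 1L) {
    stop("degenerate kernel: all rows identical")
  }
  X <- empirical_kernel_map(K)
  fit <- e1071::svm(X, y = NULL, type = "one-classification",
                    kernel = "linear", nu = nu, scale = FALSE)
  structure(list(mode = "one_class", kernel_mode = "precomputed",
                 sv_index = fit$index,
                 coef = as.numeric(fit$coefs),
                 b = fit$rho,
                 sv_labels = NULL,
                 n_train = nrow(K),
                 params = list(nu = nu)),
            class = "trained_model")
}

#' Decision values of a trained model
#'
#' Recomputed from the stored dual coefficients and bias:
#' \eqn{f(x) = \sum_i \alpha_i K(x, sv_i) - b}.
#'
#' @param model A `trained_model`.
#' @param newdata For precomputed models, a kernel cross-matrix of the
#'   query points against the full training set (`n_query x n_train`);
#'   for RBF models, a feature matrix.
#' @return Numeric vector of decision values; positive means class +1
#'   (binary) or inside the boundary (one-class).
#' @export
decision_values <- function(model, newdata) {
  stopifnot(inherits(model, "trained_model"), is.matrix(newdata))
  if (model$kernel_mode == "rbf") {
    Kq <- exp(-model$params$gamma *
                squared_distances(newdata, model$sv_features))
    drop(Kq %*% model$coef - model$b)
  } else {
    if (ncol(newdata) != model$n_train) {
      stop("need kernel rows against all ", model$n_train,
           " training points")
    }
    drop(newdata[, model$sv_index, drop = FALSE] %*% model$coef - model$b)
  }
}

#' Predicted labels (+1/-1) of a trained model
#' @inheritParams decision_values
#' @return Vector of +1/-1 (binary: class; one-class: inlier/outlier).
#' @export
predict_labels <- function(model, newdata) {
  ifelse(decision_values(model, newdata) > 0, 1, -1)
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model: ", x$mode, " SVM (", x$kernel_mode, " kernel), ",
      length(x$sv_index), " support vectors, params: ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a trained model to JSON
#'
#' Writes a flat record (mode, kernel mode, parameters, support indices,
#' dual coefficients, bias, and support-vector coordinates for RBF
#' models) from which [decision_values()] can be evaluated.
#'
#' @param model A `trained_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  obj <- unclass(model)
  if (!is.null(obj$sv_features)) {
    obj$sv_features <- as.data.frame(obj$sv_features)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a trained model from JSON
#' @param path Path written by [write_model()].
#' @return A `trained_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$sv_features)) obj$sv_features <- as.matrix(obj$sv_features)
  structure(obj, class = "trained_model")
}

#' Grid-searched SVM training with stratified cross-validation
#'
#' Evaluates every grid point by k-fold stratified cross-validated F1
#' (NaN scored as 0), picks the best (ties resolved toward smaller `C`,
#' then smaller `gamma`), and refits on all training data. In
#' `"precomputed"` mode the gamma grid is ignored and only the cost `C`
#' is searched; in `"rbf"` mode the (C, gamma) product grid is searched
#' on explicit features.
#'
#' @param x Kernel matrix (`mode = "precomputed"`) or feature matrix
#'   (`mode = "rbf"`) over the training points.
#' @param labels Vector of +1/-1 labels.
#' @param C_grid Candidate costs (default \eqn{2^{-5}, 2^{-3}, ..., 2^{15}}).
#' @param gamma_grid Candidate RBF widths (default
#'   \eqn{2^{-15}, 2^{-13}, ..., 2^{3}}); ignored for precomputed
#'   kernels.
#' @param folds Number of CV folds (default 5).
#' @param mode `"precomputed"` or `"rbf"`.
#' @param seed Optional seed for the fold assignment.
#' @return List with `model` (refit on all data), `best_params`
#'   (list C, gamma), and `cv_table` (data.frame C, gamma, mean_f1).
#' @export
grid_search_train <- function(x, labels,
                              C_grid = 2^seq(-5, 15, by = 2),
                              gamma_grid = 2^seq(-15, 3, by = 2),
                              folds = 5,
                              mode = c("precomputed", "rbf"),
                              seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(folds >= 2, length(C_grid) >= 1, nrow(x) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  grid <- if (mode == "precomputed") {
    data.frame(C = sort(C_grid), gamma = NA_real_)
  } else {
    expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  }
  fold_id <- stratified_folds(labels, folds)
  cv_f1 <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    f1s <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      if (length(unique(labels[tr])) < 2L) { f1s[f] <- 0; next }
      if (!any(labels[te] == 1)) {
        # fold without positives: recall undefined, scored 0
        f1s[f] <- 0
        next
      }
      if (mode == "precomputed") {
        m <- train_binary(x[tr, tr, drop = FALSE], labels[tr],
                          C = grid$C[g])
        pred <- predict_labels(m, x[te, tr, drop = FALSE])
      } else {
        m <- train_binary_rbf(x[tr, , drop = FALSE], labels[tr],
                              C = grid$C[g], gamma = grid$gamma[g])
        pred <- predict_labels(m, x[te, , drop = FALSE])
      }
      f1s[f] <- precision_recall_f1(
        confusion_counts(labels[te], pred))["f1"]
    }
    cv_f1[g] <- mean(f1s)
  }
  best <- which(cv_f1 == max(cv_f1))
  ord <- best[order(grid$C[best], grid$gamma[best])]
  best <- ord[1L]
  model <- if (mode == "precomputed") {
    train_binary(x, labels, C = grid$C[best])
  } else {
    train_binary_rbf(x, labels, C = grid$C[best], gamma = grid$gamma[best])
  }
  list(model = model,
       best_params = list(C = grid$C[best],
                          gamma = if (mode == "rbf") grid$gamma[best]
                                  else NULL),
       cv_table = data.frame(C = grid$C, gamma = grid$gamma,
                             mean_f1 = cv_f1))
}

# fold labels 1..folds, stratified by class, order randomized by current
# RNG state
stratified_folds <- function(labels, folds) {
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    id[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  id
}
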