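#' Pairwise ICP-MSE similarity matrices
#'
#' `build_train_matrix()` registers every ordered pair of training clouds
#' and stores the ICP MSE at [i, j] (cloud i as source, cloud j as target;
#' the matrix is directional and not symmetrized). The diagonal is 0 by
#' construction without running ICP. `build_test_matrix()` does the same for
#' every (test, train) pair, giving an n_test x n_train feature matrix.
#' These raw dissimilarity rows are the features fed (after column
#' z-scoring) to the discriminant classifier.
#'
#' @param clouds,train_clouds,test_clouds lists of canonicalized,
#'   length-normalized [seed_cloud()]s.
#' @param ... passed to [icp()].
#' @return numeric matrix of MSEs (mm^2).
#' @export
build_train_matrix <- function(clouds, ...) {
  n <- length(clouds)
  if (n < 2L)
    stop_carposort("need at least 2 training clouds",
                   class = "carposort_parameter_error")
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) M[i, j] <- icp(clouds[[i]], clouds[[j]], ...)$mse
  }
  M
}

#' @rdname build_train_matrix
#' @export
build_test_matrix <- function(test_clouds, train_clouds, ...) {
  if (length(test_clouds) < 1L || length(train_clouds) < 1L)
    stop_carposort("both cloud sets must be non-empty",
                   class = "carposort_empty_input_error")
  M <- matrix(0, length(test_clouds), length(train_clouds))
  for (k in seq_along(test_clouds)) for (j in seq_along(train_clouds)) {
    M[k, j] <- icp(test_clouds[[k]], train_clouds[[j]], ...)$mse
  }
  M
}

#' All-pairs ICP-MSE cache over a cloud pool
#'
#' Computes the full directional MSE matrix over one pool once, so that
#' tournament sessions can index sub-blocks instead of re-running ICP.
#' Session results are identical whether entries are cached or recomputed.
#'
#' @param clouds list of preprocessed [seed_cloud()]s.
#' @param ... passed to [icp()].
#' @return an n x n matrix with zero diagonal.
#' @export
pairwise_mse_matrix <- function(clouds, ...) build_train_matrix(clouds, ...)

#' Column z-scoring of similarity features
#'
#' `fit_normalizer()` learns per-train-column means and SDs;
#' `apply_normalizer()` applies them to any matrix with matching width —
#' crucially, test matrices are normalized with the *training* parameters.
#' Zero-variance columns map to all zeros.
#'
#' @param train_matrix n x n training MSE matrix (n >= 2).
#' @param matrix a matrix with the same number of columns.
#' @param params a normalizer from `fit_normalizer()`.
#' @return `fit_normalizer()`: list with `column_means`, `column_stds`;
#'   `apply_normalizer()`: the normalized matrix.
#' @export
fit_normalizer <- function(train_matrix) {
  if (nrow(train_matrix) < 2L)
    stop_carposort("need >= 2 training rows to normalize",
                   class = "carposort_parameter_error")
  list(column_means = colMeans(train_matrix),
       column_stds = apply(train_matrix, 2, sd))
}

#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(matrix, params) {
  if (ncol(matrix) != length(params$column_means))
    stop_carposort("matrix width does not match normalizer",
                   class = "carposort_parameter_error")
  s <- params$column_stds
  out <- sweep(matrix, 2, params$column_means)
  out <- sweep(out, 2, ifelse(s > 0, s, 1), `/`)
  out[, s <= 0] <- 0
  out
}

#' Fit a regularized linear discriminant model
#'
#' Classic scatter-matrix LDA: within-class scatter S_w and between-class
#' scatter S_b are formed from the (normalized) similarity features, S_w is
#' ridge-regularized as S_w + gamma * mean(diag(S_w)) * I — necessary
#' because the feature dimension equals the number of training pips, making
#' S_w singular — and the projection is the top C-1 generalized
#' eigendirections of S_w^-1 S_b. Class centroids are the projected class
#' means; prediction assigns the nearest centroid.
#'
#' @param features n x d numeric matrix (rows = training pips).
#' @param labels class labels, length n; >= 2 classes with >= 2 samples
#'   each.
#' @param gamma regularization weight, >= 0 (default 1e-3).
#' @return an object of class `lda_model` with `projection` (d x (C-1)),
#'   `class_centroids`, `class_labels`, `gamma`.
#' @export
lda_fit <- function(features, labels, gamma = 1e-3) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (gamma < 0)
    stop_carposort("gamma must be >= 0",
                   class = "carposort_parameter_error")
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop_carposort("need at least 2 classes",
                   class = "carposort_parameter_error")
  if (any(table(labels) < 2L))
    stop_carposort("every class needs at least 2 samples",
                   class = "carposort_parameter_error")
  d <- ncol(features)
  grand <- colMeans(features)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  centroids_raw <- matrix(0, length(classes), d)
  for (k in seq_along(classes)) {
    Xc <- features[labels == classes[k], , drop = FALSE]
    mk <- colMeans(Xc)
    centroids_raw[k, ] <- mk
    Xd <- sweep(Xc, 2, mk)
    Sw <- Sw + crossprod(Xd)
    dk <- mk - grand
    Sb <- Sb + nrow(Xc) * tcrossprod(dk)
  }
  ridge <- gamma * mean(diag(Sw))
  if (ridge <= 0) ridge <- gamma  # guard: zero within-class scatter
  Sr <- Sw + diag(ridge + 1e-12, d)
  # generalized eigenproblem via Cholesky whitening (keeps symmetry)
  L <- chol(Sr)                       # Sr = L'L
  M <- backsolve(L, t(backsolve(L, Sb, transpose = TRUE)),
                 transpose = TRUE)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  ncomp <- min(length(classes) - 1L, d)
  W <- backsolve(L, eg$vectors[, seq_len(ncomp), drop = FALSE])
  structure(list(projection = W,
                 class_centroids = centroids_raw %*% W,
                 class_labels = classes, gamma = gamma),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes, %d-d discriminant space, gamma %g\n",
              length(x$class_labels), ncol(x$projection), x$gamma))
  invisible(x)
}

#' Classify feature rows with a fitted discriminant model
#'
#' Projects features into discriminant space and assigns each row to the
#' nearest class centroid; exact ties go to the first class in training
#' label order.
#'
#' @param model an [lda_fit()] model.
#' @param features matrix with the training feature width.
#' @return character vector of predicted labels.
#' @export
lda_predict <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(model$projection))
    stop_carposort("feature width %d does not match training width %d",
                   ncol(features), nrow(model$projection),
                   class = "carposort_parameter_error")
  proj <- features %*% model$projection
  cent <- model$class_centroids
  d2 <- outer(rowSums(proj^2), rowSums(cent^2), `+`) -
    2 * proj %*% t(cent)
  model$class_labels[apply(d2, 1, which.min)]   # which.min: first on ties
}

#' Tournament evaluation of the similarity classifier
#'
#' Runs repeated classification sessions: each session draws a stratified
#' random subsample of the training pool (fraction `train_fraction` per
#' class), builds the train and test similarity blocks from a cached
#' all-pairs ICP table, z-scores them with the training parameters, fits the
#' discriminant model and classifies the full test pool. Accuracies are
#' accumulated over sessions to approximate the accuracy distribution; the
#' accumulative accuracy is total correct / total classified.
#'
#' @param train_clouds,test_clouds lists of preprocessed [seed_cloud()]s.
#' @param train_labels,test_labels class labels for the two pools.
#' @param n_sessions number of sessions (default 100).
#' @param rng_seed integer seed; the whole tournament is reproducible.
#' @param train_fraction per-class subsampling fraction per session
#'   (default 0.8).
#' @param gamma LDA regularization.
#' @param mse_cache optional precomputed all-pairs MSE matrix over
#'   c(train_clouds, test_clouds) (train rows first), e.g. from
#'   [pairwise_mse_matrix()]; computed here when NULL. Only the
#'   train x train and test x train blocks are used.
#' @param ... passed to [icp()] when the cache is computed.
#' @return an object of class `tournament_result`: `per_session_accuracy`,
#'   `accumulative_accuracy`, `confusion_counts` (true x predicted),
#'   `n_sessions`.
#' @export
tournament <- function(train_clouds, train_labels, test_clouds, test_labels,
                       n_sessions = 100, rng_seed = 1, train_fraction = 0.8,
                       gamma = 1e-3, mse_cache = NULL, ...) {
  if (length(train_clouds) == 0L || length(test_clouds) == 0L)
    stop_carposort("train and test pools must be non-empty",
                   class = "carposort_empty_input_error")
  train_labels <- as.character(train_labels)
  test_labels <- as.character(test_labels)
  stopifnot(length(train_labels) == length(train_clouds),
            length(test_labels) == length(test_clouds))
  if (length(unique(train_labels)) < 2L)
    stop_carposort("training pool needs >= 2 classes",
                   class = "carposort_parameter_error")
  n_tr <- length(train_clouds)
  n_te <- length(test_clouds)
  if (is.null(mse_cache))
    mse_cache <- pairwise_mse_matrix(c(train_clouds, test_clouds), ...)
  stopifnot(nrow(mse_cache) >= n_tr + n_te)
  classes <- unique(c(train_labels, test_labels))
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  acc <- numeric(n_sessions)
  for (s in seq_len(n_sessions)) {
    sub <- with_seed(derive_seed(rng_seed, s), {
      unlist(lapply(split(seq_len(n_tr), train_labels), function(ix) {
        k <- max(2L, round(train_fraction * length(ix)))
        sort(sample(ix, min(k, length(ix))))
      }), use.names = FALSE)
    })
    tr_block <- mse_cache[sub, sub, drop = FALSE]
    te_block <- mse_cache[n_tr + seq_len(n_te), sub, drop = FALSE]
    norm <- fit_normalizer(tr_block)
    model <- lda_fit(apply_normalizer(tr_block, norm), train_labels[sub],
                     gamma = gamma)
    pred <- lda_predict(model, apply_normalizer(te_block, norm))
    acc[s] <- mean(pred == test_labels)
    for (i in seq_len(n_te))
      confusion[test_labels[i], pred[i]] <-
        confusion[test_labels[i], pred[i]] + 1L
  }
  structure(list(per_session_accuracy = acc,
                 accumulative_accuracy = sum(diag(confusion)) /
                   (n_te * n_sessions),
                 confusion_counts = confusion, n_sessions = n_sessions),
            class = "tournament_result")
}

#' @export
print.tournament_result <- function(x, ...) {
  cat(sprintf(
    "<tournament_result> %d sessions; accumulative accuracy %.1f%%\n",
    x$n_sessions, 100 * x$accumulative_accuracy))
  invisible(x)
}
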