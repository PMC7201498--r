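#' SVM configuration
#'
#' Settings for the RBF-kernel support vector machine: the cost and kernel
#' width grids searched exhaustively, the number of stratified inner folds
#' used to score each grid cell, the multiclass decomposition, and optional
#' z-scoring fitted on training data only.  The default grids are the
#' conventional powers-of-two ranges (cost 2^-5..2^15, width 2^-15..2^3,
#' step 2); smaller explicit grids are advisable for leave-one-out runs.
#'
#' @param c_grid Positive cost values to search.
#' @param gamma_grid Positive RBF width values to search.
#' @param inner_folds Stratified folds for grid scoring (default 5).
#' @param decomposition `"ovo"` (one-vs-one voting, default) or `"ovr"`
#'   (one-vs-rest by decision value).
#' @param zscore Standardise features using training-fold statistics.
#' @return An object of class `SvmConfig`.
#' @export
svm_config <- function(c_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       inner_folds = 5L,
                       decomposition = c("ovo", "ovr"),
                       zscore = FALSE) {
  decomposition <- match.arg(decomposition)
  if (length(c_grid) < 1L || any(c_grid <= 0))
    stop("c_grid must be non-empty and strictly positive")
  if (length(gamma_grid) < 1L || any(gamma_grid <= 0))
    stop("gamma_grid must be non-empty and strictly positive")
  structure(list(c_grid = c_grid, gamma_grid = gamma_grid,
                 inner_folds = as.integer(inner_folds),
                 decomposition = decomposition, zscore = zscore),
            class = "SvmConfig")
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Binary soft-margin C-SVM trained by solving the standard dual QP:
#   max sum(alpha) - 1/2 alpha' (yy' * K) alpha,  0 <= alpha <= C,
#   sum(alpha * y) = 0.
# A small ridge on the quadratic term keeps the problem positive definite
# when the kernel matrix is rank-deficient (duplicated points after SMOTE).
svm_binary_qp <- function(K, y, C) {
  n <- length(y)
  Q <- (y %o% y) * K
  ridge <- 1e-8
  sol <- NULL
  for (attempt in 1:6) {
    Dmat <- Q + diag(ridge, n)
    sol <- tryCatch(
      quadprog::solve.QP(Dmat, rep(1, n),
                         Amat = cbind(y, diag(n), -diag(n)),
                         bvec = c(0, rep(0, n), rep(-C, n)), meq = 1L),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stop("SVM dual QP failed to solve")
  alpha <- pmin(pmax(sol$solution, 0), C)
  f0 <- as.vector(K %*% (alpha * y))
  tol <- 1e-6 * C
  free <- alpha > tol & alpha < C - tol
  b <- if (any(free)) mean(y[free] - f0[free]) else {
    sv <- alpha > tol
    if (any(sv)) mean(y[sv] - f0[sv]) else mean(y - f0)
  }
  list(alpha = alpha, b = b)
}

#' Fit a multiclass RBF-SVM
#'
#' One-vs-one (default): a binary soft-margin machine per class pair,
#' combined by majority vote with decision-value tie-breaking.  One-vs-rest:
#' a machine per class, predicting the largest decision value.  Training is
#' deterministic given the data and parameters.
#'
#' @param X Numeric training matrix.
#' @param y Training labels (>= 2 classes present).
#' @param C Cost parameter.
#' @param gamma RBF kernel width.
#' @param decomposition `"ovo"` or `"ovr"`.
#' @return An object of class `SvmModel` with a [predict()] method.
#' @export
svm_fit <- function(X, y, C, gamma, decomposition = c("ovo", "ovr")) {
  decomposition <- match.arg(decomposition)
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  lev <- levels(y)
  if (length(lev) < 2L) stop("training set must contain at least 2 classes")
  machines <- list()
  if (decomposition == "ovo") {
    for (i in seq_len(length(lev) - 1L)) {
      for (j in seq(i + 1L, length(lev))) {
        idx <- which(y %in% lev[c(i, j)])
        Xi <- X[idx, , drop = FALSE]
        yi <- ifelse(y[idx] == lev[i], 1, -1)
        fit <- svm_binary_qp(rbf_kernel(Xi, Xi, gamma), yi, C)
        machines[[paste(lev[i], lev[j], sep = "|")]] <-
          list(pos = lev[i], neg = lev[j], X = Xi, ay = fit$alpha * yi,
               b = fit$b)
      }
    }
  } else {
    for (i in seq_along(lev)) {
      yi <- ifelse(y == lev[i], 1, -1)
      fit <- svm_binary_qp(rbf_kernel(X, X, gamma), yi, C)
      machines[[lev[i]]] <- list(pos = lev[i], X = X, ay = fit$alpha * yi,
                                 b = fit$b)
    }
  }
  structure(list(machines = machines, levels = lev, gamma = gamma, C = C,
                 decomposition = decomposition, center = NULL, scale = NULL),
            class = "SvmModel")
}

# Fit with optional z-scoring; scaling statistics are estimated on the
# training data only and stored in the model for prediction time.
fit_svm_scaled <- function(X, y, C, gamma, cfg) {
  ctr <- NULL; scl <- NULL
  if (cfg$zscore) {
    ctr <- colMeans(X)
    scl <- pmax(apply(X, 2L, stats::sd), 1e-12)
    X <- scale(X, ctr, scl)
  }
  model <- svm_fit(X, y, C, gamma, cfg$decomposition)
  model$center <- ctr
  model$scale <- scl
  model
}

#' Predict classes with a fitted SVM
#'
#' @param object An `SvmModel` from [svm_fit()].
#' @param newdata Numeric matrix of samples to classify.
#' @param ... Unused.
#' @return Factor of predicted classes with the model's levels.
#' @export
predict.SvmModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$center))
    newdata <- scale(newdata, object$center, object$scale)
  lev <- object$levels
  n <- nrow(newdata)
  if (object$decomposition == "ovo") {
    votes <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
    margin <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
    for (mch in object$machines) {
      f <- as.vector(rbf_kernel(newdata, mch$X, object$gamma) %*% mch$ay) +
        mch$b
      pos <- f >= 0
      votes[, mch$pos] <- votes[, mch$pos] + pos
      votes[, mch$neg] <- votes[, mch$neg] + !pos
      margin[, mch$pos] <- margin[, mch$pos] + f
      margin[, mch$neg] <- margin[, mch$neg] - f
    }
    # majority vote; ties broken by accumulated decision margin, then by
    # level order (deterministic)
    pred <- vapply(seq_len(n), function(i) {
      best <- which(votes[i, ] == max(votes[i, ]))
      if (length(best) > 1L) best <- best[which.max(margin[i, best])]
      lev[best]
    }, character(1L))
  } else {
    scores <- vapply(object$machines, function(mch)
      as.vector(rbf_kernel(newdata, mch$X, object$gamma) %*% mch$ay) + mch$b,
      numeric(n))
    if (n == 1L) scores <- matrix(scores, 1L)
    pred <- lev[apply(scores, 1L, which.max)]
  }
  factor(pred, levels = lev)
}

# Deterministic stratified fold assignment: class members, in data order,
# are dealt round-robin across folds.  No RNG involved, so grid search is a
# pure function of the data and the grids.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(factor(y))) {
    idx <- which(y == cl)
    fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  fold
}

#' Grid search for the RBF-SVM cost and kernel width
#'
#' Evaluates every (cost, width) pair on stratified inner folds of the
#' training data and refits on the full set at the best pair.  The selection
#' rule is: highest mean inner-fold accuracy, ties resolved in grid order
#' (cost ascending, then width ascending), which makes the search
#' deterministic.
#'
#' @param data A [labeled_feature_set()] with >= 2 classes.
#' @param cfg An [svm_config()].
#' @return List with `model` (the refit [svm_fit()] object), `C`, `gamma`,
#'   `accuracy` (inner CV accuracy of the chosen pair) and `table` (the full
#'   grid with scores).
#' @export
grid_search_svm <- function(data, cfg = svm_config()) {
  stopifnot(inherits(data, "LabeledFeatureSet"), inherits(cfg, "SvmConfig"))
  y <- droplevels(data$y)
  if (nlevels(y) < 2L) stop("grid search needs at least 2 classes")
  X <- data$X
  k <- min(cfg$inner_folds, min(table(y)))
  k <- max(k, 2L)
  fold <- stratified_folds(y, k)
  grid <- expand.grid(gamma = cfg$gamma_grid, C = cfg$c_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("C", "gamma")]
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    total <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      te <- !tr
      if (!any(te)) next
      ytr <- droplevels(y[tr])
      pred <- if (nlevels(ytr) < 2L) {
        rep(names(which.max(table(ytr))), sum(te))
      } else {
        as.character(predict(
          fit_svm_scaled(X[tr, , drop = FALSE], y[tr], grid$C[g],
                         grid$gamma[g], cfg),
          X[te, , drop = FALSE]))
      }
      correct <- correct + sum(pred == as.character(y[te]))
      total <- total + sum(te)
    }
    grid$accuracy[g] <- correct / total
  }
  best <- which.max(grid$accuracy)   # first maximum in grid order
  model <- fit_svm_scaled(X, y, grid$C[best], grid$gamma[best], cfg)
  list(model = model, C = grid$C[best], gamma = grid$gamma[best],
       accuracy = grid$accuracy[best], table = grid)
}
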