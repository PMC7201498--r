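#' Labeled feature set
#'
#' The unit passed to resampling and classification: an n x p feature matrix,
#' a class label per row, row identifiers, and a provenance marker telling
#' original rows apart from SMOTE synthetics (`"synthetic:<parent id>"`).
#'
#' @param X Numeric n x p matrix with no non-finite entries.
#' @param y Class labels, length n; coerced to factor.
#' @param ids Optional row identifiers (default rownames of `X`, else
#'   `s1..sn`).
#' @param provenance Optional character vector; defaults to `"original"`.
#' @return An object of class `LabeledFeatureSet`.
#' @export
labeled_feature_set <- function(X, y, ids = NULL, provenance = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("feature matrix must be numeric and finite")
  if (nrow(X) < 1L) stop("feature set must have at least one row")
  y <- factor(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(table(y) < 1L)) stop("every class must have at least one member")
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  if (length(ids) != nrow(X)) stop("length(ids) must equal nrow(X)")
  if (is.null(provenance)) provenance <- rep("original", nrow(X))
  rownames(X) <- NULL
  structure(list(X = X, y = y, ids = as.character(ids),
                 provenance = provenance),
            class = "LabeledFeatureSet")
}

#' @export
print.LabeledFeatureSet <- function(x, ...) {
  tab <- table(x$y)
  cat(sprintf("LabeledFeatureSet: %d samples x %d features; classes: %s\n",
              nrow(x$X), ncol(x$X),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Resampling plan
#'
#' Bundles every choice the resampling stage needs: which method runs, the
#' SMOTE neighbourhood size `k_neighbors`, the oversampling magnification `N`
#' (`"auto"` equalises every class to the majority count; an integer N adds
#' N synthetics per minority sample), the fixed 3-neighbour ENN vote, the
#' seed, where resampling sits relative to cross-validation, and whether
#' feature blocks are resampled before or after fusion.
#'
#' @param method `"none"`, `"smote"`, `"enn"` or `"smoteenn"`.
#' @param k_neighbors SMOTE neighbourhood size (default 5).
#' @param N `"auto"` or a positive integer magnification.
#' @param enn_neighbors ENN neighbourhood size (the rule is defined for 3).
#' @param seed Integer seed driving all random draws.
#' @param placement `"train_fold_only"` (resample inside each training fold;
#'   no leakage) or `"before_cv"` (resample the full set once, the reading
#'   consistent with the near-perfect published resampling metrics).
#' @param strategy `"fuse_then_resample"` (Resampling 2, the preferred
#'   ordering) or `"resample_then_fuse"` (Resampling 1).
#' @return An object of class `ResamplingPlan`.
#' @export
resampling_plan <- function(method = c("none", "smote", "enn", "smoteenn"),
                            k_neighbors = 5L, N = "auto",
                            enn_neighbors = 3L, seed = 1L,
                            placement = c("train_fold_only", "before_cv"),
                            strategy = c("fuse_then_resample",
                                         "resample_then_fuse")) {
  method <- match.arg(method)
  placement <- match.arg(placement)
  strategy <- match.arg(strategy)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (!identical(N, "auto") && (!is.numeric(N) || N < 1 || N != round(N)))
    stop("N must be \"auto\" or a positive integer")
  if (enn_neighbors < 1L) stop("enn_neighbors must be >= 1")
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 N = N, enn_neighbors = as.integer(enn_neighbors),
                 seed = as.integer(seed), placement = placement,
                 strategy = strategy),
            class = "ResamplingPlan")
}

# Run `expr` under a private RNG stream; the caller's RNG state is untouched.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic pairwise Euclidean distances (dense; sets here are small).
pairwise_dist <- function(A, B = A) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Draw the SMOTE synthesis schedule: for each synthetic point, the class, the
# parent's index within its class, the neighbour rank among the parent's k
# same-class nearest neighbours, and the interpolation weight u in [0, 1).
# Separating the schedule from its application lets several feature blocks be
# resampled with identical draws so their synthetic rows align index-wise.
smote_schedule <- function(y, plan) {
  counts <- table(y)
  maj <- max(counts)
  out <- list()
  for (cl in names(counts)) {
    n_cl <- counts[[cl]]
    n_syn <- if (identical(plan$N, "auto")) maj - n_cl
             else if (n_cl < maj) plan$N * n_cl else 0L
    if (n_syn == 0L) next
    if (n_cl < plan$k_neighbors + 1L)
      stop("class '", cl, "' has ", n_cl, " members; SMOTE with k = ",
           plan$k_neighbors, " needs at least ", plan$k_neighbors + 1L)
    out[[cl]] <- data.frame(
      class = cl,
      parent = sample.int(n_cl, n_syn, replace = TRUE),
      rank = sample.int(plan$k_neighbors, n_syn, replace = TRUE),
      u = stats::runif(n_syn))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(class = character(), parent = integer(), rank = integer(),
               u = numeric())
}

# Interpolate the scheduled synthetics in one feature block.  Neighbour
# geometry (who the rank-th nearest same-class neighbour is) is computed in
# this block's feature space; parent, rank and u come from the schedule.
apply_smote_schedule <- function(data, schedule, k) {
  if (nrow(schedule) == 0L) return(data)
  X <- data$X
  y <- data$y
  syn_rows <- matrix(NA_real_, nrow(schedule), ncol(X))
  syn_parent <- character(nrow(schedule))
  meta <- data.frame(parent_row = integer(nrow(schedule)),
                     neighbor_row = integer(nrow(schedule)),
                     u = schedule$u)
  for (cl in unique(schedule$class)) {
    cls_idx <- which(y == cl)
    D <- pairwise_dist(X[cls_idx, , drop = FALSE])
    diag(D) <- Inf
    # k nearest same-class neighbours per member; ties broken by row order
    nn <- t(apply(D, 1L, function(dr) order(dr)[seq_len(k)]))
    rows <- which(schedule$class == cl)
    for (r in rows) {
      p_local <- schedule$parent[r]
      nb_local <- nn[p_local, schedule$rank[r]]
      p <- cls_idx[p_local]
      nb <- cls_idx[nb_local]
      syn_rows[r, ] <- X[p, ] + schedule$u[r] * (X[nb, ] - X[p, ])
      syn_parent[r] <- data$ids[p]
      meta$parent_row[r] <- p
      meta$neighbor_row[r] <- nb
    }
  }
  out <- labeled_feature_set(
    rbind(X, syn_rows),
    c(as.character(y), schedule$class),
    ids = c(data$ids, sprintf("syn%d_%s", seq_len(nrow(schedule)),
                              syn_parent)),
    provenance = c(data$provenance, paste0("synthetic:", syn_parent)))
  attr(out, "smote_log") <- meta
  out
}

#' SMOTE oversampling
#'
#' Synthetic minority oversampling: for each scheduled synthetic point a
#' minority sample x is drawn, one of its `k_neighbors` same-class Euclidean
#' nearest neighbours y is chosen, and the new point is
#' `x + u * (y - x)` with `u ~ Uniform[0, 1)` -- a random point on the
#' parent-neighbour segment.  Originals are retained untouched; synthetics
#' are appended with provenance `"synthetic:<parent id>"`.  With
#' `N = "auto"` every class is raised to the majority count, so balanced
#' input is a fixed point.
#'
#' @param data A [labeled_feature_set()].
#' @param plan A [resampling_plan()]; `plan$seed` makes the run
#'   bit-reproducible.
#' @return A [labeled_feature_set()] with an attached `"smote_log"` attribute
#'   recording parent row, neighbour row and interpolation weight per
#'   synthetic point.
#' @export
smote <- function(data, plan) {
  stopifnot(inherits(data, "LabeledFeatureSet"),
            inherits(plan, "ResamplingPlan"))
  sched <- with_local_seed(plan$seed, smote_schedule(data$y, plan))
  apply_smote_schedule(data, sched, plan$k_neighbors)
}

#' Edited nearest neighbours (ENN) cleaning
#'
#' One pass over the set: each sample's `k` nearest neighbours (default 3,
#' the classical rule) are found in the original, pre-deletion set; if two or
#' more of the three differ from the sample's own class, the sample is marked
#' for deletion.  All deletions are applied simultaneously, preserving row
#' order.  A class wiped out entirely triggers a warning, not an error.
#'
#' @param data A [labeled_feature_set()] with at least 4 rows.
#' @param k Neighbourhood size for the vote (default 3).
#' @return The surviving subset as a [labeled_feature_set()].
#' @export
enn <- function(data, k = 3L) {
  stopifnot(inherits(data, "LabeledFeatureSet"))
  n <- nrow(data$X)
  if (n < 4L) stop("ENN needs at least 4 samples, got ", n)
  if (nlevels(droplevels(data$y)) < 2L) return(data)
  D <- pairwise_dist(data$X)
  diag(D) <- Inf
  drop <- logical(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    drop[i] <- sum(data$y[nb] != data$y[i]) >= 2L
  }
  kept <- !drop
  lost <- setdiff(levels(droplevels(data$y)),
                  levels(droplevels(data$y[kept])))
  if (length(lost))
    warning("ENN removed every sample of class(es): ",
            paste(lost, collapse = ", "))
  out <- labeled_feature_set(data$X[kept, , drop = FALSE],
                             as.character(data$y)[kept],
                             ids = data$ids[kept],
                             provenance = data$provenance[kept])
  attr(out, "enn_removed") <- data$ids[drop]
  out
}

#' SMOTE followed by ENN cleaning
#'
#' The composite resampler: oversample minorities to balance, then edit away
#' samples sitting in the wrong-class neighbourhood (noise and class-overlap
#' points, including freshly synthesised ones).  Deterministic under
#' `plan$seed`.
#'
#' @inheritParams smote
#' @return A [labeled_feature_set()].
#' @export
smoteenn <- function(data, plan) {
  enn(smote(data, plan), k = plan$enn_neighbors)
}

#' Apply a resampling plan's method to a feature set
#'
#' Dispatches on `plan$method`; `"none"` returns the input unchanged.
#'
#' @inheritParams smote
#' @return A [labeled_feature_set()].
#' @export
resample <- function(data, plan) {
  switch(plan$method,
         none     = data,
         smote    = smote(data, plan),
         enn      = enn(data, k = plan$enn_neighbors),
         smoteenn = smoteenn(data, plan))
}

#' Write a labeled feature set to CSV (with provenance column)
#'
#' @param data A [labeled_feature_set()].
#' @param path Output path.
#' @export
write_feature_set_csv <- function(data, path) {
  df <- data.frame(id = data$ids, data$X, check.names = FALSE,
                   row.names = NULL)
  df$class <- as.character(data$y)
  df$provenance <- data$provenance
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled feature set written by [write_feature_set_csv()]
#'
#' @param path CSV path.
#' @return A [labeled_feature_set()].
#' @export
read_feature_set_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feat <- setdiff(names(df), c("id", "class", "provenance"))
  labeled_feature_set(as.matrix(df[, feat, drop = FALSE]), df$class,
                      ids = df$id,
                      provenance = if ("provenance" %in% names(df))
                        df$provenance else NULL)
}
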