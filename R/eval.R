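#' One-vs-rest confusion counts
#'
#' For every class c: TP = samples of c predicted c, FN = samples of c
#' predicted otherwise, FP = samples of other classes predicted c, TN = the
#' rest.  TP + FP + TN + FN = n for each class.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels, same length.
#' @param levels Optional class universe; defaults to the union of both.
#' @return Data frame with one row per class: `class`, `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (length(y_true) < 1L) stop("need at least one sample")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(levels)) levels <- sort(unique(c(y_true, y_pred)))
  n <- length(y_true)
  out <- do.call(rbind, lapply(levels, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    data.frame(class = cl, TP = tp, FP = fp, TN = n - tp - fn - fp, FN = fn,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

# Six indicators from one-vs-rest counts.  Zero denominators are flagged as
# NA ("undefined") rather than propagated as NaN; macro averages skip them
# and report how many were skipped.
metrics_from_counts <- function(counts) {
  per <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], {
      sn <- safe_div(TP, TP + FN)
      sp <- safe_div(TN, TN + FP)
      prec <- safe_div(TP, TP + FP)
      fm <- if (is.na(prec) || is.na(sn) || (prec + sn) == 0) NA_real_
            else 2 * prec * sn / (prec + sn)
      mden <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
      mcc <- if (mden == 0) NA_real_
             else (TP * TN - FP * FN) / sqrt(mden)
      gm <- if (is.na(sn) || is.na(sp)) NA_real_ else sqrt(sn * sp)
      data.frame(class = class, Sn = sn, Sp = sp, Fm = fm, Mcc = mcc,
                 Gmean = gm, stringsAsFactors = FALSE)
    })
  }))
  rownames(per) <- NULL
  per
}

#' Evaluation report from predictions
#'
#' Assembles the six standard indicators -- sensitivity, specificity,
#' F-measure, Matthews correlation coefficient, G-mean (per class, one-vs-
#' rest) and overall accuracy -- from paired true/predicted label vectors.
#' Macro averages are unweighted means over classes, excluding classes whose
#' indicator is undefined (zero denominator); the number of exclusions is
#' reported.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param metadata Optional list carried into the report (plan, config,
#'   seed, chosen SVM parameters, ...).
#' @return An object of class `EvaluationReport`: `per_class` (data frame),
#'   `macro` (named vector), `OA`, `n`, `n_undefined`, `metadata`.
#' @export
evaluation_report <- function(y_true, y_pred, metadata = list()) {
  counts <- confusion(y_true, y_pred)
  per <- metrics_from_counts(counts)
  macro <- vapply(c("Sn", "Sp", "Fm", "Mcc", "Gmean"),
                  function(m) mean(per[[m]], na.rm = TRUE), numeric(1L))
  structure(list(
    counts = counts,
    per_class = per,
    macro = macro,
    OA = mean(as.character(y_true) == as.character(y_pred)),
    n = length(y_true),
    n_undefined = sum(is.na(per[, c("Sn", "Sp", "Fm", "Mcc", "Gmean")])),
    y_true = as.character(y_true),
    y_pred = as.character(y_pred),
    metadata = metadata), class = "EvaluationReport")
}

#' Six metrics from confusion counts
#'
#' Per-class indicators computed directly from one-vs-rest counts (see
#' [confusion()]); overall accuracy is the fraction of correctly labelled
#' samples, i.e. sum of per-class TP over n.
#'
#' @param counts Data frame from [confusion()].
#' @return List with `per_class` data frame and `OA`.
#' @export
metrics <- function(counts) {
  n <- counts$TP[1L] + counts$FP[1L] + counts$TN[1L] + counts$FN[1L]
  list(per_class = metrics_from_counts(counts), OA = sum(counts$TP) / n)
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("Jackknife evaluation: n = %d, OA = %.4f\n", x$n, x$OA))
  per <- x$per_class
  num <- c("Sn", "Sp", "Fm", "Mcc", "Gmean")
  per[num] <- lapply(per[num], function(v) sprintf("%.4f", v))
  print(per, row.names = FALSE)
  cat(sprintf("macro: Sn %.4f  Sp %.4f  F-m %.4f  Mcc %.4f  G-mean %.4f\n",
              x$macro["Sn"], x$macro["Sp"], x$macro["Fm"], x$macro["Mcc"],
              x$macro["Gmean"]))
  if (x$n_undefined > 0)
    cat(x$n_undefined, "undefined per-class value(s) excluded from macros\n")
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param report An `EvaluationReport`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(n = report$n, OA = report$OA, per_class = report$per_class,
         macro = as.list(report$macro), n_undefined = report$n_undefined,
         metadata = report$metadata),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

# Apply the plan's resampling under the declared fusion strategy.  With
# `block_cols` given and strategy "resample_then_fuse" (Resampling 1), the
# SMOTE synthesis schedule (parent, neighbour rank, interpolation weight) is
# drawn once and applied to every block, so synthetic rows align index-wise
# before concatenation; the ENN edit then votes on the fused matrix, since
# per-block edits could delete different rows and break alignment.
strategy_apply <- function(data, plan, block_cols = NULL, seed = plan$seed) {
  if (plan$method == "none") return(data)
  plan2 <- plan
  plan2$seed <- as.integer(seed %% .Machine$integer.max)
  if (is.null(block_cols) || length(block_cols) < 2L ||
      plan$strategy == "fuse_then_resample")
    return(resample(data, plan2))

  # Resampling 1: per-block SMOTE under one shared schedule
  if (plan$method %in% c("smote", "smoteenn")) {
    sched <- with_local_seed(plan2$seed, smote_schedule(data$y, plan2))
    blocks <- lapply(block_cols, function(cols) {
      bl <- labeled_feature_set(data$X[, cols, drop = FALSE], data$y,
                                ids = data$ids,
                                provenance = data$provenance)
      apply_smote_schedule(bl, sched, plan2$k_neighbors)
    })
    sizes <- vapply(blocks, function(b) nrow(b$X), integer(1L))
    if (length(unique(sizes)) != 1L)
      stop("internal error: resampled feature blocks have mismatched rows")
    fused <- labeled_feature_set(
      do.call(cbind, lapply(blocks, `[[`, "X")),
      blocks[[1L]]$y, ids = blocks[[1L]]$ids,
      provenance = blocks[[1L]]$provenance)
  } else {
    fused <- data
  }
  if (plan$method %in% c("enn", "smoteenn"))
    fused <- enn(fused, k = plan2$enn_neighbors)
  fused
}

lfs_subset <- function(data, keep) {
  labeled_feature_set(data$X[keep, , drop = FALSE],
                      as.character(data$y)[keep],
                      ids = data$ids[keep],
                      provenance = data$provenance[keep])
}

#' Jackknife (leave-one-out) evaluation of the RBF-SVM
#'
#' Each *original* sample in turn is held out and predicted by a machine
#' trained on the remainder; synthetic samples are never test points.  With
#' `plan$placement = "train_fold_only"` the resampler runs inside every
#' training fold (fold seed derived from `plan$seed`), so a test sample never
#' appears, directly or as a SMOTE parent, in its own training set.  With
#' `"before_cv"` the full set is resampled once and each fold removes only
#' the held-out original row.  The procedure is deterministic given data,
#' configuration and plan seed.
#'
#' @param data A [labeled_feature_set()] of original samples.
#' @param cfg An [svm_config()].
#' @param plan A [resampling_plan()]; `method = "none"` for the plain run.
#' @param tune `"once"` (grid search once on the full processed set, then
#'   fixed (C, gamma) across folds -- the default) or `"nested"` (grid search
#'   repeated inside every training fold).
#' @param block_cols Optional list of column index vectors marking feature
#'   blocks for the `"resample_then_fuse"` strategy.
#' @return An [evaluation_report()] with chosen SVM parameters and any
#'   single-member classes flagged in the metadata.
#' @export
jackknife <- function(data, cfg = svm_config(), plan = resampling_plan("none"),
                      tune = c("once", "nested"), block_cols = NULL) {
  tune <- match.arg(tune)
  stopifnot(inherits(data, "LabeledFeatureSet"))
  n <- nrow(data$X)
  nclass <- nlevels(droplevels(data$y))
  if (n < nclass + 1L) stop("jackknife needs n >= number of classes + 1")

  # (C, gamma) are tuned on the original samples: scoring grid cells on a
  # resampled set lets synthetic points interpolate across the inner folds,
  # which inflates inner accuracy and selects overfitting kernels.
  chosen <- NULL
  if (tune == "once") {
    gs <- grid_search_svm(data, cfg)
    chosen <- list(C = gs$C, gamma = gs$gamma)
  }

  before_cv <- plan$method != "none" && plan$placement == "before_cv"
  if (before_cv)
    full <- strategy_apply(data, plan, block_cols, seed = plan$seed)

  preds <- character(n)
  fold_params <- vector("list", n)
  for (i in seq_len(n)) {
    if (before_cv) {
      train <- lfs_subset(full, full$ids != data$ids[i])
    } else {
      base <- lfs_subset(data, seq_len(n) != i)
      train <- if (plan$method == "none") base
               else strategy_apply(base, plan, block_cols,
                                   seed = plan$seed + i)
    }
    ytr <- droplevels(train$y)
    if (nlevels(ytr) < 2L) {
      preds[i] <- names(which.max(table(ytr)))
      next
    }
    par <- if (tune == "nested") {
      gs <- grid_search_svm(train, cfg)
      list(C = gs$C, gamma = gs$gamma)
    } else chosen
    fold_params[[i]] <- par
    model <- fit_svm_scaled(train$X, train$y, par$C, par$gamma, cfg)
    preds[i] <- as.character(predict(model, data$X[i, , drop = FALSE]))
  }

  singletons <- names(which(table(data$y) == 1L))
  evaluation_report(
    as.character(data$y), preds,
    metadata = list(
      plan = unclass(plan), tune = tune,
      chosen = if (tune == "once") chosen else NULL,
      fold_params = if (tune == "nested") fold_params else NULL,
      singleton_classes = if (length(singletons)) singletons else NULL,
      n_models = n))
}

#' Run a full fusion + resampling strategy end to end
#'
#' Encodes a PSSM collection with the column-lag encoder (at `xi`) and the
#' bidirectional cross-correlation (at `S`), combines the blocks under the
#' plan's fusion/resampling strategy, and evaluates by jackknife:
#' `"resample_then_fuse"` balances each block separately (shared synthesis
#' schedule) before concatenation; `"fuse_then_resample"` concatenates first
#' and balances the fused vectors.  With `method = "none"` both reduce to
#' encode + fuse + jackknife.
#'
#' @param matrices List of [pssm_matrix()] objects.
#' @param labels Class label per matrix.
#' @param xi Column-lag bound for the improved pseudo-PSSM block.
#' @param S Residue distance(s) for the cross-correlation block.
#' @param plan A [resampling_plan()].
#' @param cfg An [svm_config()].
#' @param scale Sigmoid-scale raw matrices before encoding (default TRUE).
#' @param tune Grid-search placement, as in [jackknife()].
#' @return An [evaluation_report()]; metadata records xi, S and block widths.
#' @export
run_strategy <- function(matrices, labels, xi, S, plan = resampling_plan("none"),
                         cfg = svm_config(), scale = TRUE,
                         tune = c("once", "nested")) {
  tune <- match.arg(tune)
  X_im <- encode_collection(matrices, "im_psepssm", xi = xi, scale = scale)
  X_cc <- encode_collection(matrices, "bidcc", S = S, scale = scale)
  stopifnot(identical(rownames(X_im), rownames(X_cc)))
  fusedX <- cbind(X_im, X_cc)
  data <- labeled_feature_set(fusedX, labels, ids = rownames(X_im))
  block_cols <- list(seq_len(ncol(X_im)),
                     ncol(X_im) + seq_len(ncol(X_cc)))
  rep <- jackknife(data, cfg, plan, tune = tune, block_cols = block_cols)
  rep$metadata$xi <- xi
  rep$metadata$S <- S
  rep$metadata$block_widths <- c(im_psepssm = ncol(X_im), bidcc = ncol(X_cc))
  rep$metadata$fused_width <- ncol(fusedX)
  rep
}
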