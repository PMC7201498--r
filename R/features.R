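#' Feature-vector container
#'
#' Fixed-length numeric encoding of one protein with provenance: which
#' encoder produced it and with which parameters (lag bound `xi` for the
#' pseudo-PSSM family, residue distance `S` for the bidirectional
#' cross-correlation).
#'
#' @param id Protein identifier.
#' @param values Named numeric vector, all entries finite.
#' @param encoder One of `"psepssm"`, `"im_psepssm"`, `"t1"`, `"t2"`, `"t3"`,
#'   `"bidcc"`, `"bim_pssm"`.
#' @param params Named list of encoder parameters.
#' @return An object of class `FeatureVector`.
#' @export
feature_vector <- function(id, values, encoder, params = list()) {
  encoder <- match.arg(encoder, c("psepssm", "im_psepssm", "t1", "t2", "t3",
                                  "bidcc", "bim_pssm"))
  if (any(!is.finite(values))) stop("non-finite feature values for ", id)
  structure(list(id = id, values = values, encoder = encoder, params = params),
            class = "FeatureVector")
}

#' @export
print.FeatureVector <- function(x, ...) {
  cat(sprintf("FeatureVector '%s': %s, %dD\n", x$id, x$encoder,
              length(x$values)))
  invisible(x)
}

#' @export
length.FeatureVector <- function(x) length(x$values)

# Per-lag normalisation prefactor.  The three readings of the printed
# 1/(L - xi) constant: per-lag distance (default), the maximum lag for every
# pair, or plain 1/L.
norm_factor <- function(L, d, xi, norm) {
  switch(norm,
         per_lag = 1 / (L - d),
         max_lag = 1 / (L - xi),
         global  = 1 / L,
         stop("unknown norm '", norm, "'"))
}

#' Column means of a PSSM
#'
#' Entry j is the average score of the protein's residues against amino-acid
#' type j -- the 20-dimensional composition-like core shared by the whole
#' pseudo-PSSM family.
#'
#' @param m A [pssm_matrix()].
#' @return Length-20 numeric vector named by amino acid.
#' @export
column_means <- function(m) {
  stopifnot(inherits(m, "PssmMatrix"))
  mu <- colMeans(m$scores)
  names(mu) <- paste0("mean_", colnames(m$scores))
  mu
}

#' Marginal sums of a PSSM
#'
#' Row sums R_k (one per residue), column sums S_c (one per amino acid), and
#' their scalar means, used as centering constants by the T2/T3 encoders.
#'
#' @param m A [pssm_matrix()].
#' @return List with `row_sums`, `col_sums`, `row_mean`, `col_mean`.
#' @export
marginal_sums <- function(m) {
  stopifnot(inherits(m, "PssmMatrix"))
  rs <- rowSums(m$scores)
  cs <- colSums(m$scores)
  list(row_sums = rs, col_sums = cs,
       row_mean = mean(rs), col_mean = mean(cs))
}

#' Traditional pseudo-PSSM encoder (sequence-axis lags)
#'
#' The classical baseline: 20 column means followed, for each lag d = 1..xi
#' and each amino-acid column j, by the mean squared difference between
#' scores d residues apart in the same column,
#' (1/(L-d)) * sum_i (M[i,j] - M[i+d,j])^2.  Output dimension 20 + 20*xi.
#'
#' @param m A [pssm_matrix()].
#' @param xi Lag bound, 0 <= xi < L.
#' @return A [feature_vector()] of length 20 + 20*xi.
#' @export
psepssm <- function(m, xi) {
  stopifnot(inherits(m, "PssmMatrix"))
  L <- nrow(m$scores)
  if (xi < 0 || xi != round(xi)) stop("xi must be a non-negative integer")
  if (xi >= L) stop("xi (", xi, ") must be smaller than sequence length (",
                    L, ")")
  vals <- column_means(m)
  M <- m$scores
  for (d in seq_len(xi)) {
    diffs <- M[seq_len(L - d), , drop = FALSE] -
             M[seq_len(L - d) + d, , drop = FALSE]
    lag <- colSums(diffs^2) / (L - d)
    names(lag) <- paste0("lag", d, "_", colnames(M))
    vals <- c(vals, lag)
  }
  feature_vector(m$id, vals, "psepssm", list(xi = xi))
}

# Shared driver for the column-lag family.  For lag d and left column n
# (n = 1..20-d) the per-pair factor is norm(d) * sum over all L rows of
# `term(M[,n], M[,n+d])`; factors are laid out lag-major, column-minor after
# the 20 means.  Dimension: 20 + sum_{d=1..xi}(20-d) = (20+20xi) - xi(xi+1)/2.
column_lag_encode <- function(m, xi, term, tag, norm) {
  stopifnot(inherits(m, "PssmMatrix"))
  L <- nrow(m$scores)
  if (xi < 0 || xi != round(xi)) stop("xi must be a non-negative integer")
  if (xi > 19) stop("xi (", xi, ") leaves no column pairs; need xi <= 19")
  M <- m$scores
  vals <- column_means(m)
  for (d in seq_len(xi)) {
    nf <- norm_factor(L, d, xi, norm)
    idx <- seq_len(20L - d)
    fac <- vapply(idx, function(n) nf * sum(term(M[, n], M[, n + d])),
                  numeric(1L))
    names(fac) <- paste0(tag, "_d", d, "_n", idx)
    vals <- c(vals, fac)
  }
  vals
}

#' Improved pseudo-PSSM encoder (column-axis lags)
#'
#' Instead of lagging along the sequence, the improved encoder pairs
#' *different* amino-acid columns: for each column distance d = 1..xi and
#' each left column n = 1..20-d it accumulates the squared difference
#' between columns n and n+d over all L residues, scaled by the
#' normalisation prefactor.  Because only 20-d column pairs exist at
#' distance d, the dimension is (20 + 20*xi) - xi*(xi+1)/2 -- lower than the
#' sequence-lag baseline at equal xi.
#'
#' @param m A [pssm_matrix()].
#' @param xi Column-lag bound, 0 <= xi <= 19 (xi = 0 degenerates to the bare
#'   column means).
#' @param norm Normalisation prefactor: `"per_lag"` (1/(L-d), default),
#'   `"max_lag"` (1/(L-xi)) or `"global"` (1/L).
#' @return A [feature_vector()] of length (20 + 20*xi) - xi*(xi+1)/2.
#' @export
im_psepssm <- function(m, xi, norm = c("per_lag", "max_lag", "global")) {
  norm <- match.arg(norm)
  vals <- column_lag_encode(m, xi, function(a, b) (a - b)^2, "T", norm)
  feature_vector(m$id, vals, "im_psepssm", list(xi = xi, norm = norm))
}

#' Cross-product variant of the column-lag encoder (T1)
#'
#' Same layout as [im_psepssm()] but the per-pair factor is the raw
#' cross-product sum over rows of M[,n] * M[,n+d] (no centering), so unlike
#' the squared-difference form it is not invariant to adding a constant to
#' the matrix.
#'
#' @inheritParams im_psepssm
#' @return A [feature_vector()]; dimension as [im_psepssm()].
#' @export
t1_im_pssm <- function(m, xi, norm = c("per_lag", "max_lag", "global")) {
  norm <- match.arg(norm)
  vals <- column_lag_encode(m, xi, function(a, b) a * b, "T1", norm)
  feature_vector(m$id, vals, "t1", list(xi = xi, norm = norm))
}

#' Row-sum-centered cross-product variant (T2)
#'
#' As [t1_im_pssm()] with both factors centered by the scalar mean of the
#' PSSM row sums before multiplying.
#'
#' @inheritParams im_psepssm
#' @return A [feature_vector()]; dimension as [im_psepssm()].
#' @export
t2_im_pssm <- function(m, xi, norm = c("per_lag", "max_lag", "global")) {
  norm <- match.arg(norm)
  ctr <- marginal_sums(m)$row_mean
  vals <- column_lag_encode(m, xi, function(a, b) (a - ctr) * (b - ctr),
                            "T2", norm)
  feature_vector(m$id, vals, "t2", list(xi = xi, norm = norm))
}

#' Column-sum-centered cross-product variant (T3)
#'
#' As [t2_im_pssm()] with the centering constant taken as the scalar mean of
#' the PSSM column sums.
#'
#' @inheritParams im_psepssm
#' @return A [feature_vector()]; dimension as [im_psepssm()].
#' @export
t3_im_pssm <- function(m, xi, norm = c("per_lag", "max_lag", "global")) {
  norm <- match.arg(norm)
  ctr <- marginal_sums(m)$col_mean
  vals <- column_lag_encode(m, xi, function(a, b) (a - ctr) * (b - ctr),
                            "T3", norm)
  feature_vector(m$id, vals, "t3", list(xi = xi, norm = norm))
}

#' Bidirectional cross-correlation encoder (Bid-CC)
#'
#' For a residue distance S, every ordered amino-acid pair (a, b) yields one
#' entry: the sum over positions i = 1..L-S of M[i,a] * M[i+S,b].  Both (a,b)
#' and (b,a) appear among the 400 entries, which is what makes the descriptor
#' bidirectional for a single forward distance.  Output is laid out row-major
#' by (a, b) in PSSM column order and always has length 400 regardless of L.
#'
#' @param m A [pssm_matrix()].
#' @param S Residue distance, 1 <= S < L.
#' @return A [feature_vector()] of length 400.
#' @export
bid_cc <- function(m, S) {
  stopifnot(inherits(m, "PssmMatrix"))
  L <- nrow(m$scores)
  if (S < 1 || S != round(S)) stop("S must be a positive integer")
  if (S >= L) stop("S (", S, ") must be smaller than sequence length (",
                   L, ")")
  M <- m$scores
  Tab <- crossprod(M[seq_len(L - S), , drop = FALSE],
                   M[seq_len(L - S) + S, , drop = FALSE])  # Tab[a, b]
  vals <- as.vector(t(Tab))                                 # row-major (a, b)
  aa <- colnames(M)
  names(vals) <- paste0("bidcc_S", S, "_",
                        rep(aa, each = 20L), "_", rep(aa, 20L))
  feature_vector(m$id, vals, "bidcc", list(S = S))
}

#' Fuse feature vectors into one encoding
#'
#' Concatenates per-protein feature blocks (e.g. the improved pseudo-PSSM and
#' the bidirectional cross-correlation) in the declared order, producing the
#' fused encoding.  All parts must describe the same protein.
#'
#' @param parts List of [feature_vector()] objects sharing one `id`.
#' @return A [feature_vector()] with `encoder = "bim_pssm"` whose length is
#'   the sum of the part lengths.
#' @export
fuse <- function(parts) {
  if (inherits(parts, "FeatureVector")) parts <- list(parts)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1L), "FeatureVector")))
  ids <- vapply(parts, `[[`, character(1L), "id")
  if (length(unique(ids)) != 1L)
    stop("cannot fuse features of different proteins: ",
         paste(unique(ids), collapse = ", "))
  vals <- do.call(c, lapply(parts, `[[`, "values"))
  feature_vector(ids[1L], vals, "bim_pssm",
                 list(parts = lapply(parts, function(p)
                   c(list(encoder = p$encoder), p$params))))
}

#' Encode a collection of PSSMs into a feature matrix
#'
#' Applies one encoder specification to every matrix in a collection and
#' stacks the results into a constant-width numeric matrix with one row per
#' protein, in input order.  `encoder = "bim_pssm"` fuses the column-lag
#' encoder at `xi` with the bidirectional cross-correlation at each value in
#' `S`.
#'
#' @param matrices List of [pssm_matrix()] objects.
#' @param encoder Encoder name (see [feature_vector()]).
#' @param xi Lag bound for the pseudo-PSSM family.
#' @param S Residue distance(s) for the bidirectional cross-correlation.
#' @param scale Apply [sigmoid_scale()] first (skipped for matrices already
#'   scaled).  Raw-score encoding (`scale = FALSE`) is provided for ablation.
#' @param norm Normalisation prefactor for the column-lag family.
#' @return Numeric matrix, rownames = protein ids, colnames = feature names.
#' @export
encode_collection <- function(matrices, encoder, xi = NULL, S = NULL,
                              scale = TRUE,
                              norm = c("per_lag", "max_lag", "global")) {
  norm <- match.arg(norm)
  encoder <- match.arg(encoder, c("psepssm", "im_psepssm", "t1", "t2", "t3",
                                  "bidcc", "bim_pssm"))
  stopifnot(length(matrices) >= 1L)
  ids <- vapply(matrices, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate protein ids in collection")
  rows <- lapply(matrices, function(m) {
    fv <- tryCatch(
      encode_one(m, encoder, xi = xi, S = S, scale = scale, norm = norm),
      error = function(e) stop("encoding failed for protein '", m$id,
                               "': ", conditionMessage(e), call. = FALSE))
    fv$values
  })
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stop("inconsistent feature widths across proteins")
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  X
}

encode_one <- function(m, encoder, xi = NULL, S = NULL, scale = TRUE,
                       norm = "per_lag") {
  if (scale && !m$scaled) m <- sigmoid_scale(m)
  switch(encoder,
         psepssm    = psepssm(m, xi),
         im_psepssm = im_psepssm(m, xi, norm),
         t1         = t1_im_pssm(m, xi, norm),
         t2         = t2_im_pssm(m, xi, norm),
         t3         = t3_im_pssm(m, xi, norm),
         bidcc      = {
           parts <- lapply(S, function(s) bid_cc(m, s))
           if (length(parts) == 1L) parts[[1L]] else fuse(parts)
         },
         bim_pssm   = fuse(c(list(im_psepssm(m, xi, norm)),
                             lapply(S, function(s) bid_cc(m, s)))))
}

#' Closed-form feature dimensions
#'
#' Returns the expected output length of each encoder for given parameters:
#' `20 + 20*xi` for the sequence-lag baseline, `(20 + 20*xi) - xi*(xi+1)/2`
#' for the column-lag family, and `400 * length(S)` for the bidirectional
#' cross-correlation.
#'
#' @inheritParams encode_collection
#' @return Integer dimension.
#' @export
feature_dimension <- function(encoder, xi = NULL, S = NULL) {
  encoder <- match.arg(encoder, c("psepssm", "im_psepssm", "t1", "t2", "t3",
                                  "bidcc", "bim_pssm"))
  imdim <- function(xi) as.integer((20 + 20 * xi) - xi * (xi + 1) / 2)
  switch(encoder,
         psepssm    = as.integer(20 + 20 * xi),
         im_psepssm = imdim(xi),
         t1         = imdim(xi),
         t2         = imdim(xi),
         t3         = imdim(xi),
         bidcc      = 400L * length(S),
         bim_pssm   = imdim(xi) + 400L * length(S))
}

#' Write a feature matrix to CSV
#'
#' Id column first, then one named column per feature.
#'
#' @param X Feature matrix with rownames (protein ids).
#' @param path Output CSV path.
#' @param provenance Optional character vector (e.g. `"original"` or
#'   `"synthetic:<parent>"`) written as a final column.
#' @export
write_feature_csv <- function(X, path, provenance = NULL) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   row.names = NULL)
  if (!is.null(provenance)) df$provenance <- provenance
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return List with `X` (matrix, rownames = ids) and `provenance` (or NULL).
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  prov <- NULL
  if ("provenance" %in% names(df)) {
    prov <- df$provenance
    df$provenance <- NULL
  }
  X <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(X) <- df$id
  list(X = X, provenance = prov)
}
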