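# Independent naive oracles: straightforward loop implementations kept
# deliberately separate from the package's vectorised code paths.

rand_pssm <- function(id = "P", L = 30L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pssm_matrix(id, matrix(stats::runif(L * 20L, -5, 5), L, 20L))
}

naive_column_means <- function(M) {
  out <- numeric(20L)
  for (j in 1:20) {
    s <- 0
    for (i in seq_len(nrow(M))) s <- s + M[i, j]
    out[j] <- s / nrow(M)
  }
  out
}

naive_psepssm <- function(M, xi) {
  L <- nrow(M)
  out <- naive_column_means(M)
  for (d in seq_len(xi)) {
    for (j in 1:20) {
      s <- 0
      for (i in seq_len(L - d)) s <- s + (M[i, j] - M[i + d, j])^2
      out <- c(out, s / (L - d))
    }
  }
  out
}

# Column-lag family; `term(x, y)` is the per-entry factor.
naive_column_lag <- function(M, xi, term, norm = "per_lag") {
  L <- nrow(M)
  out <- naive_column_means(M)
  for (d in seq_len(xi)) {
    nf <- switch(norm, per_lag = 1 / (L - d), max_lag = 1 / (L - xi),
                 global = 1 / L)
    for (n in seq_len(20L - d)) {
      s <- 0
      for (m in seq_len(L)) s <- s + term(M[m, n], M[m, n + d])
      out <- c(out, nf * s)
    }
  }
  out
}

naive_im <- function(M, xi, norm = "per_lag")
  naive_column_lag(M, xi, function(a, b) (a - b)^2, norm)
naive_t1 <- function(M, xi, norm = "per_lag")
  naive_column_lag(M, xi, function(a, b) a * b, norm)
naive_t2 <- function(M, xi, norm = "per_lag") {
  ctr <- mean(rowSums(M))
  naive_column_lag(M, xi, function(a, b) (a - ctr) * (b - ctr), norm)
}
naive_t3 <- function(M, xi, norm = "per_lag") {
  ctr <- mean(colSums(M))
  naive_column_lag(M, xi, function(a, b) (a - ctr) * (b - ctr), norm)
}

naive_bidcc <- function(M, S) {
  L <- nrow(M)
  out <- numeric(0L)
  for (a in 1:20) {
    for (b in 1:20) {
      s <- 0
      for (i in seq_len(L - S)) s <- s + M[i, a] * M[i + S, b]
      out <- c(out, s)
    }
  }
  out
}

# Brute-force one-vs-rest recount straight from the label pairs.
naive_counts <- function(y_true, y_pred, cl) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == cl && y_pred[i] == cl) tp <- tp + 1L
    else if (y_true[i] == cl) fn <- fn + 1L
    else if (y_pred[i] == cl) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Brute-force ENN survivors: 3-NN majority vote on the original set.
naive_enn_keep <- function(X, y, k = 3L) {
  n <- nrow(X)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    keep[i] <- sum(y[nb] != y[i]) < 2L
  }
  keep
}
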