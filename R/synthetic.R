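#' Specification for a synthetic labeled PSSM collection
#'
#' Describes the stated world the generator emulates: per-class collection
#' sizes (default 43/30/13/12, the shape of a small four-location apoptosis
#' benchmark), per-protein length range, class-dependent mean column
#' profiles, Gaussian score noise, and an optional column-lag coupling that
#' plants class signal where the column-lag encoders look for it.
#'
#' @param n_per_class Positive integers, one per class.
#' @param length_range `(L_min, L_max)` for per-protein row counts; `L_min`
#'   must exceed the largest lag/distance parameter under test.
#' @param class_profiles Optional K x 20 matrix of mean raw scores per class;
#'   by default class k is raised by `separation` on its own block of five
#'   alphabet columns (cycling), against a baseline of zero.
#' @param noise_sd Standard deviation of the additive Gaussian score noise.
#' @param separation Mean shift that distinguishes classes in the default
#'   profiles (raw log-odds units).
#' @param lag_signal Optional coupling strength between adjacent alphabet
#'   columns, with a class-dependent coefficient, so that column-lag
#'   features carry signal beyond the column means.
#' @param p Feature dimension for [generate_feature_blobs()].
#' @param seed Integer seed; the whole collection is deterministic in it.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_per_class = c(43L, 30L, 13L, 12L),
                           length_range = c(50L, 120L),
                           class_profiles = NULL,
                           noise_sd = 2, separation = 4,
                           lag_signal = 0, p = 10L, seed = 1L) {
  if (any(n_per_class < 1L)) stop("n_per_class must be positive")
  if (length(length_range) != 2L || length_range[1L] > length_range[2L] ||
      length_range[1L] < 2L)
    stop("length_range must be (L_min, L_max) with 2 <= L_min <= L_max")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  K <- length(n_per_class)
  if (is.null(class_profiles)) {
    class_profiles <- matrix(0, K, 20L)
    for (k in seq_len(K)) {
      cols <- ((k - 1L) * 5L + 0:4) %% 20L + 1L
      class_profiles[k, cols] <- separation
    }
  }
  class_profiles <- as.matrix(class_profiles)
  if (nrow(class_profiles) != K || ncol(class_profiles) != 20L)
    stop("class_profiles must be K x 20")
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 class_profiles = class_profiles,
                 noise_sd = noise_sd, separation = separation,
                 lag_signal = lag_signal, p = as.integer(p),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a labeled collection of synthetic PSSMs
#'
#' Each protein's raw scores are its class profile plus Gaussian noise, with
#' row count uniform over the length range; when `lag_signal > 0` a
#' class-dependent fraction of each column is added to its right-hand
#' neighbour, planting column-lag covariance.  Scores are rounded to
#' integers and clipped to [-10, 12] to resemble profile-search log-odds,
#' and matrices are returned unscaled.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrices` (list of [pssm_matrix()]) and `labels`
#'   (factor `C1..CK`, one per matrix, in matrix order).
#' @export
generate_pssms <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_local_seed(spec$seed, {
    K <- length(spec$n_per_class)
    coef <- if (K > 1L)
      spec$lag_signal * seq(-1, 1, length.out = K) else spec$lag_signal
    matrices <- list()
    labels <- character()
    for (k in seq_len(K)) {
      for (i in seq_len(spec$n_per_class[k])) {
        L <- sample(seq(spec$length_range[1L], spec$length_range[2L]), 1L)
        M <- matrix(rep(spec$class_profiles[k, ], each = L), L, 20L) +
          matrix(stats::rnorm(L * 20L, sd = spec$noise_sd), L, 20L)
        if (spec$lag_signal > 0)
          M[, 2:20] <- M[, 2:20] + coef[k] * M[, 1:19]
        M <- pmin(pmax(round(M), -10), 12)
        id <- sprintf("C%d_P%03d", k, i)
        matrices[[length(matrices) + 1L]] <- pssm_matrix(id, M)
        labels <- c(labels, paste0("C", k))
      }
    }
    list(matrices = matrices, labels = factor(labels))
  })
}

#' Generate labeled Gaussian feature blobs
#'
#' Draws class-conditional spherical Gaussians directly in feature space for
#' unit-testing the resamplers and the classifier in isolation: class k is
#' centred at `separation` along basis axis k (cycling through the `p`
#' dimensions), with isotropic noise `noise_sd`.
#'
#' @param spec A [synthetic_spec()]; uses `n_per_class`, `p`, `separation`,
#'   `noise_sd` and `seed`.
#' @return A [labeled_feature_set()].
#' @export
generate_feature_blobs <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_local_seed(spec$seed, {
    K <- length(spec$n_per_class)
    n <- sum(spec$n_per_class)
    X <- matrix(0, n, spec$p)
    y <- character(n)
    row <- 0L
    for (k in seq_len(K)) {
      mu <- numeric(spec$p)
      mu[(k - 1L) %% spec$p + 1L] <- spec$separation
      for (i in seq_len(spec$n_per_class[k])) {
        row <- row + 1L
        X[row, ] <- mu + stats::rnorm(spec$p, sd = spec$noise_sd)
        y[row] <- paste0("C", k)
      }
    }
    labeled_feature_set(X, y, ids = sprintf("b%03d", seq_len(n)))
  })
}

#' Write a PSSM collection in the PSI-BLAST ASCII dialect
#'
#' Emits one `<id>.pssm` file per matrix in the same layout the parser reads
#' (header with the duplicated 20-letter column ordering, residue rows with
#' log-odds and a zero percentage block, trailing statistics line) plus a
#' `labels.csv` mapping id to class.  Round-tripping through
#' [parse_ascii_pssm()] reproduces the scores exactly for integer matrices.
#'
#' @param collection List as returned by [generate_pssms()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pssm_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- PSSM_ALPHABET
  for (j in seq_along(collection$matrices)) {
    m <- collection$matrices[[j]]
    if (m$scaled) stop("collections are written on the raw integer scale")
    lines <- c(
      "",
      paste("Last position-specific scoring matrix computed, weighted",
            "observed percentages rounded down, information per position,",
            "and relative weight of gapless real matches to pseudocounts"),
      paste0("            ", paste(sprintf("%3s", c(aa, aa)), collapse = "")))
    for (i in seq_len(nrow(m$scores))) {
      res <- aa[which.max(m$scores[i, ])]
      lines <- c(lines, paste0(
        sprintf("%5d %s  ", i, res),
        paste(sprintf("%3d", as.integer(round(m$scores[i, ]))),
              collapse = ""),
        paste(sprintf("%4d", integer(20L)), collapse = ""),
        sprintf("  %5.2f %9.2f", 0, 0)))
    }
    lines <- c(lines, "", sprintf("%22s %.4f %.4f", "K         Lambda",
                                  0.0410, 0.2670))
    writeLines(lines, file.path(dir, paste0(m$id, ".pssm")))
  }
  utils::write.csv(
    data.frame(id = vapply(collection$matrices, `[[`, character(1L), "id"),
               class = as.character(collection$labels)),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a PSSM collection directory written by [write_pssm_collection()]
#'
#' @param dir Directory containing `<id>.pssm` files and `labels.csv`.
#' @return List with `matrices` and `labels`, ordered as in `labels.csv`.
#' @export
read_pssm_collection <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  matrices <- lapply(lab$id, function(id) {
    path <- file.path(dir, paste0(id, ".pssm"))
    if (!file.exists(path)) stop("missing PSSM file for id '", id, "'")
    parse_ascii_pssm(path, id = id)
  })
  list(matrices = matrices, labels = factor(lab$class))
}
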