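#' PSI-BLAST native amino-acid column order
#'
#' The fixed 20-symbol ordering in which PSI-BLAST emits the columns of an
#' ASCII PSSM (`-out_ascii_pssm`).  Feature positions in every encoder are
#' defined relative to this ordering, so it is preserved verbatim on parse and
#' never re-sorted.
#'
#' @format Character vector of the 20 standard amino-acid one-letter codes.
#' @export
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a PSSM matrix object
#'
#' A `PssmMatrix` holds the L x 20 position-specific score matrix of one
#' protein: one row per residue, one column per amino-acid type in the
#' PSI-BLAST native column order.  Raw PSI-BLAST scores are integer log-odds;
#' after [sigmoid_scale()] every entry lies strictly in (0, 1) and the
#' `scaled` flag is set.
#'
#' @param id Non-empty sequence identifier.
#' @param scores Numeric L x 20 matrix (L >= 1).  Column names, if absent,
#'   are set to [PSSM_ALPHABET].
#' @param scaled Logical; whether the sigmoid transform has been applied.
#' @return An object of class `PssmMatrix`.
#' @examples
#' m <- pssm_matrix("P1", matrix(0, 5, 20))
#' dim(m$scores)
#' @export
pssm_matrix <- function(id, scores, scaled = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string")
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("PSSM must have exactly 20 columns, got ", ncol(scores))
  if (nrow(scores) < 1L)
    stop("PSSM must have at least one row")
  if (!is.numeric(scores) || any(!is.finite(scores)))
    stop("PSSM scores must be finite numbers")
  if (is.null(colnames(scores))) colnames(scores) <- PSSM_ALPHABET
  if (isTRUE(scaled) && (any(scores <= 0) || any(scores >= 1)))
    stop("scaled PSSM entries must lie strictly in (0, 1)")
  structure(list(id = id, scores = scores, scaled = isTRUE(scaled)),
            class = "PssmMatrix")
}

#' @export
print.PssmMatrix <- function(x, ...) {
  cat(sprintf("PssmMatrix '%s': %d x 20 (%s)\n", x$id, nrow(x$scores),
              if (x$scaled) "sigmoid-scaled" else "raw log-odds"))
  invisible(x)
}

#' Read a multi-record FASTA file of protein sequences
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] adding the validation
#' this pipeline needs: the file must be non-empty and well-formed, and record
#' identifiers (the first whitespace-delimited token of each header) must be
#' unique.  Ambiguity codes (B, Z, X, U, ...) are accepted and flagged in the
#' `ambiguous` field rather than rejected: the paired PSSM row is whatever the
#' profile search produced for that residue.
#'
#' @param path Path to a FASTA file.
#' @return A list of records, each a list with fields `id`, `sequence` and
#'   `ambiguous` (logical), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: line ", first, " is not a '>' header")
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (any(!nzchar(ids))) stop("malformed FASTA: empty record identifier")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifiers: ", paste(unique(dup), collapse = ", "))
  seqs <- unname(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("zero-length sequence for record ", ids[nchar(seqs) == 0L][1L])
  lapply(seq_along(ids), function(i) {
    list(id = ids[i], sequence = seqs[i],
         ambiguous = grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs[i]))
  })
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard `-out_ascii_pssm` layout: a couple of header lines, one
#' of which lists the 20 amino-acid column letters (twice -- once for the
#' log-odds block, once for the weighted-percentage block), then one line per
#' residue starting with the position index and residue letter followed by 20
#' integer log-odds and 20 percentages, then trailing statistics lines.  Only
#' the first numeric block (the position-specific log-odds scores) is kept.
#'
#' @param path Path to an ASCII PSSM file.
#' @param id Identifier for the resulting matrix; defaults to the file name
#'   without extension.
#' @return A [pssm_matrix()] with `scaled = FALSE` and columns in the order
#'   the file declares (PSI-BLAST native order).
#' @export
parse_ascii_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  # locate the column-letter header: >= 20 single-letter AA fields
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) >= 20L && all(toks %in% PSSM_ALPHABET)) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at))
    stop("not a PSI-BLAST ASCII PSSM: no amino-acid column header in ", path)
  col_order <- strsplit(trimws(lines[header_at]), "\\s+")[[1L]][1:20]

  rows <- list()
  residues <- character()
  for (i in seq(header_at + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) {
      if (length(rows)) break else next   # blank line ends the residue block
    }
    toks <- strsplit(ln, "\\s+")[[1L]]
    # residue rows: "<pos> <letter> <40+ numbers>"
    if (!grepl("^[0-9]+$", toks[1L])) {
      if (length(rows)) break             # trailing statistics block
      stop("PSSM format error at line ", i, ": expected residue row")
    }
    if (length(toks) < 2L || !grepl("^[A-Z]$", toks[2L]))
      stop("PSSM format error at line ", i, ": missing residue letter")
    nums <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (length(nums) < 40L || any(is.na(nums[1:40])))
      stop("PSSM format error at line ", i, " (residue row ",
           length(rows) + 1L, "): need 40 numeric fields, got ",
           sum(!is.na(nums)))
    rows[[length(rows) + 1L]] <- nums[1:20]
    residues <- c(residues, toks[2L])
  }
  if (!length(rows)) stop("PSSM file has no residue rows: ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  rownames(scores) <- NULL
  m <- pssm_matrix(id, scores, scaled = FALSE)
  attr(m, "residues") <- residues
  m
}

#' Sigmoid-scale a PSSM
#'
#' Applies the logistic transform f(x) = 1 / (1 + exp(-x)) entry-wise, mapping
#' the integer log-odds onto (0, 1) to damp the influence of extreme scores
#' before feature encoding.  Scaling twice is a usage error: the transform is
#' not idempotent and a double application silently compresses all signal.
#'
#' @param m A [pssm_matrix()] with `scaled = FALSE`.
#' @return The same matrix with every entry transformed and `scaled = TRUE`.
#' @export
sigmoid_scale <- function(m) {
  stopifnot(inherits(m, "PssmMatrix"))
  if (m$scaled) stop("PSSM '", m$id, "' is already sigmoid-scaled")
  out <- m
  out$scores <- 1 / (1 + exp(-m$scores))
  out$scaled <- TRUE
  out
}

#' Check a PSSM against its FASTA record
#'
#' Row count of the score matrix must equal the residue count of the paired
#' sequence; a mismatch raises a warning (never silent truncation).
#'
#' @param m A [pssm_matrix()].
#' @param record A record from [read_fasta()] with a matching `id`.
#' @return `TRUE` invisibly if consistent, `FALSE` invisibly after warning.
#' @export
validate_pssm_against_fasta <- function(m, record) {
  stopifnot(inherits(m, "PssmMatrix"))
  if (!identical(m$id, record$id))
    stop("id mismatch: PSSM '", m$id, "' vs FASTA '", record$id, "'")
  L <- nchar(record$sequence)
  if (nrow(m$scores) != L) {
    warning("PSSM '", m$id, "' has ", nrow(m$scores),
            " rows but the FASTA sequence has ", L, " residues")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Write PSSM matrices to the package TSV dump format
#'
#' One line per residue: id, row index, then 20 tab-separated scores at full
#' double precision so that a read-back reproduces the matrix exactly.
#'
#' @param matrices A `PssmMatrix` or list of them.
#' @param path Output file path.
#' @export
write_pssm_tsv <- function(matrices, path) {
  if (inherits(matrices, "PssmMatrix")) matrices <- list(matrices)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", "row", colnames(matrices[[1L]]$scores), "scaled"),
                   collapse = "\t"), con)
  for (m in matrices) {
    for (i in seq_len(nrow(m$scores))) {
      writeLines(paste(c(m$id, i, sprintf("%.17g", m$scores[i, ]),
                         as.integer(m$scaled)), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read PSSM matrices from the package TSV dump format
#'
#' @param path File written by [write_pssm_tsv()].
#' @return A list of [pssm_matrix()] objects in first-appearance order.
#' @export
read_pssm_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty PSSM TSV: ", path)
  cols <- names(df)[3:22]
  out <- list()
  for (the_id in unique(df$id)) {
    sub <- df[df$id == the_id, , drop = FALSE]
    sub <- sub[order(as.integer(sub$row)), , drop = FALSE]
    scores <- as.matrix(vapply(sub[cols], as.numeric, numeric(nrow(sub))))
    if (nrow(sub) == 1L) scores <- matrix(scores, 1L, 20L,
                                          dimnames = list(NULL, cols))
    colnames(scores) <- cols
    out[[length(out) + 1L]] <- pssm_matrix(the_id, scores,
                                           scaled = sub$scaled[1L] == "1")
  }
  out
}
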