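#' Read RNA/DNA sequences from a FASTA file
#'
#' Reads a FASTA file into a named character vector of uppercase sequences.
#' Both DNA and RNA alphabets are accepted; `U` and `T` are treated as the
#' same symbol by all downstream feature extraction. The ambiguity code `N`
#' is tolerated here and ignored during k-mer counting; any other letter is
#' an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are record ids (first whitespace
#'   token of each header), values are uppercase sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">l1", "ACGU", ">l2", "GGAU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyNA(ids) || any(ids == "")) {
    stop("FASTA file contains a record with an empty header", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) {
    stop("sequence with characters outside {A,C,G,T,U,N}: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("`seqs` must have unique names", call. = FALSE)
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a lncRNA-miRNA interaction list into a binary matrix
#'
#' Reads a two-column TSV of `(lncRNA_id, miRNA_id)` pairs and returns the
#' binary interaction matrix `Y` with rows ordered by `lnc_ids` and columns
#' by `mir_ids`. Duplicated pairs collapse to a single 1. Pairs naming an
#' unknown id are an error unless `skip_unknown = TRUE`, in which case they
#' are dropped with a warning (silent id/index drift is the classic bug in
#' id-indexed matrices, so strictness is the default).
#'
#' @param path Path to a TSV with two columns and no header.
#' @param lnc_ids Character vector fixing the row order.
#' @param mir_ids Character vector fixing the column order.
#' @param skip_unknown Drop pairs with unknown ids instead of failing.
#' @return Binary matrix `length(lnc_ids) x length(mir_ids)` with dimnames.
#' @export
read_interactions <- function(path, lnc_ids, mir_ids, skip_unknown = FALSE) {
  if (!file.exists(path)) stop("interaction file not found: ", path, call. = FALSE)
  if (anyDuplicated(lnc_ids)) stop("`lnc_ids` must be unique", call. = FALSE)
  if (anyDuplicated(mir_ids)) stop("`mir_ids` must be unique", call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("interaction TSV must have two columns", call. = FALSE)
  interaction_matrix(tab[[1L]], tab[[2L]], lnc_ids, mir_ids,
                     skip_unknown = skip_unknown)
}

#' Build a binary interaction matrix from paired id vectors
#'
#' @param lnc Character vector of lncRNA ids (one per interaction).
#' @param mir Character vector of miRNA ids, same length as `lnc`.
#' @inheritParams read_interactions
#' @return Binary matrix with dimnames `list(lnc_ids, mir_ids)`.
#' @export
interaction_matrix <- function(lnc, mir, lnc_ids, mir_ids, skip_unknown = FALSE) {
  ri <- match(lnc, lnc_ids)
  ci <- match(mir, mir_ids)
  unknown <- is.na(ri) | is.na(ci)
  if (any(unknown)) {
    offending <- unique(c(lnc[is.na(ri)], mir[is.na(ci)]))
    if (!skip_unknown) {
      stop("interaction pair references unknown id(s): ",
           paste(offending, collapse = ", "), call. = FALSE)
    }
    warning("skipping ", sum(unknown), " pair(s) with unknown id(s): ",
            paste(offending, collapse = ", "), call. = FALSE)
    ri <- ri[!unknown]; ci <- ci[!unknown]
  }
  Y <- matrix(0, length(lnc_ids), length(mir_ids),
              dimnames = list(lnc_ids, mir_ids))
  Y[cbind(ri, ci)] <- 1
  Y
}

#' Write an interaction matrix back to a two-column TSV
#'
#' Pairs are written in row-major order (by lncRNA, then miRNA index), so
#' the output is deterministic for a given matrix.
#'
#' @param Y Binary interaction matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(Y, path) {
  stopifnot_matrix(Y)
  idx <- which(t(Y) == 1)  # transpose so ordering is row-major in Y
  m <- ncol(Y)
  ri <- (idx - 1L) %/% m + 1L
  ci <- (idx - 1L) %% m + 1L
  utils::write.table(
    data.frame(lnc = rownames(Y)[ri], mir = colnames(Y)[ci]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a numeric matrix as TSV with row and column names
#'
#' @param path File path.
#' @return `read_matrix_tsv`: numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_matrix_tsv
#' @param X Numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(X, path) {
  stopifnot_matrix(X)
  utils::write.table(
    data.frame(id = rownames(X), X, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ranked pair predictions to TSV
#'
#' Writes one row per lncRNA-miRNA pair with columns
#' `(lncRNA_id, miRNA_id, score, known)`, sorted by descending score with
#' ties broken lexicographically by `(lncRNA_id, miRNA_id)` so output is
#' deterministic. Training positives (cells of `Y_known` equal to 1) are
#' flagged in the `known` column and, when `mask_known = TRUE`, excluded
#' from the ranking altogether.
#'
#' @param P Prediction score matrix with dimnames (lncRNAs x miRNAs).
#' @param path Output path.
#' @param Y_known Optional binary matrix of known (training) interactions,
#'   aligned with `P`.
#' @param mask_known Exclude known positives from the output ranking.
#' @return The written data frame, invisibly.
#' @export
write_predictions <- function(P, path, Y_known = NULL, mask_known = FALSE) {
  stopifnot_matrix(P)
  if (is.null(rownames(P)) || is.null(colnames(P))) {
    stop("`P` must carry lncRNA/miRNA ids as dimnames", call. = FALSE)
  }
  known <- if (is.null(Y_known)) {
    matrix(0, nrow(P), ncol(P))
  } else {
    if (!all(dim(Y_known) == dim(P))) {
      stop("`Y_known` and `P` must have identical dimensions", call. = FALSE)
    }
    Y_known
  }
  df <- data.frame(
    lncRNA_id = rep(rownames(P), times = ncol(P)),
    miRNA_id  = rep(colnames(P), each = nrow(P)),
    score     = as.vector(P),
    known     = as.integer(as.vector(known) == 1),
    stringsAsFactors = FALSE)
  if (mask_known) df <- df[df$known == 0L, , drop = FALSE]
  df <- df[order(-df$score, df$lncRNA_id, df$miRNA_id), , drop = FALSE]
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
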