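#' k-mer frequency features from sequences
#'
#' Converts each sequence into its vector of overlapping k-mer frequencies:
#' counts of every length-`k` window (step 1) over the alphabet `{A,C,G,T}`,
#' divided by the number of counted windows so each row sums to 1. `U` is
#' mapped to `T` before counting, so RNA and DNA spellings of the same
#' sequence yield identical features. Windows containing `N` contribute no
#' count. Feature columns are the `4^k` words in lexicographic order
#' (`A < C < G < T`).
#'
#' With the default `k = 5` the feature space has 1024 dimensions, large
#' enough to separate transcripts by local composition yet small enough
#' that the Euclidean geometry used by the neighborhood reconstruction
#' remains meaningful for a few hundred entities.
#'
#' @param seqs Named character vector of sequences over `{A,C,G,T,U,N}`
#'   (case-insensitive), e.g. from [read_fasta()].
#' @param k Word length, a positive integer (default 5).
#' @return Numeric matrix, one row per sequence (rownames = ids), `4^k`
#'   columns named by k-mer.
#' @examples
#' kmer_features(c(s1 = "ACGT"), k = 1)
#' @export
kmer_features <- function(seqs, k = 5) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (length(seqs) == 0L) stop("no sequences supplied", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("`seqs` must have unique names", call. = FALSE)
  }
  clean <- chartr("U", "T", toupper(seqs))
  bad <- grepl("[^ACGTN]", clean)
  if (any(bad)) {
    stop("sequence with characters outside {A,C,G,T,U,N}: ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  too_short <- nchar(clean) < k
  if (any(too_short)) {
    stop("sequence shorter than k = ", k, ": ",
         paste(names(seqs)[too_short], collapse = ", "), call. = FALSE)
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(clean), width = k, step = 1L)
  total <- rowSums(counts)
  if (any(total == 0)) {
    # every window hit an N; no usable k-mer content
    stop("no countable k-mer window (all windows contain N) for: ",
         paste(names(seqs)[total == 0], collapse = ", "), call. = FALSE)
  }
  X <- counts / total
  rownames(X) <- names(seqs)
  X
}
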