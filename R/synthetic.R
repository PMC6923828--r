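#' Configuration for the synthetic bipartite network generator
#'
#' The generator plants the structure the prediction models assume:
#' entities fall into groups, sequences within a group are drawn from a
#' shared first-order nucleotide chain (so k-mer profiles carry the group
#' signal), and interactions are dense within matching groups and sparse
#' across groups.
#'
#' @param n_lnc,n_mir Numbers of lncRNAs and miRNAs.
#' @param n_groups Number of planted groups (at most 24, one distinct
#'   base-transition pattern per group).
#' @param p_in,p_out Interaction probabilities for same-group and
#'   cross-group pairs; `p_out < p_in` required.
#' @param seq_len_lnc,seq_len_mir Sequence lengths. Defaults emulate a
#'   short lncRNA (500 nt) and a mature miRNA (22 nt); the very short
#'   miRNA sequences are what make miRNA k-mer profiles noisy relative to
#'   interaction profiles, as in real interaction databases.
#' @param kmer_bias Transition sharpening `>= 1`: each group prefers one
#'   group-specific base-to-base transition by this factor, separating
#'   within-group from between-group 5-mer profiles in Euclidean distance.
#' @param cold_start_fraction Fraction of entities (per side) whose
#'   interactions are removed after sampling, producing cold-start cases.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_lnc = 120, n_mir = 60, n_groups = 4,
                              p_in = 0.5, p_out = 0.02,
                              seq_len_lnc = 500, seq_len_mir = 22,
                              kmer_bias = 20, cold_start_fraction = 0,
                              seed = 7) {
  if (p_out < 0 || p_in > 1 || p_out >= p_in) {
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  if (n_groups > min(n_lnc, n_mir)) {
    stop("`n_groups` cannot exceed the number of entities on either side",
         call. = FALSE)
  }
  if (n_groups > 24) stop("`n_groups` must be <= 24", call. = FALSE)
  if (kmer_bias < 1) stop("`kmer_bias` must be >= 1", call. = FALSE)
  if (cold_start_fraction < 0 || cold_start_fraction >= 1) {
    stop("`cold_start_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_lnc = n_lnc, n_mir = n_mir, n_groups = n_groups,
                 p_in = p_in, p_out = p_out,
                 seq_len_lnc = seq_len_lnc, seq_len_mir = seq_len_mir,
                 kmer_bias = kmer_bias,
                 cold_start_fraction = cold_start_fraction, seed = seed),
            class = "simulation_config")
}

markov_sequence <- function(len, trans) {
  bases <- c("A", "C", "G", "T")
  s <- integer(len)
  s[1] <- sample.int(4L, 1L)
  for (p in seq_len(len - 1L)) {
    s[p + 1L] <- sample.int(4L, 1L, prob = trans[s[p], ])
  }
  paste(bases[s], collapse = "")
}

#' Simulate a bipartite lncRNA-miRNA network with planted groups
#'
#' Assigns every entity to a group, samples its sequence from a
#' group-specific first-order Markov chain over `{A,C,G,T}` (each group
#' prefers a distinct base-permutation of transitions, sharpened by
#' `kmer_bias`; a first-order chain rather than i.i.d. letters is used so
#' that 5-mer profiles retain the group signal), and samples interactions
#' as `Bernoulli(p_in)` for same-group pairs and `Bernoulli(p_out)`
#' otherwise. A `cold_start_fraction` of entities on each side then has
#' all its interactions removed while keeping its sequence -- exactly the
#' situation the SC and PC combination strategies exist to handle.
#' Optionally writes FASTA and interaction TSV files.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Optional directory to write `lncRNA.fa`, `miRNA.fa` and
#'   `interactions.tsv` into.
#' @return List with `lnc_seqs`, `mir_seqs` (named character vectors),
#'   `Y` (binary matrix after cold-start removal), `Y_full` (before
#'   removal), group labels, the cold-start id vectors and `cfg`.
#' @export
simulate_network <- function(cfg = simulation_config(), out_dir = NULL) {
  res <- with_seed(cfg$seed, {
    g <- cfg$n_groups
    lnc_groups <- rep(seq_len(g), length.out = cfg$n_lnc)
    mir_groups <- rep(seq_len(g), length.out = cfg$n_mir)

    # one distinct preferred-transition permutation per group
    perms <- list()
    while (length(perms) < g) {
      p <- sample(4L)
      if (!any(vapply(perms, identical, logical(1), p))) {
        perms[[length(perms) + 1L]] <- p
      }
    }
    trans <- lapply(perms, function(p) {
      M <- matrix(1, 4, 4)
      M[cbind(seq_len(4L), p)] <- cfg$kmer_bias
      M / rowSums(M)
    })

    lnc_seqs <- vapply(lnc_groups, function(grp)
      markov_sequence(cfg$seq_len_lnc, trans[[grp]]), character(1))
    names(lnc_seqs) <- sprintf("lnc%03d", seq_len(cfg$n_lnc))
    mir_seqs <- vapply(mir_groups, function(grp)
      markov_sequence(cfg$seq_len_mir, trans[[grp]]), character(1))
    names(mir_seqs) <- sprintf("mir%03d", seq_len(cfg$n_mir))

    same <- outer(lnc_groups, mir_groups, "==")
    prob <- ifelse(same, cfg$p_in, cfg$p_out)
    Y_full <- matrix(stats::rbinom(length(prob), 1L, as.vector(prob)),
                     cfg$n_lnc, cfg$n_mir,
                     dimnames = list(names(lnc_seqs), names(mir_seqs)))
    Y <- Y_full
    cold_lnc <- character(0)
    cold_mir <- character(0)
    if (cfg$cold_start_fraction > 0) {
      n_cl <- floor(cfg$cold_start_fraction * cfg$n_lnc)
      n_cm <- floor(cfg$cold_start_fraction * cfg$n_mir)
      cold_lnc <- sort(sample(names(lnc_seqs), n_cl))
      cold_mir <- sort(sample(names(mir_seqs), n_cm))
      Y[cold_lnc, ] <- 0
      Y[, cold_mir] <- 0
    }
    list(lnc_seqs = lnc_seqs, mir_seqs = mir_seqs, Y = Y, Y_full = Y_full,
         lnc_groups = stats::setNames(lnc_groups, names(lnc_seqs)),
         mir_groups = stats::setNames(mir_groups, names(mir_seqs)),
         cold_lnc = cold_lnc, cold_mir = cold_mir, cfg = cfg)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$lnc_seqs, file.path(out_dir, "lncRNA.fa"))
    write_fasta(res$mir_seqs, file.path(out_dir, "miRNA.fa"))
    write_interactions(res$Y, file.path(out_dir, "interactions.tsv"))
  }
  res
}

#' Mask all interactions of selected entities (cold-start protocol)
#'
#' Selects a fraction of entities on each side among those with at least
#' one interaction and at least one non-interaction, zeroes their entire
#' row or column of `Y`, and returns the masked matrix together with the
#' removed positives. This is the per-entity evaluation protocol for
#' cold-start prediction: for every selected entity, its full profile
#' (removed positives vs never-observed pairs) is the evaluation vector.
#'
#' @param Y Binary interaction matrix.
#' @param fraction Fraction in `(0, 1)` of each side's entities to mask
#'   (at least one per side).
#' @param seed Integer seed.
#' @return List with `Y_train`, `held_out` (linear indices of removed
#'   positives), `cold_lnc` and `cold_mir` (row/column indices).
#' @export
holdout_cold_start <- function(Y, fraction, seed = 1) {
  stopifnot_matrix(Y)
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  l <- nrow(Y); m <- ncol(Y)
  elig_l <- which(rowSums(Y) > 0 & rowSums(Y) < m)
  elig_m <- which(colSums(Y) > 0 & colSums(Y) < l)
  if (!length(elig_l) || !length(elig_m)) {
    stop("no eligible entity (needs >= 1 positive and >= 1 negative) on ",
         "one side", call. = FALSE)
  }
  picks <- with_seed(seed, list(
    lnc = sort(sample(elig_l, max(1L, min(floor(fraction * l), length(elig_l))))),
    mir = sort(sample(elig_m, max(1L, min(floor(fraction * m), length(elig_m)))))))
  Y_train <- Y
  Y_train[picks$lnc, ] <- 0
  Y_train[, picks$mir] <- 0
  held_out <- which(Y == 1 & Y_train == 0)
  list(Y_train = Y_train, held_out = held_out,
       cold_lnc = picks$lnc, cold_mir = picks$mir)
}
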