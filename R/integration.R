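#' Similarity-based information combination (SC)
#'
#' Builds the integrated similarity used by SLNPM-SC: for an entity with at
#' least one known interaction the row of the interaction-profile
#' similarity is kept; for a cold-start entity (all-zero profile) the row
#' of the sequence-feature similarity is substituted instead. The switch is
#' a hard, row-level substitution -- nothing is blended -- so changing the
#' sequence similarity of an entity that has interactions can never change
#' the result. The resulting matrix is generally asymmetric; label
#' propagation treats it as a directed graph.
#'
#' @param S_IP Interaction-profile similarity (square, aligned with the
#'   chosen side of `Y`), e.g. from [interaction_profile_similarity()].
#' @param S_SF Sequence-feature similarity, same shape and order.
#' @param Y Binary interaction matrix used to decide which entities have
#'   interactions.
#' @param side `"lncRNA"` (rows of `Y`) or `"miRNA"` (columns of `Y`).
#' @return Integrated similarity matrix, same shape as `S_IP`.
#' @export
integrate_sc <- function(S_IP, S_SF, Y, side = c("lncRNA", "miRNA")) {
  side <- match.arg(side)
  stopifnot_matrix(S_IP); stopifnot_matrix(S_SF); stopifnot_matrix(Y)
  n <- if (side == "lncRNA") nrow(Y) else ncol(Y)
  if (!all(dim(S_IP) == c(n, n)) || !all(dim(S_SF) == c(n, n))) {
    stop("similarity matrices must be ", n, " x ", n, " for side ", side,
         call. = FALSE)
  }
  degree <- if (side == "lncRNA") rowSums(Y) else colSums(Y)
  S <- S_IP
  cold <- degree == 0
  S[cold, ] <- S_SF[cold, , drop = FALSE]
  S
}

#' Complement cold-start interaction profiles from sequence neighbors (PC)
#'
#' Implements the interaction-profile combination step of SLNPM-PC. The
#' profile of a lncRNA without any known interaction is replaced by the
#' similarity-weighted average of the profiles of its `k_nn` most
#' sequence-similar lncRNAs that each have at least one interaction
#' (normalized by the sum of the used similarities); all-zero miRNA columns
#' are complemented symmetrically from their sequence neighbors. Profiles
#' that are already nonzero are returned unchanged. Complemented entries
#' are convex combinations of binary profiles and therefore lie in
#' `[0, 1]`; running the complementation twice gives the same result as
#' running it once.
#'
#' Neighbor eligibility requires at least one known interaction in the
#' binary input matrix; similarity ties are broken by ascending index. If
#' all selected similarities are zero the unweighted mean of the neighbor
#' profiles is used, with a warning.
#'
#' @param Y Binary interaction matrix (lncRNAs x miRNAs).
#' @param S_LSF lncRNA sequence similarity (`l x l`).
#' @param S_MSF miRNA sequence similarity (`m x m`).
#' @param k_nn Number of sequence neighbors used for the complementation.
#' @return Real-valued matrix, same shape as `Y`: original rows/columns
#'   where interactions exist, complemented profiles elsewhere.
#' @export
complement_profiles_pc <- function(Y, S_LSF, S_MSF, k_nn = 10) {
  stopifnot_matrix(Y); stopifnot_matrix(S_LSF); stopifnot_matrix(S_MSF)
  if (k_nn < 1) stop("`k_nn` must be >= 1", call. = FALSE)
  l <- nrow(Y); m <- ncol(Y)
  if (!all(dim(S_LSF) == c(l, l)) || !all(dim(S_MSF) == c(m, m))) {
    stop("similarity matrices must match the dimensions of `Y`", call. = FALSE)
  }
  lnc_deg <- rowSums(Y != 0)
  mir_deg <- colSums(Y != 0)
  if (all(lnc_deg == 0) || all(mir_deg == 0)) {
    stop("at least one lncRNA and one miRNA must have a nonzero profile",
         call. = FALSE)
  }

  weighted_profile <- function(sims, profiles, who) {
    # sims: similarities to eligible neighbors; profiles: their profile rows
    ord <- order(-sims, seq_along(sims))
    top <- ord[seq_len(min(k_nn, length(sims)))]
    q <- sum(sims[top])
    if (q <= 0) {
      warning("all selected similarities are zero for ", who,
              "; using the unweighted neighbor mean", call. = FALSE)
      return(colMeans(profiles[top, , drop = FALSE]))
    }
    drop(sims[top] %*% profiles[top, , drop = FALSE]) / q
  }

  Yc <- Y
  eligible_l <- which(lnc_deg > 0)
  for (i in which(lnc_deg == 0)) {
    Yc[i, ] <- weighted_profile(S_LSF[i, eligible_l],
                                Y[eligible_l, , drop = FALSE],
                                paste0("lncRNA ", rownames(Y)[i]))
  }
  # columns use the row-complemented matrix: previously all-zero columns
  # are still zero across eligible rows, so the result is order-independent
  eligible_m <- which(mir_deg > 0)
  for (j in which(mir_deg == 0)) {
    Yc[, j] <- weighted_profile(S_MSF[j, eligible_m],
                                t(Yc[, eligible_m, drop = FALSE]),
                                paste0("miRNA ", colnames(Y)[j]))
  }
  Yc
}

#' Interaction similarities from a complemented profile matrix (PC)
#'
#' Learns the linear neighborhood similarity over the rows (lncRNA side)
#' and the columns (miRNA side) of a complemented interaction matrix, as
#' used by SLNPM-PC after [complement_profiles_pc()].
#'
#' @param Y_complemented Real-valued interaction matrix with no all-zero
#'   row or column.
#' @param cfg An [lns_config()].
#' @return List with elements `lnc` (`l x l`) and `mir` (`m x m`), both
#'   row-stochastic LNS similarity matrices.
#' @export
pc_similarities <- function(Y_complemented, cfg = lns_config()) {
  stopifnot_matrix(Y_complemented)
  if (any(rowSums(Y_complemented != 0) == 0) ||
      any(colSums(Y_complemented != 0) == 0)) {
    stop("complemented matrix still has an all-zero profile; ",
         "increase `k_nn` or check that interacting neighbors exist",
         call. = FALSE)
  }
  list(lnc = lns_similarity(Y_complemented, cfg),
       mir = lns_similarity(t(Y_complemented), cfg))
}
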