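#' Configuration for label propagation and score fusion
#'
#' @param alpha Absorbing probability in `[0, 1)`: the fraction of label
#'   mass that keeps diffusing along the similarity graph at every step;
#'   `1 - alpha` is re-injected from the initial labels.
#' @param beta Fusion weight in `[0, 1]` between the lncRNA-graph
#'   prediction (`beta = 1`) and the miRNA-graph prediction (`beta = 0`).
#' @param max_iter Maximum number of propagation iterations.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   label matrix between iterations.
#' @return A list of class `"prop_config"`.
#' @export
prop_config <- function(alpha = 0.4, beta = 0.25, max_iter = 1000, tol = 1e-8) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha >= 1) {
    stop("`alpha` must be in [0, 1)", call. = FALSE)
  }
  if (length(beta) != 1L || !is.finite(beta) || beta < 0 || beta > 1) {
    stop("`beta` must be in [0, 1]", call. = FALSE)
  }
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "prop_config")
}

check_propagation_operator <- function(S) {
  stopifnot_matrix(S)
  if (nrow(S) != ncol(S)) stop("`S` must be square", call. = FALSE)
  rs <- rowSums(S)
  # isolated nodes (all-zero similarity rows, e.g. cold-start entities in a
  # pure interaction-profile model) are permitted: they retain exactly
  # (1 - alpha) times their initial label
  ok <- abs(rs - 1) <= 1e-6 | abs(rs) <= 1e-6
  if (!all(ok)) {
    stop("`S` rows must sum to 1 (or 0 for isolated nodes) within 1e-6; ",
         "offending rows: ", paste(which(!ok)[seq_len(min(5, sum(!ok)))],
                                   collapse = ", "), call. = FALSE)
  }
  invisible(S)
}

#' Propagate labels over a similarity graph
#'
#' Iterates `F <- alpha * S %*% F + (1 - alpha) * Y0` from `F = Y0` until
#' the maximum absolute change falls below `tol` or `max_iter` is reached.
#' Because the spectral radius of `alpha * S` is at most `alpha < 1` for a
#' row-stochastic `S`, the iteration converges to the closed form
#' `(1 - alpha) * solve(I - alpha * S) %*% Y0` (see
#' [label_propagate_closed()], which is kept as an independent code path
#' for cross-checking).
#'
#' @param S Row-stochastic similarity matrix (rows summing to 1 within
#'   1e-6; all-zero rows are allowed and represent isolated nodes).
#' @param Y0 Initial label matrix (or vector), one row per node of `S`.
#' @param alpha Absorbing probability in `[0, 1)`.
#' @param tol,max_iter Convergence controls; see [prop_config()].
#' @return Matrix of propagated labels, same shape as `Y0`.
#' @examples
#' S <- matrix(c(0, 1, 1, 0), 2, 2)
#' label_propagate(S, c(1, 0), alpha = 0.5)  # (2/3, 1/3)
#' @export
label_propagate <- function(S, Y0, alpha = 0.4, tol = 1e-8, max_iter = 1000) {
  if (is.vector(Y0)) Y0 <- matrix(Y0, ncol = 1L)
  check_propagation_operator(S)
  if (nrow(Y0) != nrow(S)) {
    stop("`Y0` must have one row per node of `S`", call. = FALSE)
  }
  if (alpha < 0 || alpha >= 1) stop("`alpha` must be in [0, 1)", call. = FALSE)
  F_cur <- Y0
  for (it in seq_len(max_iter)) {
    F_new <- alpha * (S %*% F_cur) + (1 - alpha) * Y0
    delta <- max(abs(F_new - F_cur))
    F_cur <- F_new
    if (delta < tol) return(F_cur)
  }
  warning("label propagation did not converge in ", max_iter,
          " iterations (last change ", signif(delta, 3), ")", call. = FALSE)
  F_cur
}

#' @rdname label_propagate
#' @details `label_propagate_closed()` computes the fixed point directly by
#'   solving the linear system; intended for moderate graph sizes and as a
#'   cross-check of the iterative path.
#' @export
label_propagate_closed <- function(S, Y0, alpha = 0.4) {
  if (is.vector(Y0)) Y0 <- matrix(Y0, ncol = 1L)
  check_propagation_operator(S)
  (1 - alpha) * solve(diag(nrow(S)) - alpha * S, Y0)
}

#' Score all lncRNA-miRNA pairs by two-graph label propagation
#'
#' Propagates the interaction labels on the lncRNA similarity graph (each
#' miRNA's interaction column is the initial label vector of the lncRNA
#' nodes) and, symmetrically, on the miRNA similarity graph, then fuses the
#' two score matrices as `beta * P_l + (1 - beta) * P_m`.
#'
#' @param Y Interaction matrix used as initial labels (`l x m`; binary for
#'   SC, possibly real-valued after PC complementation).
#' @param S_L lncRNA similarity matrix (`l x l`, row-stochastic).
#' @param S_M miRNA similarity matrix (`m x m`, row-stochastic).
#' @param cfg A [prop_config()].
#' @return Prediction matrix `P` (`l x m`) with attributes `"P_l"` and
#'   `"P_m"` holding the two unfused propagation results.
#' @export
predict_interactions <- function(Y, S_L, S_M, cfg = prop_config()) {
  stopifnot_matrix(Y)
  if (nrow(S_L) != nrow(Y) || nrow(S_M) != ncol(Y)) {
    stop("`S_L`/`S_M` must be aligned with the rows/columns of `Y`",
         call. = FALSE)
  }
  P_l <- label_propagate(S_L, Y, cfg$alpha, cfg$tol, cfg$max_iter)
  P_m <- t(label_propagate(S_M, t(Y), cfg$alpha, cfg$tol, cfg$max_iter))
  P <- cfg$beta * P_l + (1 - cfg$beta) * P_m
  dimnames(P) <- dimnames(Y)
  attr(P, "P_l") <- P_l
  attr(P, "P_m") <- P_m
  P
}

#' SLNPM-SC: similarity-combination prediction pipeline
#'
#' Full pipeline of the similarity-based combination model: 5-mer-derived
#' sequence similarities and interaction-profile similarities are learned
#' by linear neighborhood similarity, combined row-wise with
#' [integrate_sc()] (cold-start entities fall back to their sequence
#' similarity row), and all pairs are scored by two-graph label
#' propagation. Default parameters are neighborhood ratio `K = 0.8`,
#' `alpha = 0.4`, `beta = 0.25`.
#'
#' @param Y Binary training interaction matrix (lncRNAs x miRNAs).
#' @param X_lnc lncRNA feature matrix (rows aligned with rows of `Y`),
#'   e.g. from [kmer_features()].
#' @param X_mir miRNA feature matrix (rows aligned with columns of `Y`).
#' @param lns_cfg An [lns_config()]; the default uses `K = 0.8`.
#' @param prop_cfg A [prop_config()].
#' @param S_LSF,S_MSF Optional precomputed sequence similarity matrices
#'   (they do not depend on `Y`, so repeated-evaluation callers can reuse
#'   them across folds).
#' @return Prediction matrix as from [predict_interactions()].
#' @export
slnpm_sc <- function(Y, X_lnc, X_mir,
                     lns_cfg = lns_config(neighbor_ratio = 0.8),
                     prop_cfg = prop_config(),
                     S_LSF = NULL, S_MSF = NULL) {
  stopifnot_matrix(Y)
  if (is.null(S_LSF)) S_LSF <- lns_similarity(X_lnc, lns_cfg)
  if (is.null(S_MSF)) S_MSF <- lns_similarity(X_mir, lns_cfg)
  S_LIP <- interaction_profile_similarity(Y, "lncRNA", lns_cfg)
  S_MIP <- interaction_profile_similarity(Y, "miRNA", lns_cfg)
  S_LIS <- integrate_sc(S_LIP, S_LSF, Y, "lncRNA")
  S_MIS <- integrate_sc(S_MIP, S_MSF, Y, "miRNA")
  predict_interactions(Y, S_LIS, S_MIS, prop_cfg)
}

#' SLNPM-PC: profile-complementation prediction pipeline
#'
#' Full pipeline of the interaction-profile combination model: cold-start
#' profiles are complemented from sequence neighbors
#' ([complement_profiles_pc()]), interaction similarities are learned on
#' the complemented matrix ([pc_similarities()]), and the complemented
#' matrix is propagated on both graphs. Default parameters are
#' neighborhood ratio `K = 0.9`, `alpha = 0.4`, `beta = 0.25`.
#'
#' @inheritParams slnpm_sc
#' @param k_nn Number of sequence neighbors for the complementation.
#' @param lns_cfg An [lns_config()]; the default uses `K = 0.9`.
#' @return Prediction matrix as from [predict_interactions()].
#' @export
slnpm_pc <- function(Y, X_lnc, X_mir,
                     lns_cfg = lns_config(neighbor_ratio = 0.9),
                     prop_cfg = prop_config(), k_nn = 10,
                     S_LSF = NULL, S_MSF = NULL) {
  stopifnot_matrix(Y)
  if (is.null(S_LSF)) S_LSF <- lns_similarity(X_lnc, lns_cfg)
  if (is.null(S_MSF)) S_MSF <- lns_similarity(X_mir, lns_cfg)
  Yc <- complement_profiles_pc(Y, S_LSF, S_MSF, k_nn)
  sims <- pc_similarities(Yc, lns_cfg)
  predict_interactions(Yc, sims$lnc, sims$mir, prop_cfg)
}
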