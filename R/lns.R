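#' Configuration for linear neighborhood similarity learning
#'
#' @param neighbor_ratio Neighborhood ratio `K` in `(0, 1]`: the fraction of
#'   the other `n - 1` data points selected as nearest neighbors for each
#'   entity. The number of neighbors is `max(1, floor(K * (n - 1)))` (an
#'   entity is not its own neighbor).
#' @param mu Tradeoff parameter `mu >= 0` of the reconstruction objective.
#'   Because the learned rows are constrained to the probability simplex,
#'   where the `mu` term of the objective is constant, `mu` does not change
#'   the learned weights; it is kept so the objective can be evaluated as
#'   written and for interface compatibility with penalty-type solvers.
#' @param max_iter Maximum number of solver iterations.
#' @param tol Convergence tolerance on the relative Frobenius-norm change
#'   of the weight matrix between iterations.
#' @return A list of class `"lns_config"`.
#' @export
lns_config <- function(neighbor_ratio = 0.8, mu = 1, max_iter = 100, tol = 1e-6) {
  if (length(neighbor_ratio) != 1L || !is.finite(neighbor_ratio) ||
      neighbor_ratio <= 0 || neighbor_ratio > 1) {
    stop("`neighbor_ratio` must be in (0, 1]", call. = FALSE)
  }
  if (length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop("`mu` must be a nonnegative number", call. = FALSE)
  }
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  structure(list(neighbor_ratio = neighbor_ratio, mu = mu,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "lns_config")
}

#' Select nearest neighbors for every data point
#'
#' Row `i` of the returned indicator matrix marks the
#' `max(1, floor(K * (n - 1)))` points with smallest Euclidean distance to
#' point `i`; the point itself is excluded. Distance ties are broken by
#' ascending index, so the selection is deterministic.
#'
#' @param X Numeric feature matrix, one row per entity (`n >= 2`).
#' @param neighbor_ratio Neighborhood ratio `K` in `(0, 1]`.
#' @return Binary `n x n` indicator matrix `C` with zero diagonal.
#' @export
select_neighbors <- function(X, neighbor_ratio = 0.8) {
  stopifnot_matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 data points to select neighbors", call. = FALSE)
  if (neighbor_ratio <= 0 || neighbor_ratio > 1) {
    stop("`neighbor_ratio` must be in (0, 1]", call. = FALSE)
  }
  k <- max(1L, as.integer(floor(neighbor_ratio * (n - 1))))
  D <- as.matrix(stats::dist(X))
  C <- matrix(0L, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    ord <- order(D[i, others], others)  # ties -> ascending index
    C[i, others[ord[seq_len(k)]]] <- 1L
  }
  C
}

#' Linear neighborhood reconstruction objective
#'
#' Evaluates `0.5 * ||X - (C * W) X||_F^2 +
#' (mu / 2) * sum_i ((C * W) e)_i^2`, the reconstruction error of all data
#' points from their neighbors plus the tradeoff term on row sums.
#'
#' @param X Feature matrix (`n x d`).
#' @param W Weight matrix (`n x n`).
#' @param C Binary neighbor indicator (`n x n`), e.g. from
#'   [select_neighbors()].
#' @param mu Tradeoff parameter.
#' @return A single nonnegative number.
#' @export
lns_objective <- function(X, W, C, mu = 1) {
  stopifnot_matrix(X); stopifnot_matrix(W)
  n <- nrow(X)
  if (!all(dim(W) == c(n, n)) || !all(dim(C) == c(n, n))) {
    stop("`W` and `C` must be n x n with n = nrow(X)", call. = FALSE)
  }
  M <- C * W
  R <- X - M %*% X
  0.5 * sum(R * R) + (mu / 2) * sum(rowSums(M)^2)
}

#' Learn a linear neighborhood similarity matrix
#'
#' Each entity is reconstructed as a weighted combination of its nearest
#' neighbors; the weights minimize the squared reconstruction error subject
#' to being nonnegative and summing to one, so every learned row lies on
#' the probability simplex over the selected neighborhood. The row
#' subproblems are convex quadratic programs; they are solved jointly by
#' accelerated projected gradient descent (FISTA) with a descent safeguard,
#' so the objective is non-increasing over iterations and the returned rows
#' match an exact quadratic-programming solve of each subproblem.
#'
#' Weights are initialized uniformly over each neighborhood and iterated
#' until the relative Frobenius-norm change drops below `cfg$tol` or
#' `cfg$max_iter` is reached. Rows are exactly on the simplex at every
#' iterate (the projection enforces the constraint), hence the returned
#' matrix is row-stochastic and supported on the neighbor indicator.
#'
#' @param X Numeric feature matrix, one row per entity (`n >= 2`), all
#'   entries finite.
#' @param cfg An [lns_config()].
#' @param trace Record the objective value at every iterate in the
#'   `"objective_trace"` attribute of the result.
#' @return `n x n` similarity matrix `W` (row-stochastic, zero diagonal,
#'   support inside the neighbor indicator), with attributes `"iterations"`
#'   and, if `trace`, `"objective_trace"`.
#' @examples
#' X <- matrix(c(0, 0, 0.1, 0, 1, 1), ncol = 2, byrow = TRUE)
#' lns_similarity(X, lns_config(neighbor_ratio = 0.5))
#' @export
lns_similarity <- function(X, cfg = lns_config(), trace = FALSE) {
  stopifnot_matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 data points", call. = FALSE)
  C <- select_neighbors(X, cfg$neighbor_ratio)
  k <- max(1L, as.integer(floor(cfg$neighbor_ratio * (n - 1))))
  nb <- lapply(seq_len(n), function(i) which(C[i, ] == 1L))

  G <- tcrossprod(X)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
  step <- 1 / max(L, .Machine$double.eps)

  project_rows <- function(M) {
    for (i in seq_len(n)) {
      w <- project_simplex(M[i, nb[[i]]])
      M[i, ] <- 0
      M[i, nb[[i]]] <- w
    }
    M
  }
  # reconstruction part of the objective; the mu term is constant on the
  # simplex and is added only for reporting
  recon <- function(W) { R <- X - W %*% X; 0.5 * sum(R * R) }

  W <- C / k
  Z <- W
  t_k <- 1
  f <- recon(W)
  obj_trace <- if (trace) lns_objective(X, W, C, cfg$mu) else NULL
  iters <- 0L
  for (it in seq_len(cfg$max_iter)) {
    cand <- project_rows(Z - step * (Z %*% G - G))
    f_cand <- recon(cand)
    if (f_cand > f) {
      # momentum overshot: fall back to a plain (guaranteed-descent)
      # projected gradient step from the current iterate
      cand <- project_rows(W - step * (W %*% G - G))
      f_cand <- recon(cand)
      t_k <- 1
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    Z <- cand + ((t_k - 1) / t_next) * (cand - W)
    delta <- norm(cand - W, "F") / max(norm(W, "F"), .Machine$double.eps)
    W <- cand
    f <- f_cand
    t_k <- t_next
    iters <- it
    if (trace) obj_trace <- c(obj_trace, lns_objective(X, W, C, cfg$mu))
    if (delta < cfg$tol) break
  }
  dimnames(W) <- list(rownames(X), rownames(X))
  attr(W, "iterations") <- iters
  if (trace) attr(W, "objective_trace") <- obj_trace
  W
}

#' Interaction profile similarity via linear neighborhood learning
#'
#' Treats each entity's interaction profile (its row of `Y` for lncRNAs,
#' its column for miRNAs) as a feature vector and learns the linear
#' neighborhood similarity among the entities that have at least one known
#' interaction. Entities with an all-zero profile carry no interaction
#' information: they are excluded from the solve, and both their row and
#' their column of the returned matrix are all zeros.
#'
#' @param Y Binary interaction matrix (lncRNAs x miRNAs).
#' @param side `"lncRNA"` (rows of `Y`) or `"miRNA"` (columns of `Y`).
#' @param cfg An [lns_config()].
#' @return Square similarity matrix over all entities of the chosen side;
#'   rows of entities with interactions are on the probability simplex over
#'   their (interacting) neighbors, cold-start rows/columns are zero.
#' @export
interaction_profile_similarity <- function(Y, side = c("lncRNA", "miRNA"),
                                           cfg = lns_config()) {
  side <- match.arg(side)
  stopifnot_matrix(Y)
  if (!all(Y %in% c(0, 1))) stop("`Y` must be binary", call. = FALSE)
  X <- if (side == "lncRNA") Y else t(Y)
  n <- nrow(X)
  active <- rowSums(X) > 0
  if (sum(active) < 2L) {
    stop("fewer than 2 ", side, "s have a nonzero interaction profile",
         call. = FALSE)
  }
  W_sub <- lns_similarity(X[active, , drop = FALSE], cfg)
  S <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  S[active, active] <- W_sub
  S
}
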