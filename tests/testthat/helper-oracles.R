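# Independent oracles and small fixture builders shared across tests.

# AUC by brute-force enumeration of all positive-negative pairs,
# ties counting one half.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exact solve of one row's neighborhood-reconstruction problem:
# min 0.5 * w' G w  (G the Gram matrix of neighbor differences, plus the
# mu term, constant on the constraint set) s.t. sum(w) = 1, w >= 0,
# via a general-purpose quadratic-programming routine.
qp_row_oracle <- function(X, C, mu, i) {
  nb <- which(C[i, ] == 1)
  A <- X[nb, , drop = FALSE]
  Dm <- sweep(A, 2, X[i, ])
  H <- tcrossprod(Dm) + mu + 1e-10 * diag(length(nb))
  sol <- pracma::quadprog(H, rep(0, length(nb)),
                          Aeq = matrix(1, 1, length(nb)), beq = 1,
                          lb = rep(0, length(nb)))
  w <- numeric(nrow(X))
  w[nb] <- sol$xmin
  w
}

# Random feature matrix with rows on the probability simplex (the domain
# of k-mer frequency features).
random_simplex_features <- function(n, d) {
  X <- matrix(runif(n * d), n, d)
  X / rowSums(X)
}

# Random row-stochastic matrix.
random_row_stochastic <- function(n) {
  S <- matrix(runif(n * n), n, n)
  S / rowSums(S)
}

# Random doubly-stochastic matrix as a convex combination of permutation
# matrices (Birkhoff construction).
random_doubly_stochastic <- function(n, n_perms = 5) {
  w <- runif(n_perms); w <- w / sum(w)
  S <- matrix(0, n, n)
  for (k in seq_len(n_perms)) {
    P <- diag(n)[sample(n), , drop = FALSE]
    S <- S + w[k] * P
  }
  S
}

# Small simulated network plus k-mer features, used by integration-level
# tests that do not need the full-size fixture.
tiny_network <- function(n_lnc = 24, n_mir = 12, seed = 11, ...) {
  sim <- simulate_network(simulation_config(
    n_lnc = n_lnc, n_mir = n_mir, n_groups = 3, seed = seed, ...))
  sim$X_lnc <- kmer_features(sim$lnc_seqs)
  sim$X_mir <- kmer_features(sim$mir_seqs)
  sim
}
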