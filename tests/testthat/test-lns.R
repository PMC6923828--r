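test_that("neighbor selection follows Euclidean distance with index tie-breaks", {
  # 1-D points 0, 1, 10 with one neighbor each
  X <- matrix(c(0, 1, 10), ncol = 1)
  C <- select_neighbors(X, neighbor_ratio = 0.5)  # floor(0.5 * 2) = 1
  expect_equal(unname(C), rbind(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0)))

  # K = 1 selects everyone but self
  C_all <- select_neighbors(X, neighbor_ratio = 1)
  expect_equal(unname(rowSums(C_all)), rep(2, 3))
  expect_equal(unname(diag(C_all)), rep(0L, 3))

  # identical points: ties resolved toward the lowest other index
  X_dup <- matrix(1, 3, 2)
  C_dup <- select_neighbors(X_dup, neighbor_ratio = 0.5)
  expect_equal(unname(C_dup), rbind(c(0, 1, 0), c(1, 0, 0), c(1, 0, 0)))

  expect_error(select_neighbors(matrix(1, 1, 2)), "at least 2")
})

test_that("reconstruction objective matches an element-wise recomputation", {
  # zero weights leave the full signal unexplained
  set.seed(21)
  X <- matrix(rnorm(6), 3, 2)
  C <- select_neighbors(X, 1)
  expect_equal(lns_objective(X, matrix(0, 3, 3), C, mu = 1), 0.5 * sum(X^2))

  # identical twins reconstruct each other perfectly
  X_twin <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE)
  W_twin <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(lns_objective(X_twin, W_twin, select_neighbors(X_twin, 1), mu = 0), 0)

  # random case vs an independent double-loop expansion of both norms
  W <- matrix(runif(9), 3, 3)
  mu <- 0.7
  M <- C * W
  recon <- 0
  for (i in 1:3) for (j in 1:2) {
    pred <- 0
    for (k in 1:3) pred <- pred + M[i, k] * X[k, j]
    recon <- recon + (X[i, j] - pred)^2
  }
  sums <- 0
  for (i in 1:3) sums <- sums + sum(M[i, ])^2
  expect_equal(lns_objective(X, W, C, mu), 0.5 * recon + mu / 2 * sums,
               tolerance = 1e-12)

  expect_error(lns_objective(X, matrix(0, 2, 2), C, 1), "n x n")
})

test_that("identical twins receive full mutual weight", {
  X <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2, byrow = TRUE)
  W <- lns_similarity(X, lns_config(neighbor_ratio = 1))
  expect_equal(unname(W), matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
})

test_that("learned rows are simplex-constrained and supported on neighbors", {
  set.seed(22)
  for (rep in 1:5) {
    X <- random_simplex_features(7, 4)
    cfg <- lns_config(neighbor_ratio = 0.6, max_iter = 500)
    W <- lns_similarity(X, cfg)
    C <- select_neighbors(X, 0.6)
    expect_true(all(W >= 0))
    expect_true(all(W[C == 0] == 0))
    expect_equal(unname(rowSums(W)), rep(1, 7), tolerance = 1e-9)
  }
})

test_that("solver descends the objective and agrees with an exact QP solve", {
  set.seed(23)
  X <- random_simplex_features(8, 5)
  cfg <- lns_config(neighbor_ratio = 0.5, mu = 1, max_iter = 3000, tol = 1e-12)
  W <- lns_similarity(X, cfg, trace = TRUE)
  tr <- attr(W, "objective_trace")
  expect_true(all(diff(tr) <= 1e-8))
  C <- select_neighbors(X, 0.5)
  for (i in 1:8) {
    expect_equal(W[i, ], qp_row_oracle(X, C, 1, i), tolerance = 1e-4)
  }
})

test_that("similarity learning is scale-invariant", {
  set.seed(24)
  X <- random_simplex_features(6, 3)
  cfg <- lns_config(neighbor_ratio = 0.5, mu = 0, max_iter = 5000, tol = 1e-13)
  W1 <- lns_similarity(X, cfg)
  W2 <- lns_similarity(5 * X, cfg)
  expect_equal(unname(W1), unname(W2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("profile similarity zeroes cold-start rows and columns", {
  set.seed(25)
  Y <- matrix(rbinom(40, 1, 0.5), 8, 5)
  Y[rowSums(Y) == 0, 1] <- 1  # exactly one cold row below
  Y[3, ] <- 0
  S <- interaction_profile_similarity(Y, "lncRNA", lns_config(neighbor_ratio = 0.5))
  expect_equal(S[3, ], rep(0, 8))
  expect_equal(S[, 3], rep(0, 8))
  expect_equal(unname(rowSums(S)[-3]), rep(1, 7), tolerance = 1e-9)

  # all profiles nonzero: identical to plain LNS on the rows
  Y_full <- matrix(rbinom(40, 1, 0.6), 8, 5)
  Y_full[rowSums(Y_full) == 0, 1] <- 1
  cfg <- lns_config(neighbor_ratio = 0.5)
  expect_equal(unname(interaction_profile_similarity(Y_full, "lncRNA", cfg)),
               unname(lns_similarity(Y_full, cfg)), ignore_attr = TRUE)

  # miRNA side works on columns
  S_m <- interaction_profile_similarity(Y_full, "miRNA", cfg)
  expect_equal(dim(S_m), c(5, 5))

  # identical profiles among four entities: mutual weight 1 at one neighbor
  Y_tw <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0), c(1, 1, 1))
  S_tw <- interaction_profile_similarity(Y_tw, "lncRNA",
                                         lns_config(neighbor_ratio = 1 / 3))
  expect_equal(S_tw[1, 2], 1)
  expect_equal(S_tw[2, 1], 1)

  expect_error(interaction_profile_similarity(matrix(0, 3, 3), "lncRNA"),
               "fewer than 2")
})
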