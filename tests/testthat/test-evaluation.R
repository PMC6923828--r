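test_that("fold partition is exact, balanced, and seed-deterministic", {
  Y <- matrix(0, 4, 5); Y[1:10] <- 1
  folds <- split_folds(Y, 5, seed = 1)
  expect_equal(lengths(folds), c(`1` = 2L, `2` = 2L, `3` = 2L, `4` = 2L, `5` = 2L))

  Y11 <- matrix(0, 4, 5); Y11[1:11] <- 1
  folds11 <- split_folds(Y11, 5, seed = 1)
  expect_equal(sort(unname(lengths(folds11))), c(2L, 2L, 2L, 2L, 3L))

  # exact partition of the positives
  expect_setequal(unlist(folds11), which(Y11 == 1))
  expect_equal(sum(lengths(folds11)), 11L)

  expect_identical(split_folds(Y, 5, seed = 7), split_folds(Y, 5, seed = 7))
  expect_error(split_folds(matrix(c(1, 0, 0, 0), 2, 2), 5), "fewer positives")
})

test_that("AUC and AUPR match hand-checked rankings", {
  m <- compute_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$aupr, 1)

  # one concordant, one discordant pair
  expect_equal(compute_metrics(c(0.9, 0.5, 0.1), c(0, 1, 0))$auc, 0.5)

  # complete ties
  expect_equal(compute_metrics(rep(0.3, 6), c(1, 0, 1, 0, 0, 1))$auc, 0.5)

  expect_error(compute_metrics(c(1, 2), c(1, 1)), "both classes")
})

test_that("rank AUC equals brute-force pair enumeration and external check", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    scores <- sample(seq(0, 1, length.out = 21), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(compute_metrics(scores, labels)$auc, bf_auc(scores, labels))
  }
  # independent library cross-check on one non-degenerate instance
  scores <- runif(80); labels <- rbinom(80, 1, 0.3)
  expect_equal(compute_metrics(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c(0, 1),
                                              direction = "<", quiet = TRUE))))
})

test_that("ranking metrics are invariant to monotone score transforms", {
  set.seed(52)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.4)
  m1 <- compute_metrics(scores, labels)
  m2 <- compute_metrics(exp(scores / 3), labels)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-12)
})

test_that("thresholded metrics follow the top-r rule and the F1 identity", {
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  labels <- c(1, 0, 1, 0, 0)
  m <- compute_metrics(scores, labels)  # r = 2 -> top-2 called positive
  expect_equal(m$rec, 1 / 2)
  expect_equal(m$pr, 1 / 2)
  expect_equal(m$sp, 2 / 3)
  expect_equal(m$acc, 3 / 5)
  expect_equal(m$f1, 2 * m$pr * m$rec / (m$pr + m$rec))

  # numeric threshold variant
  m_num <- compute_metrics(scores, labels, threshold = 0.75)
  expect_equal(m_num$rec, 1 / 2)
  expect_equal(m_num$pr, 1 / 2)
})

test_that("top-k recall counts held-out positives in a hand-ranked matrix", {
  P <- matrix(c(0.9, 0.1, 0.8, 0.3,
                0.7, 0.2, 0.6, 0.4,
                0.5, 0.05, 0.45, 0.35,
                0.44, 0.04, 0.43, 0.33), 4, 4, byrow = TRUE)
  dimnames(P) <- list(paste0("l", 1:4), paste0("m", 1:4))
  train_pos <- which(P > 0.85)            # cell with 0.9
  held_out <- c(which(P == 0.8), which(P == 0.45), which(P == 0.04))
  counts <- topk_recall(P, held_out, train_pos, ks = c(1, 3, 8, 15))
  # candidate ranking: .8 .7 .6 .5 .45 .44 .43 .4 .35 .33 .3 .2 .1 .05 .04
  expect_equal(unname(counts), c(1L, 1L, 2L, 3L))
  expect_true(all(diff(counts) >= 0))

  # all held-out ranked first
  P2 <- matrix(seq(16, 1), 4, 4)
  ho <- which(P2 >= 15)
  expect_equal(unname(topk_recall(P2, ho, integer(0), ks = c(1, 2, 5))),
               c(1L, 2L, 2L))

  expect_error(topk_recall(P, held_out, train_pos, ks = c(1, 99)), "exceeds")
  expect_error(topk_recall(P, held_out, train_pos, ks = c(3, 2)), "ascending")
})

test_that("cross-validation summary is the mean of per-fold metrics and never leaks", {
  sim <- tiny_network()
  cv <- cross_validate(sim$Y, sim$X_lnc, sim$X_mir, method = "sc",
                       n_runs = 1, n_folds = 3, seed = 5)
  expect_equal(nrow(cv$folds), 3)
  expect_equal(unname(cv$summary["auc"]), mean(cv$folds$auc))
  expect_equal(unname(cv$summary["aupr"]), mean(cv$folds$aupr))
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))

  # leakage guard at the fold level: masking really removes the positives
  folds <- split_folds(sim$Y, 3, seed = 5)
  Y_train <- sim$Y; Y_train[folds[[1]]] <- 0
  expect_equal(sum(Y_train[folds[[1]]]), 0)
  expect_equal(sum(sim$Y) - sum(Y_train), length(folds[[1]]))
})

test_that("singleton grids reproduce a direct cross-validation call", {
  sim <- tiny_network()
  cfg <- lns_config(neighbor_ratio = 0.6)
  tab <- grid_search(sim$Y, sim$X_lnc, sim$X_mir, method = "sc",
                     k_grid = 0.6, alpha_grid = 0.4, beta_grid = 0.25,
                     n_runs = 1, n_folds = 3, seed = 5)
  expect_equal(nrow(tab), 1)
  cv <- cross_validate(sim$Y, sim$X_lnc, sim$X_mir, method = "sc",
                       lns_cfg = cfg,
                       prop_cfg = prop_config(alpha = 0.4, beta = 0.25),
                       n_runs = 1, n_folds = 3, seed = 5)
  expect_equal(tab$aupr, unname(cv$summary["aupr"]), tolerance = 1e-10)
  expect_equal(tab$auc, unname(cv$summary["auc"]), tolerance = 1e-10)

  # the beta endpoints of a grid equal the single-graph models
  tab_b <- grid_search(sim$Y, sim$X_lnc, sim$X_mir, method = "sc",
                       k_grid = 0.6, alpha_grid = 0.4, beta_grid = c(0, 1),
                       n_runs = 1, n_folds = 3, seed = 5)
  cv_l <- cross_validate(sim$Y, sim$X_lnc, sim$X_mir, method = "sc",
                         lns_cfg = cfg,
                         prop_cfg = prop_config(alpha = 0.4, beta = 1),
                         n_runs = 1, n_folds = 3, seed = 5)
  cv_m <- cross_validate(sim$Y, sim$X_lnc, sim$X_mir, method = "sc",
                         lns_cfg = cfg,
                         prop_cfg = prop_config(alpha = 0.4, beta = 0),
                         n_runs = 1, n_folds = 3, seed = 5)
  expect_equal(tab_b$aupr[tab_b$beta == 1], unname(cv_l$summary["aupr"]),
               tolerance = 1e-10)
  expect_equal(tab_b$aupr[tab_b$beta == 0], unname(cv_m$summary["aupr"]),
               tolerance = 1e-10)

  # argmax row dominates every other row
  expect_true(all(tab_b$aupr[attr(tab_b, "best")] >= tab_b$aupr))
})
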