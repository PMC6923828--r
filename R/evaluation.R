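#' Partition known interactions into cross-validation folds
#'
#' Randomly splits the positive cells of `Y` into `n_folds` disjoint sets
#' of near-equal size (sizes differ by at most one). Deterministic for a
#' given seed; the caller's RNG state is left untouched.
#'
#' @param Y Binary interaction matrix.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of integer vectors of linear indices into `Y`.
#' @export
split_folds <- function(Y, n_folds = 5, seed = 1) {
  stopifnot_matrix(Y)
  if (n_folds < 2) stop("`n_folds` must be >= 2", call. = FALSE)
  pos <- which(Y == 1)
  if (length(pos) < n_folds) {
    stop("fewer positives (", length(pos), ") than folds (", n_folds, ")",
         call. = FALSE)
  }
  perm <- with_seed(seed, sample(pos))
  sizes <- rep(length(pos) %/% n_folds, n_folds)
  extra <- length(pos) %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(n_folds), times = sizes))
}

# AUC as the probability that a random positive outscores a random
# negative, ties counting one half (rank / Mann-Whitney formulation).
rank_auc <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  r <- rank(scores)  # average ranks handle ties
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

# Non-interpolated average precision; deterministic tie-break by index.
average_precision <- function(scores, labels) {
  o <- order(-scores, seq_along(scores))
  lab <- labels[o]
  hits <- cumsum(lab)
  prec_at_pos <- hits[lab == 1] / which(lab == 1)
  mean(prec_at_pos)
}

#' Threshold-free and thresholded ranking metrics
#'
#' Computes AUC (probability that a random positive outscores a random
#' negative, ties counting one half), AUPR (non-interpolated average
#' precision), and the thresholded metrics REC, SP, PR, ACC and F1. By
#' default the threshold is the rank cutoff at `r` = number of positives
#' in the evaluated set (the top-`r` ranked pairs are called positive),
#' which is parameter-free and invariant to monotone rescaling of the
#' scores; passing a number instead calls pairs with `score >= threshold`
#' positive.
#'
#' @param scores Numeric score vector.
#' @param labels Binary label vector, same length; both classes must be
#'   present.
#' @param threshold `"rank"` (default) or a numeric cutoff.
#' @return A list of class `"slnpm_metrics"` with elements `aupr`, `auc`,
#'   `rec`, `sp`, `pr`, `acc`, `f1`.
#' @export
compute_metrics <- function(scores, labels, threshold = "rank") {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("`labels` must be binary", call. = FALSE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop("both classes must be present to compute metrics", call. = FALSE)
  }
  pred <- if (identical(threshold, "rank")) {
    o <- order(-scores, seq_along(scores))
    p <- integer(length(scores)); p[o[seq_len(np)]] <- 1L
    p
  } else {
    as.integer(scores >= threshold)
  }
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  rec <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  acc <- (tp + tn) / length(labels)
  f1 <- if (pr + rec > 0) 2 * pr * rec / (pr + rec) else 0
  structure(list(aupr = average_precision(scores, labels),
                 auc = rank_auc(scores, labels),
                 rec = rec, sp = sp, pr = pr, acc = acc, f1 = f1),
            class = "slnpm_metrics")
}

#' @export
print.slnpm_metrics <- function(x, ...) {
  cat(sprintf("AUPR %.4f  AUC %.4f  REC %.4f  SP %.4f  PR %.4f  ACC %.4f  F1 %.4f\n",
              x$aupr, x$auc, x$rec, x$sp, x$pr, x$acc, x$f1))
  invisible(x)
}

# Build a prediction matrix for one training split under a given model.
# Sequence similarities are Y-independent and passed in precomputed.
pipeline_predict <- function(Y_train, method, S_LSF, S_MSF,
                             lns_cfg, prop_cfg, k_nn) {
  switch(method,
    sc = slnpm_sc(Y_train, NULL, NULL, lns_cfg, prop_cfg,
                  S_LSF = S_LSF, S_MSF = S_MSF),
    pc = slnpm_pc(Y_train, NULL, NULL, lns_cfg, prop_cfg, k_nn,
                  S_LSF = S_LSF, S_MSF = S_MSF),
    ip = predict_interactions(
      Y_train,
      interaction_profile_similarity(Y_train, "lncRNA", lns_cfg),
      interaction_profile_similarity(Y_train, "miRNA", lns_cfg),
      prop_cfg),
    seq = predict_interactions(Y_train, S_LSF, S_MSF, prop_cfg),
    stop("unknown method: ", method, call. = FALSE))
}

default_lns_cfg <- function(method) {
  lns_config(neighbor_ratio = if (identical(method, "pc")) 0.9 else 0.8)
}

#' Repeated cross-validated evaluation of an interaction-prediction model
#'
#' Runs `n_runs` repetitions of `n_folds`-fold cross-validation over the
#' known interactions. In every fold the held-out positives are masked to
#' 0 in the training matrix, the entire pipeline (profile similarities,
#' cold-start combination) is rebuilt on the training matrix only, all
#' pairs are scored, and metrics are computed over all pairs except the
#' training positives, with the held-out positives labeled 1 and
#' never-observed pairs labeled 0 (the full complement; no negative
#' sampling). Reported summary values are arithmetic means over the
#' `n_runs * n_folds` per-fold metric sets. Run `r` uses seed
#' `seed + r - 1`, so runs are independent but the whole evaluation is
#' reproducible.
#'
#' Besides the two full models (`"sc"`, `"pc"`), two ablations are
#' available: `"ip"` uses only interaction-profile similarities (cold-start
#' entities keep all-zero similarity rows) and `"seq"` uses only sequence
#' similarities.
#'
#' @param Y Binary interaction matrix.
#' @param X_lnc,X_mir Feature matrices for the two sides (ignored by
#'   `method = "ip"`).
#' @param method One of `"sc"`, `"pc"`, `"ip"`, `"seq"`.
#' @param lns_cfg An [lns_config()]; defaults to `K = 0.8` (`K = 0.9` for
#'   PC).
#' @param prop_cfg A [prop_config()].
#' @param k_nn PC complementation neighbor count.
#' @param n_runs,n_folds Protocol size (defaults 20 x 5).
#' @param seed Base seed.
#' @return List of class `"slnpm_cv"`: `folds` (one data-frame row per
#'   run/fold with all metrics) and `summary` (named means).
#' @export
cross_validate <- function(Y, X_lnc = NULL, X_mir = NULL,
                           method = c("sc", "pc", "ip", "seq"),
                           lns_cfg = NULL, prop_cfg = prop_config(),
                           k_nn = 10, n_runs = 20, n_folds = 5, seed = 1) {
  method <- match.arg(method)
  stopifnot_matrix(Y)
  if (is.null(lns_cfg)) lns_cfg <- default_lns_cfg(method)
  needs_seq <- method %in% c("sc", "pc", "seq")
  S_LSF <- if (needs_seq) lns_similarity(X_lnc, lns_cfg) else NULL
  S_MSF <- if (needs_seq) lns_similarity(X_mir, lns_cfg) else NULL

  rows <- vector("list", n_runs * n_folds)
  idx <- 0L
  for (r in seq_len(n_runs)) {
    folds <- split_folds(Y, n_folds, seed + r - 1)
    for (f in seq_len(n_folds)) {
      Y_train <- Y
      Y_train[folds[[f]]] <- 0
      P <- pipeline_predict(Y_train, method, S_LSF, S_MSF,
                            lns_cfg, prop_cfg, k_nn)
      eval_mask <- Y_train != 1
      met <- compute_metrics(P[eval_mask], Y[eval_mask])
      idx <- idx + 1L
      rows[[idx]] <- data.frame(run = r, fold = f,
                                aupr = met$aupr, auc = met$auc,
                                rec = met$rec, sp = met$sp, pr = met$pr,
                                acc = met$acc, f1 = met$f1)
    }
  }
  folds_df <- do.call(rbind, rows)
  metric_cols <- c("aupr", "auc", "rec", "sp", "pr", "acc", "f1")
  structure(list(folds = folds_df,
                 summary = colMeans(folds_df[metric_cols]),
                 method = method),
            class = "slnpm_cv")
}

#' @export
print.slnpm_cv <- function(x, ...) {
  cat("Cross-validated", toupper(x$method), "model over",
      nrow(x$folds), "fold evaluations\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Held-out positives recovered among the top-ranked predictions
#'
#' Ranks all pairs except the training positives by descending score
#' (ties broken by ascending linear index) and counts how many held-out
#' positives appear in the top `k`, for each `k`.
#'
#' @param P Prediction matrix.
#' @param held_out Integer vector of linear indices of held-out positive
#'   pairs.
#' @param train_pos Integer vector of linear indices of training positives
#'   (excluded from the ranking).
#' @param ks Ascending vector of cutoffs.
#' @return Named integer vector of counts, one per `k`.
#' @export
topk_recall <- function(P, held_out, train_pos, ks) {
  stopifnot_matrix(P)
  if (is.unsorted(ks, strictly = TRUE)) {
    stop("`ks` must be strictly ascending", call. = FALSE)
  }
  candidates <- setdiff(seq_along(P), train_pos)
  if (max(ks) > length(candidates)) {
    stop("largest k (", max(ks), ") exceeds the number of candidate pairs (",
         length(candidates), ")", call. = FALSE)
  }
  o <- candidates[order(-P[candidates], candidates)]
  is_hit <- o %in% held_out
  hits <- cumsum(is_hit)
  stats::setNames(hits[ks], as.character(ks))
}

#' Grid search over neighborhood ratio, absorbing probability and fusion weight
#'
#' Full-factorial cross-validated evaluation over the three model
#' parameters. For efficiency the two propagation components are computed
#' once per `(K, alpha)` fold and re-fused for every `beta`, which is
#' algebraically identical to rerunning the full pipeline.
#'
#' @inheritParams cross_validate
#' @param k_grid,alpha_grid,beta_grid Nonempty numeric grids.
#' @param n_runs Repetitions per combination (default 1; the full protocol
#'   rarely pays off during tuning).
#' @return Data frame with one row per `(K, alpha, beta)` holding mean
#'   AUPR and AUC; the AUPR-maximizing row index is in attribute `"best"`.
#' @export
grid_search <- function(Y, X_lnc = NULL, X_mir = NULL,
                        method = c("sc", "pc", "ip", "seq"),
                        k_grid = seq(0.1, 0.9, by = 0.1),
                        alpha_grid = seq(0.1, 0.9, by = 0.1),
                        beta_grid = seq(0, 1, by = 0.05),
                        k_nn = 10, n_runs = 1, n_folds = 5, seed = 1) {
  method <- match.arg(method)
  if (!length(k_grid) || !length(alpha_grid) || !length(beta_grid)) {
    stop("parameter grids must be nonempty", call. = FALSE)
  }
  needs_seq <- method %in% c("sc", "pc", "seq")
  acc <- list()
  for (K in k_grid) {
    lns_cfg <- lns_config(neighbor_ratio = K)
    S_LSF <- if (needs_seq) lns_similarity(X_lnc, lns_cfg) else NULL
    S_MSF <- if (needs_seq) lns_similarity(X_mir, lns_cfg) else NULL
    for (alpha in alpha_grid) {
      # per (run, fold): P_l and P_m are beta-independent
      sums <- matrix(0, length(beta_grid), 2,
                     dimnames = list(NULL, c("aupr", "auc")))
      n_eval <- 0L
      for (r in seq_len(n_runs)) {
        folds <- split_folds(Y, n_folds, seed + r - 1)
        for (f in seq_len(n_folds)) {
          Y_train <- Y
          Y_train[folds[[f]]] <- 0
          P <- pipeline_predict(Y_train, method, S_LSF, S_MSF, lns_cfg,
                                prop_config(alpha = alpha, beta = 0.5), k_nn)
          P_l <- attr(P, "P_l"); P_m <- attr(P, "P_m")
          eval_mask <- Y_train != 1
          labels <- Y[eval_mask]
          for (b in seq_along(beta_grid)) {
            scores <- beta_grid[b] * P_l[eval_mask] +
              (1 - beta_grid[b]) * P_m[eval_mask]
            sums[b, "aupr"] <- sums[b, "aupr"] + average_precision(scores, labels)
            sums[b, "auc"] <- sums[b, "auc"] + rank_auc(scores, labels)
          }
          n_eval <- n_eval + 1L
        }
      }
      acc[[length(acc) + 1L]] <- data.frame(
        K = K, alpha = alpha, beta = beta_grid,
        aupr = sums[, "aupr"] / n_eval, auc = sums[, "auc"] / n_eval)
    }
  }
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  attr(out, "best") <- which.max(out$aupr)
  out
}
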