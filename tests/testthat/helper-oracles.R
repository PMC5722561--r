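# Independent brute-force oracles used by the acceptance and module tests.

# naive UPGMA: exhaustive search of the closest cluster pair at every step,
# cluster distance recomputed as the mean over all original cross-pairs;
# returns the cophenetic (merge-height) matrix
upgma_oracle_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(members) > 1) {
    best <- NULL
    bestd <- Inf
    for (i in seq_len(length(members) - 1))
      for (j in seq(i + 1, length(members))) {
        avg <- mean(d[members[[i]], members[[j]]])
        if (avg < bestd) { bestd <- avg; best <- c(i, j) }
      }
    for (a in members[[best[1]]])
      for (b in members[[best[2]]])
        coph[a, b] <- coph[b, a] <- bestd
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  coph
}

# exact two-group Kruskal-Wallis permutation p by exhaustive enumeration,
# with H computed by stats::kruskal.test (independent of the package's
# internal H path)
kw_permutation_oracle <- function(g1, g2) {
  vals <- c(g1, g2)
  n <- length(vals)
  n1 <- length(g1)
  h_of <- function(idx) {
    g <- factor(seq_len(n) %in% idx)
    unname(stats::kruskal.test(vals, g)$statistic)
  }
  obs <- h_of(seq_len(n1))
  combos <- utils::combn(n, n1)
  hs <- apply(combos, 2, h_of)
  mean(hs >= obs - 1e-12)
}

# straight-line re-implementation of the 0.632+ bootstrap (no selection),
# mirroring the package's derived seed streams so agreement is exact
oracle_632plus <- function(x, y, cfg) {
  yf <- factor(y, levels = c("nontumor", "tumor"))
  n <- nrow(x)
  ds <- function(seed, ...) biomepair:::derive_seed(seed, ...)
  set.seed(ds(cfg$seed, "forest"))
  full <- randomForest::randomForest(x = x, y = yf, ntree = cfg$ntree,
                                     mtry = min(cfg$mtry, ncol(x)),
                                     importance = TRUE, keep.forest = TRUE)
  apparent <- predict(full, x)
  err_bar <- mean(as.character(apparent) != as.character(yf))
  p_cls <- sapply(levels(yf), function(k) mean(yf == k))
  q_cls <- sapply(levels(yf), function(k) mean(apparent == k))
  gamma <- sum(p_cls * (1 - q_cls))

  err_sum <- numeric(n)
  err_cnt <- numeric(n)
  for (b in seq_len(cfg$n_bootstrap)) {
    set.seed(ds(cfg$seed, "boot", b))
    idx <- sample.int(n, n, replace = TRUE)
    holdout <- setdiff(seq_len(n), unique(idx))
    if (!length(holdout)) next
    ytr <- yf[idx]
    if (length(unique(ytr)) == 1) {
      pred <- rep(as.character(ytr[1]), length(holdout))
    } else {
      set.seed(ds(ds(cfg$seed, "boot-fit", b), "forest"))
      rf <- randomForest::randomForest(x = x[idx, , drop = FALSE], y = ytr,
                                       ntree = cfg$ntree,
                                       mtry = min(cfg$mtry, ncol(x)),
                                       importance = TRUE, keep.forest = TRUE)
      pred <- as.character(predict(rf, x[holdout, , drop = FALSE]))
    }
    wrong <- pred != as.character(yf[holdout])
    err_sum[holdout] <- err_sum[holdout] + wrong
    err_cnt[holdout] <- err_cnt[holdout] + 1
  }
  err1 <- mean(err_sum / err_cnt)
  err1p <- min(err1, gamma)
  R <- if (err1p > err_bar && gamma > err_bar)
    (err1p - err_bar) / (gamma - err_bar) else 0
  R <- min(1, max(0, R))
  w <- 0.632 / (1 - 0.368 * R)
  list(err_bar = err_bar, err1 = err1, gamma = gamma, R = R, w = w,
       err_632plus = (1 - w) * err_bar + w * err1p)
}
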