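#' Random-forest layer configuration
#'
#' @param ntree number of trees; odd (default 2001) to avoid vote ties.
#' @param mtry candidate variables per split (default 10; capped at the
#'   number of features actually supplied).
#' @param seed master seed; every stochastic sub-stage (forest fitting,
#'   label permutations, bootstraps) consumes its own derived stream.
#' @param n_random_models label-permuted refits for the importance null
#'   (default 20).
#' @param n_bootstrap bootstrap resamples for the 0.632+ error estimate
#'   (default 1000).
#' @param drop_fraction fraction of the least important remaining variables
#'   removed per backward-elimination step (default 0.2).
#' @param c_sd subset-selection slack in SDs of the minimum OOB error; 0
#'   (default) selects the smallest subset attaining the minimum error.
#' @return an `rf_config` list.
#' @export
rf_config <- function(ntree = 2001, mtry = 10, seed = 1,
                      n_random_models = 20, n_bootstrap = 1000,
                      drop_fraction = 0.2, c_sd = 0) {
  stopifnot(is_count(ntree), ntree >= 3, is_count(mtry), mtry >= 1,
            is_count(n_random_models), is_count(n_bootstrap), c_sd >= 0)
  if (ntree %% 2 == 0) stop2("ntree must be odd to avoid vote ties")
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop2("drop_fraction must lie in (0, 1)")
  structure(list(ntree = ntree, mtry = mtry, seed = seed,
                 n_random_models = n_random_models,
                 n_bootstrap = n_bootstrap, drop_fraction = drop_fraction,
                 c_sd = c_sd),
            class = "rf_config")
}

as_class_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop2("need exactly 2 classes, got: ",
                             paste(lv, collapse = ", "))
  # "tumor" is the positive (vote-fraction) class when present
  if ("tumor" %in% lv) lv <- c(setdiff(lv, "tumor"), "tumor")
  factor(labels, levels = lv)
}

#' Fit a random forest and expose out-of-bag vote fractions
#'
#' Wraps [randomForest::randomForest()]: `ntree` classification trees, each
#' grown on a bootstrap resample with `mtry` candidate variables per split.
#' The vote fraction of a sample is the fraction of trees in which the
#' sample was out of bag that voted for the positive ("tumor") class; the
#' OOB error is the fraction of samples misclassified at the 0.5 vote
#' threshold. Importance is the permutation mean decrease in accuracy.
#'
#' @param features samples x variables numeric matrix (no missing values).
#' @param labels two-class vector/factor aligned with the rows of
#'   `features`; `"tumor"` is used as the positive class when present.
#' @param config an [rf_config()].
#' @return an `rf_fit` list: `model`, `votes` (named per-sample positive
#'   vote fractions), `oob_error`, `importance`, `labels`, `positive`.
#' @export
fit_rf <- function(features, labels, config = rf_config()) {
  features <- as.matrix(features)
  if (anyNA(features)) stop2("missing values in features")
  y <- as_class_factor(labels)
  if (length(y) != nrow(features)) stop2("labels/features length mismatch")
  if (min(table(y)) < 2) stop2("need >= 2 samples per class")
  pos <- levels(y)[2]
  with_seed(derive_seed(config$seed, "forest"), {
    model <- randomForest::randomForest(
      x = features, y = y, ntree = config$ntree,
      mtry = min(config$mtry, ncol(features)),
      importance = TRUE, keep.forest = TRUE)
  })
  if (any(model$oob.times == 0))
    stop2("some samples were out of bag in zero trees; increase ntree")
  votes <- model$votes[, pos]
  names(votes) <- rownames(features) %||% seq_along(votes)
  oob_error <- mean((votes > 0.5) != (y == pos))
  structure(list(model = model,
                 votes = votes,
                 oob_error = oob_error,
                 importance = model$importance[, "MeanDecreaseAccuracy"],
                 labels = y, positive = pos, config = config),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %d samples, %d variables, ntree=%d, OOB error %.3f\n",
              length(x$votes), length(x$importance),
              x$config$ntree, x$oob_error))
  invisible(x)
}

#' Importance null from label-permuted refits
#'
#' The observed sorted importance curve is compared with
#' `n_random_models` curves from models refit on randomly permuted labels
#' (class sizes preserved exactly). Informative data shows the observed
#' curve rising above the null band at the top ranks; pure noise stays
#' within it.
#'
#' @inheritParams fit_rf
#' @return list with `observed` (sorted non-increasing importance),
#'   `null_curves` (`n_random_models` x variables matrix, each row sorted),
#'   `null_mean` and `null_sd` per rank.
#' @export
importance_null <- function(features, labels, config = rf_config()) {
  if (config$n_random_models < 2) stop2("n_random_models must be >= 2")
  observed <- sort(fit_rf(features, labels, config)$importance,
                   decreasing = TRUE)
  y <- as_class_factor(labels)
  curves <- t(vapply(seq_len(config$n_random_models), function(m) {
    perm <- with_seed(derive_seed(config$seed, "null-perm", m),
                      sample(as.character(y)))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "null-fit", m)
    sort(fit_rf(features, perm, cfg)$importance, decreasing = TRUE)
  }, numeric(ncol(features))))
  list(observed = observed, null_curves = curves,
       null_mean = colMeans(curves), null_sd = apply(curves, 2, stats::sd))
}

backward_sizes <- function(p, drop_fraction) {
  sizes <- p
  k <- p
  while (k > 2) {
    k2 <- max(2, floor(k * (1 - drop_fraction)))
    if (k2 >= k) k2 <- k - 1
    sizes <- c(sizes, k2)
    k <- k2
  }
  sizes
}

#' Backward variable elimination over OOB error
#'
#' Variables are ranked once by the full model's permutation importance
#' (not re-ranked after drops, avoiding selection bias); at each step the
#' least important `drop_fraction` of the remaining variables is removed
#' and the OOB error of a forest on the survivors recorded, down to 2
#' variables. With `c_sd = 0` the subset attaining the minimum OOB error is
#' selected, ties broken toward the smallest subset; `c_sd > 0` allows any
#' subset within `c_sd` binomial SDs of the minimum.
#'
#' @inheritParams fit_rf
#' @return list with `sizes`, `oob_errors`, `selected_size`,
#'   `selected_vars`, `ranking` (full-model importance order) and
#'   `full_fit`.
#' @export
backward_variable_selection <- function(features, labels,
                                        config = rf_config()) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop2("need >= 2 features")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("v", seq_len(ncol(features)))
  full <- fit_rf(features, labels, config)
  ranking <- colnames(features)[order(full$importance, decreasing = TRUE)]
  sizes <- backward_sizes(ncol(features), config$drop_fraction)
  errors <- vapply(sizes, function(k) {
    if (k == ncol(features)) return(full$oob_error)
    fit_rf(features[, ranking[seq_len(k)], drop = FALSE],
           labels, config)$oob_error
  }, numeric(1))
  min_err <- min(errors)
  n <- nrow(features)
  thresh <- min_err + config$c_sd * sqrt(min_err * (1 - min_err) / n)
  selected_size <- min(sizes[errors <= thresh])
  list(sizes = sizes, oob_errors = errors,
       selected_size = selected_size,
       selected_vars = ranking[seq_len(selected_size)],
       ranking = ranking, full_fit = full)
}

#' No-information error rate
#'
#' `gamma = sum_k p_k (1 - q_k)` over classes, where `p_k` are the observed
#' class proportions and `q_k` the predicted-class proportions: the error
#' rate expected if predictions were assigned independently of the truth.
#'
#' @param labels observed class vector.
#' @param predictions predicted class vector of equal length.
#' @return the no-information rate in `[0, 1]`.
#' @export
no_information_rate <- function(labels, predictions) {
  if (!length(labels) || length(labels) != length(predictions))
    stop2("labels and predictions must be equal-length, non-empty")
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  classes <- union(labels, predictions)
  p <- vapply(classes, function(k) mean(labels == k), numeric(1))
  q <- vapply(classes, function(k) mean(predictions == k), numeric(1))
  sum(p * (1 - q))
}

#' The 0.632+ combination formulas
#'
#' Given the apparent error `err_bar`, the leave-one-out bootstrap error
#' `err1` and the no-information rate `gamma`, computes the clipped
#' `err1' = min(err1, gamma)`, the relative overfitting rate
#' `R = (err1' - err_bar) / (gamma - err_bar)` (0 when `err1' <= err_bar`
#' or `gamma <= err_bar`, clipped to `[0, 1]`), the weight
#' `w = 0.632 / (1 - 0.368 R)` and the estimate
#' `err632plus = (1 - w) err_bar + w err1'`.
#'
#' @param err_bar apparent (training) error in `[0, 1]`.
#' @param err1 leave-one-out bootstrap error in `[0, 1]`.
#' @param gamma no-information rate in `[0, 1]`.
#' @return list `err_bar`, `err1`, `err1_prime`, `gamma`, `R`, `w`,
#'   `err_632plus`.
#' @export
estimate_632plus <- function(err_bar, err1, gamma) {
  stopifnot(err_bar >= 0, err_bar <= 1, err1 >= 0, err1 <= 1,
            gamma >= 0, gamma <= 1)
  err1_prime <- min(err1, gamma)
  R <- if (err1_prime > err_bar && gamma > err_bar)
    (err1_prime - err_bar) / (gamma - err_bar) else 0
  R <- min(1, max(0, R))
  w <- 0.632 / (1 - 0.368 * R)
  list(err_bar = err_bar, err1 = err1, err1_prime = err1_prime,
       gamma = gamma, R = R, w = w,
       err_632plus = (1 - w) * err_bar + w * err1_prime)
}

#' 0.632+ bootstrap estimate of prediction error
#'
#' For each of `n_bootstrap` resamples, samples drawn with replacement form
#' the training set and the never-drawn samples are held out; a forest
#' (optionally preceded by in-bootstrap backward variable selection) is fit
#' on the training set and the held-out samples are predicted. `err1` is
#' the mean over samples of each sample's mean held-out error; the apparent
#' error `err_bar` and no-information rate come from the full-data forest
#' predicting its own training data with all trees. The components are
#' combined by [estimate_632plus()].
#'
#' @inheritParams fit_rf
#' @param with_selection run [backward_variable_selection()] inside each
#'   bootstrap and record the selected variable sets.
#' @return a `bootstrap_eval` list: the estimator internals (`err_bar`,
#'   `err1`, `gamma`, `R`, `w`, `err_632plus`), per-sample holdout counts,
#'   and — with selection — per-iteration error curves, selected sets and
#'   per-variable selection frequencies.
#' @export
bootstrap_632plus <- function(features, labels, config = rf_config(),
                              with_selection = FALSE) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("v", seq_len(ncol(features)))
  y <- as_class_factor(labels)
  n <- nrow(features)

  full <- fit_rf(features, y, config)
  apparent_pred <- stats::predict(full$model, features)
  err_bar <- mean(as.character(apparent_pred) != as.character(y))
  gamma <- no_information_rate(y, apparent_pred)

  err_sum <- numeric(n)
  err_cnt <- numeric(n)
  curves <- list()
  selected_sets <- list()
  for (b in seq_len(config$n_bootstrap)) {
    idx <- with_seed(derive_seed(config$seed, "boot", b),
                     sample.int(n, n, replace = TRUE))
    holdout <- setdiff(seq_len(n), unique(idx))
    if (!length(holdout)) next
    ytr <- y[idx]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "boot-fit", b)
    if (length(unique(ytr)) == 1) {
      pred <- rep(as.character(ytr[1]), length(holdout))
    } else if (with_selection) {
      sel <- backward_variable_selection(features[idx, , drop = FALSE],
                                         ytr, cfg)
      curves[[length(curves) + 1]] <-
        data.frame(iteration = b, size = sel$sizes, oob_error = sel$oob_errors)
      selected_sets[[length(selected_sets) + 1]] <- sel$selected_vars
      fit <- fit_rf(features[idx, sel$selected_vars, drop = FALSE], ytr, cfg)
      pred <- as.character(stats::predict(
        fit$model, features[holdout, sel$selected_vars, drop = FALSE]))
    } else {
      fit <- fit_rf(features[idx, , drop = FALSE], ytr, cfg)
      pred <- as.character(stats::predict(fit$model,
                                          features[holdout, , drop = FALSE]))
    }
    wrong <- pred != as.character(y[holdout])
    err_sum[holdout] <- err_sum[holdout] + wrong
    err_cnt[holdout] <- err_cnt[holdout] + 1
  }
  if (any(err_cnt == 0))
    stop2(sum(err_cnt == 0),
          " sample(s) never held out; increase n_bootstrap")
  err1 <- mean(err_sum / err_cnt)

  est <- estimate_632plus(err_bar, err1, gamma)
  sel_freq <- NULL
  if (with_selection && length(selected_sets)) {
    tabs <- table(unlist(selected_sets))
    sel_freq <- stats::setNames(numeric(ncol(features)), colnames(features))
    sel_freq[names(tabs)] <- tabs / length(selected_sets)
  }
  structure(c(est,
              list(n_bootstrap = config$n_bootstrap,
                   holdout_counts = err_cnt,
                   selection_frequency = sel_freq,
                   error_curves = if (length(curves)) do.call(rbind, curves),
                   selected_sets = selected_sets,
                   full_fit = full)),
            class = "bootstrap_eval")
}

#' @export
print.bootstrap_eval <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_eval> err_bar=%.3f err1=%.3f gamma=%.3f ",
                     "R=%.3f w=%.3f err632+=%.3f (%d bootstraps)\n"),
              x$err_bar, x$err1, x$gamma, x$R, x$w, x$err_632plus,
              x$n_bootstrap))
  invisible(x)
}

#' Per-patient tumor minus non-tumor vote-fraction differences
#'
#' For each complete pair, `d = voteFraction(tumor) -
#' voteFraction(nontumor)`; `d > 0` means the pair trends in the correct
#' direction even when individual samples are misclassified at the 0.5
#' threshold. Pairs lacking a vote for either member are excluded and
#' logged. Patient covariates are joined in for downstream grouping.
#'
#' @param fit an [fit_rf()] result whose votes cover the cohort's paired
#'   samples.
#' @param cohort the `paired_cohort` the features came from.
#' @return data.frame of class `vote_diff`: `patient_id`, `vote_tumor`,
#'   `vote_nontumor`, `d`, per-sample correctness flags,
#'   `correct_direction`, and patient covariates.
#' @export
vote_fraction_differences <- function(fit, cohort) {
  stopifnot(inherits(fit, "rf_fit"), is_paired_cohort(cohort))
  votes <- fit$votes
  pairs <- cohort$pairs
  have <- pairs$tumor %in% names(votes) & pairs$nontumor %in% names(votes)
  if (any(!have))
    log_msg("votediff", "excluding ", sum(!have),
            " pair(s) without votes: ",
            paste(pairs$patient_id[!have], collapse = ", "))
  pairs <- pairs[have, , drop = FALSE]
  if (!nrow(pairs)) stop2("no pair has votes for both samples")
  out <- data.frame(
    patient_id = pairs$patient_id,
    vote_tumor = as.numeric(votes[pairs$tumor]),
    vote_nontumor = as.numeric(votes[pairs$nontumor]),
    stringsAsFactors = FALSE)
  out$d <- out$vote_tumor - out$vote_nontumor
  out$tumor_correct <- out$vote_tumor > 0.5
  out$nontumor_correct <- !(out$vote_nontumor > 0.5)
  out$correct_direction <- out$d > 0
  covars <- cohort$metadata[cohort$metadata$tissue == "tumor",
                            intersect(c("patient_id", "t_stage", "n_stage",
                                        "smoking", "age", "sex"),
                                      names(cohort$metadata)),
                            drop = FALSE]
  out <- merge(out, covars, by = "patient_id", sort = TRUE)
  class(out) <- c("vote_diff", class(out))
  out
}

#' Test vote-fraction differences across a clinical grouping
#'
#' Compares the per-patient paired differences `d` between the grouping's
#' levels — the between-group test of the tissue-by-group interaction in a
#' two-level repeated-measures design. Default is the Welch test
#' ([stats::oneway.test()], equal to the two-sided Welch t-test for two
#' groups); `method = "ranksum"` uses Wilcoxon/Kruskal-Wallis.
#'
#' A shrunken mean `d` in one group (e.g. high T-stage) indicates that the
#' group's normal tissue already resembles its tumor tissue — a
#' field-cancerization signature.
#'
#' @param votediff a [vote_fraction_differences()] result.
#' @param grouping covariate column (default `"t_stage"`).
#' @param method `"welch"` or `"ranksum"`.
#' @return list with `grouping`, per-group `means`, `sds` and `sizes`,
#'   `statistic`, `p_value`, `method`, and `direction` (the group with the
#'   smaller mean `d`).
#' @export
field_effect_test <- function(votediff, grouping = "t_stage",
                              method = c("welch", "ranksum")) {
  method <- match.arg(method)
  if (!grouping %in% names(votediff))
    stop2("grouping '", grouping, "' not in vote-difference table")
  keep <- !is.na(votediff[[grouping]])
  if (any(!keep))
    log_msg("fieldeffect", "excluding ", sum(!keep),
            " patient(s) with unknown ", grouping)
  d <- votediff$d[keep]
  g <- factor(votediff[[grouping]][keep])
  if (nlevels(g) < 2) stop2("grouping '", grouping, "' has a single level")
  if (min(table(g)) < 2) stop2("need >= 2 patients per group")

  means <- tapply(d, g, mean)
  sds <- tapply(d, g, stats::sd)
  if (all(sds == 0, na.rm = TRUE)) {
    p <- if (length(unique(means)) == 1) 1 else 0
    stat <- NA_real_
  } else if (method == "welch") {
    ht <- stats::oneway.test(d ~ g, var.equal = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (nlevels(g) == 2) {
    ht <- suppressWarnings(stats::wilcox.test(d ~ g))
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    ht <- stats::kruskal.test(d, g)
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  list(grouping = grouping,
       means = means, sds = sds, sizes = table(g),
       statistic = stat, p_value = p, method = method,
       direction = names(means)[which.min(means)])
}
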