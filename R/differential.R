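# Group-wise hypothesis testing on diversity and per-taxon abundance, and
# intra-/inter-kingdom correlation screens.

kw_statistic <- function(values, g) {
  # H on mid-ranks with tie correction
  n <- length(values)
  r <- rank(values)
  nj <- tapply(r, g, length)
  rj <- tapply(r, g, mean)
  h <- 12 / (n * (n + 1)) * sum(nj * (rj - (n + 1) / 2)^2)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0)  # all values identical
  h / corr
}

#' Kruskal-Wallis rank test
#'
#' H is computed on mid-ranks with tie correction. `p_method = "chisq"`
#' (default, via [stats::kruskal.test()]) refers H to a chi-square
#' distribution with `length(groups) - 1` degrees of freedom;
#' `p_method = "exact"` (two groups, small n) enumerates all label
#' assignments and returns the exact permutation p-value
#' `P(H_perm >= H_obs)`.
#'
#' @param groups list of numeric vectors, each non-empty, total n >= 3.
#' @param p_method `"chisq"` or `"exact"`.
#' @return list with `statistic` (H), `p_value`, `df`, `method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "exact")) {
  p_method <- match.arg(p_method)
  if (length(groups) < 2) stop2("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop2("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop2("need total n >= 3")
  g <- factor(rep(seq_along(groups), sizes))
  df <- length(groups) - 1

  if (length(unique(values)) == 1)
    return(list(statistic = 0, p_value = 1, df = df, method = p_method))

  if (p_method == "chisq") {
    kt <- stats::kruskal.test(values, g)
    return(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                df = df, method = "chisq"))
  }
  if (length(groups) != 2)
    stop2("exact permutation p implemented for 2 groups only")
  h_obs <- kw_statistic(values, g)
  n <- length(values)
  combos <- utils::combn(n, sizes[1])
  h_perm <- apply(combos, 2, function(idx) {
    gp <- factor(ifelse(seq_len(n) %in% idx, 1, 2))
    kw_statistic(values, gp)
  })
  list(statistic = h_obs,
       p_value = mean(h_perm >= h_obs - 1e-12),
       df = df, method = "exact")
}

#' Dunn post-hoc comparisons with Bonferroni adjustment
#'
#' Pairwise z statistics on pooled mid-ranks with tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups; two-sided normal p-values are
#' multiplied by the number of comparisons and capped at 1. With two groups
#' the adjustment factor is 1.
#'
#' @param groups named (or unnamed) list of numeric vectors.
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_bonferroni <- function(groups) {
  if (length(groups) < 2) stop2("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop2("empty group")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  g <- rep(names(groups), lengths(groups))
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  ties <- table(values)
  sigma2 <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  cmb <- utils::combn(names(groups), 2)
  k <- ncol(cmb)
  out <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    a <- cmb[1, i]; b <- cmb[2, i]
    se <- sqrt(sigma2 * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    out$z[i] <- z
    out$p[i] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adj <- pmin(1, out$p * k)
  out
}

grouping_values <- function(metadata, grouping) {
  if (!grouping %in% names(metadata))
    stop2("grouping variable '", grouping, "' not in metadata")
  v <- metadata[[grouping]]
  if (all(is.na(v))) stop2("grouping variable '", grouping, "' is all-unknown")
  v
}

select_analysis_samples <- function(metadata, grouping, tissue = NULL) {
  md <- metadata
  if (!is.null(tissue)) {
    tissue <- match.arg(tissue, c("tumor", "nontumor"))
    md <- md[md$tissue == tissue, , drop = FALSE]
  }
  v <- grouping_values(md, grouping)
  known <- !is.na(v)
  if (any(!known))
    log_msg("stats", "excluding ", sum(!known),
            " sample(s) with unknown ", grouping)
  md[known, , drop = FALSE]
}

#' Per-taxon differential abundance screen
#'
#' Relative abundance is computed per kingdom at the requested rank; each
#' taxon with a nonzero total is tested across the grouping's levels with
#' the Kruskal-Wallis test, and Bonferroni-Dunn adjustment is applied
#' within the set of taxa tested per kingdom (the multiplicity family).
#' All-zero taxa are excluded and logged. The unpaired Kruskal-Wallis
#' comparison deliberately ignores the patient pairing; `paired = TRUE`
#' switches to a Wilcoxon signed-rank test on within-pair differences, an
#' extension available only for the tissue grouping.
#'
#' @param cohort a `paired_cohort`.
#' @param rank taxonomic rank to test at.
#' @param grouping metadata column defining groups (default `"tissue"`).
#' @param tissue optional tissue filter for covariate groupings (e.g. T-stage
#'   within tumor samples).
#' @param paired use the paired Wilcoxon signed-rank variant.
#' @return data.frame, one row per taxon, sorted by adjusted p: lineage,
#'   per-group mean/SD of relative abundance, `statistic`, `p`, `p_adj`,
#'   `direction`.
#' @export
per_taxon_differential <- function(cohort, rank = "genus",
                                   grouping = "tissue", tissue = NULL,
                                   paired = FALSE) {
  stopifnot(is_paired_cohort(cohort))
  if (paired && grouping != "tissue")
    stop2("paired variant only applies to the tissue grouping")
  md <- select_analysis_samples(cohort$metadata, grouping, tissue)
  groups <- md[[grouping]]
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop2("grouping '", grouping, "' has a single level")
  if (min(table(groups)) < 2) stop2("need >= 2 samples per group")

  res <- lapply(c("bacteria", "fungi"), function(kd) {
    tab <- aggregate_to_rank(cohort[[kd]], rank)
    tab <- subset_samples(tab, md$sample_id)
    nonzero <- rowSums(tab$counts) > 0
    if (any(!nonzero))
      log_msg("difftax", sum(!nonzero), " all-zero ", kd,
              " taxa excluded at rank ", rank)
    tab <- abundance_table(tab$taxa[nonzero, , drop = FALSE],
                           tab$counts[nonzero, , drop = FALSE],
                           rank = rank, values = tab$values)
    props <- to_relative_abundance(tab)$counts
    m <- nrow(props)
    if (m == 0) return(NULL)
    rows <- lapply(seq_len(m), function(i) {
      by_group <- split(props[i, ], groups)[lv]
      if (paired) {
        d <- props[i, md$sample_id[md$tissue == "tumor"]] -
          props[i, md$sample_id[md$tissue == "nontumor"]]
        wt <- suppressWarnings(stats::wilcox.test(d))
        stat <- unname(wt$statistic); pv <- wt$p.value
      } else {
        kw <- kruskal_wallis(by_group)
        stat <- kw$statistic; pv <- kw$p_value
      }
      means <- vapply(by_group, mean, numeric(1))
      sds <- vapply(by_group, stats::sd, numeric(1))
      direction <- if ("tumor" %in% lv) {
        if (means[["tumor"]] >= mean(means[setdiff(lv, "tumor")]))
          "tumor_up" else "tumor_down"
      } else paste0(lv[which.max(means)], "_up")
      c(list(kingdom = kd, taxon_id = tab$taxa$taxon_id[i],
             phylum = tab$taxa$phylum[i], genus = tab$taxa$genus[i]),
        stats::setNames(as.list(means), paste0("mean_", lv)),
        stats::setNames(as.list(sds), paste0("sd_", lv)),
        list(statistic = stat, p = pv, direction = direction))
    })
    out <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    out$p_adj <- pmin(1, out$p * m)  # Bonferroni-Dunn within the taxon family
    out
  })
  res <- do.call(rbind, res)
  res <- res[order(res$p_adj, res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare diversity or richness across groups
#'
#' The per-sample metric ([sample_diversity()]) is computed per kingdom at
#' the requested rank, then compared across the grouping's levels with the
#' Kruskal-Wallis test.
#'
#' @inheritParams per_taxon_differential
#' @param metric `"shannon"` or `"richness"`.
#' @return data.frame, one row per kingdom, with per-group means/SDs,
#'   `statistic` and `p`.
#' @export
diversity_comparison <- function(cohort, rank = "genus",
                                 metric = c("shannon", "richness"),
                                 grouping = "tissue", tissue = NULL) {
  metric <- match.arg(metric)
  stopifnot(is_paired_cohort(cohort))
  md <- select_analysis_samples(cohort$metadata, grouping, tissue)
  groups <- md[[grouping]]
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop2("grouping '", grouping, "' has a single level")

  rows <- lapply(c("bacteria", "fungi"), function(kd) {
    tab <- subset_samples(aggregate_to_rank(cohort[[kd]], rank), md$sample_id)
    div <- sample_diversity(tab)
    v <- div[[metric]]
    by_group <- split(v, groups)[lv]
    kw <- kruskal_wallis(by_group)
    c(list(kingdom = kd, metric = metric, rank = rank),
      stats::setNames(as.list(vapply(by_group, mean, numeric(1))),
                      paste0("mean_", lv)),
      stats::setNames(as.list(vapply(by_group, stats::sd, numeric(1))),
                      paste0("sd_", lv)),
      list(statistic = kw$statistic, p = kw$p_value))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Intra- and inter-kingdom abundance correlation screen
#'
#' Rank (Spearman, default) correlations between taxon relative abundances
#' across the samples of one tissue. `scope` selects all pairs within
#' bacteria, within fungi, or the rectangular bacteria-by-fungi set.
#' Benjamini-Hochberg adjustment is applied across all testable pairs in
#' the scope (exploratory screens over thousands of pairs). Constant taxa
#' yield undefined coefficients, reported as `NA`.
#'
#' @param cohort a `paired_cohort`.
#' @param rank taxonomic rank.
#' @param tissue `"tumor"` or `"nontumor"`.
#' @param scope `"intra_bacteria"`, `"intra_fungi"` or `"inter_kingdom"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `scope`, `tissue`, `method`, `pairs` (data.frame
#'   `taxon1`, `taxon2`, `r`, `p`, `p_adj`) and the coefficient matrix `r`.
#' @export
correlation_screen <- function(cohort, rank = "genus", tissue = "tumor",
                               scope = c("intra_bacteria", "intra_fungi",
                                         "inter_kingdom"),
                               method = c("spearman", "pearson")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  stopifnot(is_paired_cohort(cohort))
  tissue <- match.arg(tissue, c("tumor", "nontumor"))
  ids <- cohort$metadata$sample_id[cohort$metadata$tissue == tissue]
  if (length(ids) < 4) stop2("need >= 4 samples in tissue '", tissue, "'")

  mat_of <- function(kd) {
    tab <- subset_samples(aggregate_to_rank(cohort[[kd]], rank), ids)
    tab <- drop_empty_taxa(tab)
    t(to_relative_abundance(tab)$counts)   # samples x taxa
  }
  if (scope == "inter_kingdom") {
    x <- mat_of("bacteria"); y <- mat_of("fungi")
  } else {
    x <- y <- mat_of(if (scope == "intra_bacteria") "bacteria" else "fungi")
  }
  suppressWarnings({
    r <- stats::cor(x, y, method = method)
  })
  const_x <- apply(x, 2, function(v) length(unique(v)) == 1)
  const_y <- apply(y, 2, function(v) length(unique(v)) == 1)
  r[const_x, ] <- NA
  r[, const_y] <- NA

  if (scope == "inter_kingdom") {
    pairs <- expand.grid(taxon1 = colnames(x), taxon2 = colnames(y),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    cmb <- utils::combn(colnames(x), 2)
    pairs <- data.frame(taxon1 = cmb[1, ], taxon2 = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  pairs$r <- r[cbind(pairs$taxon1, pairs$taxon2)]
  n <- nrow(x)
  pairs$p <- vapply(seq_len(nrow(pairs)), function(i) {
    if (is.na(pairs$r[i])) return(NA_real_)
    suppressWarnings(stats::cor.test(x[, pairs$taxon1[i]],
                                     y[, pairs$taxon2[i]],
                                     method = method, exact = FALSE)$p.value)
  }, numeric(1))
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  list(scope = scope, tissue = tissue, method = method,
       pairs = pairs, r = r, n_samples = n)
}
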