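#' Validated sample-by-sample distance matrices
#'
#' A distance matrix here is a square numeric matrix with sample IDs as
#' dimnames, symmetric with a zero diagonal and non-negative entries
#' (Bray-Curtis and unweighted UniFrac values additionally lie in `[0,1]`).
#'
#' @param d square numeric matrix.
#' @return the validated matrix, classed `distance_matrix`.
#' @export
distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop2("distance matrix must be square")
  if (anyNA(d) || any(!is.finite(d))) stop2("NaN/NA distances")
  if (any(d < 0)) stop2("negative distances")
  if (max(abs(d - t(d))) > 1e-12) stop2("asymmetric distance matrix")
  if (any(abs(diag(d)) > 1e-12)) stop2("non-zero diagonal")
  if (is.null(rownames(d))) stop2("distance matrix needs sample IDs")
  colnames(d) <- rownames(d)
  class(d) <- c("distance_matrix", class(d))
  d
}

counts_of <- function(x) {
  if (is_abundance_table(x)) x$counts else as.matrix(x)
}

#' Shannon diversity index of one sample
#'
#' Entropy `H = -sum(p_i * log(p_i))` over the positive entries of a
#' proportion vector; natural log by default (the ecology convention), with
#' `base` for log2/log10 variants. `H` lies in `[0, log(richness)]`, with
#' the maximum attained by a uniform community.
#'
#' @param proportions non-negative vector summing to 1 (tolerance 1e-6).
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return the Shannon index.
#' @export
shannon_index <- function(proportions, base = exp(1)) {
  if (any(proportions < 0)) stop2("negative proportions")
  if (abs(sum(proportions) - 1) > 1e-6)
    stop2("proportions sum to ", format(sum(proportions)), ", not 1")
  as.numeric(vegan::diversity(proportions, index = "shannon", base = base))
}

#' Taxon richness of one sample
#'
#' Number of taxa with strictly positive abundance; invariant to rescaling.
#'
#' @param counts non-negative vector.
#' @return integer count of positive entries.
#' @export
richness <- function(counts) {
  if (any(counts < 0)) stop2("negative counts")
  sum(counts > 0)
}

#' Per-sample Shannon index and richness of a table
#'
#' @param table an [abundance_table()] (counts or proportions).
#' @param base logarithm base for the Shannon index.
#' @return data.frame `sample_id`, `shannon`, `richness`, with the table's
#'   rank as attribute `"rank"`.
#' @export
sample_diversity <- function(table, base = exp(1)) {
  stopifnot(is_abundance_table(table))
  m <- table$counts
  totals <- colSums(m)
  if (any(totals == 0))
    stop2("zero-total sample(s): ",
          paste(colnames(m)[totals == 0], collapse = ", "))
  props <- sweep(m, 2, totals, "/")
  out <- data.frame(
    sample_id = colnames(m),
    shannon = apply(props, 2, shannon_index, base = base),
    richness = apply(m, 2, richness),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rank") <- table$rank
  out
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `BC(a, b) = 1 - 2 * sum(min(a_i, b_i)) / (sum(a) + sum(b))`, computed via
#' [vegan::vegdist()]. Values lie in `[0, 1]`: 0 for identical columns, 1
#' for disjoint support.
#'
#' @param x an [abundance_table()] or taxa-by-samples matrix (counts or
#'   proportions).
#' @return a [distance_matrix()].
#' @export
bray_curtis <- function(x) {
  m <- counts_of(x)
  if (ncol(m) < 2) stop2("need at least 2 samples")
  totals <- colSums(m)
  if (any(totals == 0))
    stop2("zero-total sample(s): ",
          paste(colnames(m)[totals == 0], collapse = ", "))
  distance_matrix(as.matrix(vegan::vegdist(t(m), method = "bray")))
}

#' Unweighted UniFrac distances
#'
#' Presence/absence phylogenetic dissimilarity: for samples A and B, the
#' total length of branches leading exclusively to taxa present in exactly
#' one of the two samples, divided by the total length of branches leading
#' to taxa present in either. Implemented directly on the tree's edge
#' matrix so that arbitrary rooted topologies (including multifurcations
#' and star trees) are handled; [picante::unifrac()] restricts itself to
#' strictly rooted binary-basal trees and serves as a cross-check.
#'
#' @param table an [abundance_table()] or taxa-by-samples matrix; only
#'   presence (`> 0`) is used.
#' @param tree a rooted `phylo` whose tip set covers the table's taxa, with
#'   positive branch lengths.
#' @return a [distance_matrix()].
#' @export
unweighted_unifrac <- function(table, tree) {
  m <- counts_of(table)
  if (ncol(m) < 2) stop2("need at least 2 samples")
  if (is.null(tree$edge.length)) stop2("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) stop2("tree branch lengths must be > 0")
  missing <- setdiff(rownames(m), tree$tip.label)
  if (length(missing))
    stop2("taxa missing from tree: ", paste(missing, collapse = ", "))
  totals <- colSums(m > 0)
  if (any(totals == 0))
    stop2("sample(s) with no taxa present: ",
          paste(colnames(m)[totals == 0], collapse = ", "))

  ntip <- length(tree$tip.label)
  # tips descending from the child node of each edge
  clades <- ape::prop.part(tree)
  child <- tree$edge[, 2]
  incidence <- matrix(FALSE, nrow(tree$edge), ntip)
  for (e in seq_len(nrow(tree$edge))) {
    tips <- if (child[e] <= ntip) child[e] else clades[[child[e] - ntip]]
    incidence[e, tips] <- TRUE
  }

  pres <- matrix(FALSE, ncol(m), ntip,
                 dimnames = list(colnames(m), tree$tip.label))
  pres[, rownames(m)] <- t(m > 0)
  edge_pres <- pres %*% t(incidence) > 0   # samples x edges
  len <- tree$edge.length
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- edge_pres[i, ]; b <- edge_pres[j, ]
    shared_total <- sum(len[a | b])
    d[i, j] <- d[j, i] <- sum(len[xor(a, b)]) / shared_total
  }
  distance_matrix(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes it via [stats::cmdscale()].
#' Coordinates on a Euclidean input reproduce the distances exactly at full
#' rank. Negative eigenvalues (common for Bray-Curtis) are reported, and by
#' default excluded from the variance-explained denominator.
#'
#' @param dm a [distance_matrix()] (or square symmetric matrix).
#' @param k number of axes (at most `n - 1`).
#' @param negative_in_denominator include `abs()` of negative eigenvalues in
#'   the variance-explained denominator.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   non-increasing, negatives retained) and `variance_explained` per
#'   returned axis.
#' @export
pcoa_ordination <- function(dm, k = 2, negative_in_denominator = FALSE) {
  d <- distance_matrix(dm)
  n <- nrow(d)
  if (k > n - 1) stop2("k must be at most n - 1 = ", n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  coords <- fit$points
  eig <- fit$eig
  denom <- if (negative_in_denominator) sum(abs(eig)) else sum(pmax(eig, 0))
  list(coordinates = coords,
       eigenvalues = eig,
       variance_explained = pmax(eig[seq_len(ncol(coords))], 0) / denom)
}

#' UPGMA (average-linkage) dendrogram of samples
#'
#' Samples are ordered lexicographically before clustering so that merge
#' ties resolve deterministically. The result is ultrametric with
#' non-decreasing merge heights; leaf heights follow the average-linkage
#' convention (two samples at distance 0.4 merge at height 0.2).
#'
#' @param dm a [distance_matrix()].
#' @param linkage `"average"` (UPGMA, default) or `"complete"`.
#' @return list with `hclust`, the corresponding `phylo`, its `newick`
#'   string, and the merge `heights`.
#' @export
upgma_dendrogram <- function(dm, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  d <- distance_matrix(dm)
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(unclass(d)), method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy, newick = ape::write.tree(phy),
       heights = hc$height)
}

#' Write a distance matrix as square TSV with header row and column
#' @param dm a [distance_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  d <- distance_matrix(dm)
  df <- data.frame(sample_id = rownames(d), unclass(d),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
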