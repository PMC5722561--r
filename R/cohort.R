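#' Paired two-kingdom cohorts
#'
#' A `paired_cohort` bundles the bacterial and fungal abundance tables, the
#' sample metadata, and the patient pairing map (one tumor and one non-tumor
#' sample per patient). Only patients contributing a complete pair present
#' in both kingdom tables are retained; everything else is reported and
#' dropped.
#'
#' @param bacteria,fungi [abundance_table()] objects (kingdoms checked).
#' @param metadata validated metadata (see [sample_metadata()]).
#' @return an object of class `paired_cohort`: a list with `bacteria`,
#'   `fungi`, `metadata`, and `pairs` (data.frame `patient_id`, `tumor`,
#'   `nontumor` holding sample IDs).
#' @export
build_cohort <- function(bacteria, fungi, metadata) {
  stopifnot(is_abundance_table(bacteria), is_abundance_table(fungi))
  if (!all(bacteria$taxa$kingdom == "bacteria"))
    stop2("'bacteria' table contains non-bacterial lineages")
  if (!all(fungi$taxa$kingdom == "fungi"))
    stop2("'fungi' table contains non-fungal lineages")
  metadata <- sample_metadata(metadata)

  present <- metadata$sample_id %in% sample_ids(bacteria) &
    metadata$sample_id %in% sample_ids(fungi)
  if (any(!present))
    log_msg("cohort", "dropping ", sum(!present),
            " metadata sample(s) absent from one or both tables: ",
            paste(metadata$sample_id[!present], collapse = ", "))
  md <- metadata[present, , drop = FALSE]

  tum <- md[md$tissue == "tumor", c("patient_id", "sample_id")]
  non <- md[md$tissue == "nontumor", c("patient_id", "sample_id")]
  pairs <- merge(tum, non, by = "patient_id", suffixes = c(".t", ".n"))
  names(pairs) <- c("patient_id", "tumor", "nontumor")
  pairs <- pairs[order(pairs$patient_id), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0)
    stop2("no patient has a complete tumor/non-tumor pair in both tables")
  unpaired <- setdiff(md$patient_id, pairs$patient_id)
  if (length(unpaired))
    log_msg("cohort", "excluding ", length(unpaired),
            " patient(s) without a complete pair: ",
            paste(unpaired, collapse = ", "))

  ids <- c(rbind(pairs$tumor, pairs$nontumor))
  md <- md[md$sample_id %in% ids, , drop = FALSE]
  md <- md[order(md$patient_id, md$tissue), , drop = FALSE]
  rownames(md) <- NULL
  cohort <- structure(
    list(bacteria = drop_empty_taxa(subset_samples(bacteria, md$sample_id)),
         fungi = drop_empty_taxa(subset_samples(fungi, md$sample_id)),
         metadata = md, pairs = pairs),
    class = "paired_cohort")
  cohort
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf(paste0("<paired_cohort> %d patients (%d samples); ",
                     "%d bacterial + %d fungal taxa at rank %s/%s\n"),
              nrow(x$pairs), nrow(x$metadata),
              nrow(x$bacteria$counts), nrow(x$fungi$counts),
              x$bacteria$rank, x$fungi$rank))
  invisible(x)
}

#' @rdname build_cohort
#' @param x object to test.
#' @export
is_paired_cohort <- function(x) inherits(x, "paired_cohort")

#' Keep only the given patients of a cohort
#' @keywords internal
subset_cohort <- function(cohort, patient_ids) {
  pairs <- cohort$pairs[cohort$pairs$patient_id %in% patient_ids, , drop = FALSE]
  if (nrow(pairs) == 0) stop2("no patients left after subsetting")
  ids <- c(rbind(pairs$tumor, pairs$nontumor))
  md <- cohort$metadata[cohort$metadata$sample_id %in% ids, , drop = FALSE]
  rownames(md) <- NULL
  rownames(pairs) <- NULL
  structure(list(bacteria = subset_samples(cohort$bacteria, md$sample_id),
                 fungi = subset_samples(cohort$fungi, md$sample_id),
                 metadata = md, pairs = pairs),
            class = "paired_cohort")
}

#' Exclude pairs with insufficient bacterial sequencing depth
#'
#' A pair is removed — both samples, both kingdoms — when either member's
#' total bacterial read count is strictly below `min_reads` (default 50
#' reads). Filtering on the bacterial library only, and removing the whole
#' pair, preserves the paired design. The removal log is attached as
#' attribute `"removed_pairs"`.
#'
#' @param cohort a [build_cohort()] result.
#' @param min_reads minimum bacterial reads per sample (default 50).
#' @return the filtered `paired_cohort`; removed pairs in
#'   `attr(, "removed_pairs")`.
#' @export
filter_low_depth_pairs <- function(cohort, min_reads = 50) {
  stopifnot(is_paired_cohort(cohort), is_count(min_reads))
  totals <- colSums(cohort$bacteria$counts)
  tt <- totals[cohort$pairs$tumor]
  nt <- totals[cohort$pairs$nontumor]
  removed <- tt < min_reads | nt < min_reads
  log <- data.frame(patient_id = cohort$pairs$patient_id,
                    tumor_reads = as.numeric(tt),
                    nontumor_reads = as.numeric(nt),
                    stringsAsFactors = FALSE)[removed, , drop = FALSE]
  rownames(log) <- NULL
  if (all(removed))
    stop2("all pairs removed at min_reads=", min_reads)
  if (any(removed))
    log_msg("filter", nrow(log), " pair(s) removed (<", min_reads,
            " bacterial reads): ", paste(log$patient_id, collapse = ", "))
  out <- subset_cohort(cohort, cohort$pairs$patient_id[!removed])
  out$bacteria <- drop_empty_taxa(out$bacteria)
  out$fungi <- drop_empty_taxa(out$fungi)
  attr(out, "removed_pairs") <- log
  out
}

#' Merge the two kingdoms into one genus-level feature matrix
#'
#' Both tables are aggregated to genus and converted to relative abundance
#' per kingdom (bacterial and fungal reads come from separate amplicon
#' libraries with incomparable depths), then the columns are concatenated
#' into a samples-by-genera matrix whose column names are prefixed with the
#' kingdom. Joint normalization over the pooled counts is available via
#' `joint = TRUE`.
#'
#' @param cohort a `paired_cohort` (any rank at or below genus).
#' @param joint normalize over the pooled two-kingdom counts instead.
#' @return list with `features` (samples x genera proportion matrix) and
#'   `lineage` (data.frame describing each feature column).
#' @export
merge_genus_tables <- function(cohort, joint = FALSE) {
  stopifnot(is_paired_cohort(cohort))
  b <- aggregate_to_rank(cohort$bacteria, "genus")
  f <- aggregate_to_rank(cohort$fungi, "genus")
  if (!identical(sort(sample_ids(b)), sort(sample_ids(f))))
    stop2("sample sets differ between kingdoms")
  ids <- cohort$metadata$sample_id
  b <- subset_samples(b, ids)
  f <- subset_samples(f, ids)
  if (joint) {
    pooled <- rbind(b$counts, f$counts)
    pooled <- sweep(pooled, 2, colSums(pooled), "/")
    bp <- pooled[seq_len(nrow(b$counts)), , drop = FALSE]
    fp <- pooled[-seq_len(nrow(b$counts)), , drop = FALSE]
  } else {
    bp <- to_relative_abundance(b)$counts
    fp <- to_relative_abundance(f)$counts
  }
  lineage <- rbind(b$taxa, f$taxa)
  feature <- paste(lineage$kingdom, lineage$genus, sep = ":")
  feature <- make.unique(feature, sep = "#")
  lineage$feature <- feature
  features <- t(rbind(bp, fp))
  colnames(features) <- feature
  rownames(lineage) <- NULL
  list(features = features, lineage = lineage)
}
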