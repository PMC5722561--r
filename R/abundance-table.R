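#' Abundance tables
#'
#' An `abundance_table` holds a taxon-by-sample matrix of non-negative
#' integer counts together with the taxonomic lineage of each row. It is the
#' universal input of the pipeline: one table per kingdom (bacteria or
#' fungi), at a stated row granularity (`rank`). Relative-abundance tables
#' produced by [to_relative_abundance()] carry the same structure with
#' real-valued proportions (`values = "proportions"`).
#'
#' @param taxa data.frame with columns `taxon_id`, `kingdom`, `phylum` and,
#'   depending on `rank`, `genus` and optionally `species`. `taxon_id` must
#'   be unique; `kingdom` must be a single value, `"bacteria"` or `"fungi"`.
#' @param counts numeric matrix, one row per taxon, one column per sample;
#'   non-negative, and integral when `values = "counts"`.
#' @param rank row granularity: `"otu"`, `"species"`, `"genus"` or
#'   `"phylum"`.
#' @param values `"counts"` (default) or `"proportions"`.
#' @return an object of class `abundance_table`: a list with elements
#'   `taxa`, `counts`, `rank`, `values`.
#' @export
abundance_table <- function(taxa, counts, rank = "genus", values = "counts") {
  rank <- match.arg(rank, TAXON_RANKS)
  values <- match.arg(values, c("counts", "proportions"))
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"

  if (!all(c("taxon_id", "kingdom", "phylum") %in% names(taxa)))
    stop2("'taxa' needs columns taxon_id, kingdom, phylum")
  if (!"genus" %in% names(taxa)) taxa$genus <- NA_character_
  if (!"species" %in% names(taxa)) taxa$species <- NA_character_
  taxa <- taxa[c("taxon_id", "kingdom", "phylum", "genus", "species")]

  if (anyDuplicated(taxa$taxon_id))
    stop2("duplicate taxon_id: ",
          paste(unique(taxa$taxon_id[duplicated(taxa$taxon_id)]), collapse = ", "))
  bad_k <- setdiff(unique(taxa$kingdom), KINGDOMS)
  if (length(bad_k))
    stop2("unknown kingdom value(s): ", paste(bad_k, collapse = ", "))
  if (any(is.na(taxa$phylum) | taxa$phylum == ""))
    stop2("empty phylum in lineage")
  if (rank %in% c("otu", "species", "genus") &&
      any(is.na(taxa$genus) | taxa$genus == ""))
    stop2("empty genus in lineage at rank ", rank)

  if (nrow(counts) != nrow(taxa))
    stop2("counts has ", nrow(counts), " rows but taxa describes ", nrow(taxa))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop2("counts must be finite and non-negative")
  if (values == "counts" && any(counts != round(counts)))
    stop2("counts must be integral")
  if (is.null(colnames(counts)))
    stop2("counts must carry sample IDs as column names")
  if (anyDuplicated(colnames(counts)))
    stop2("duplicate sample IDs: ",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  rownames(counts) <- taxa$taxon_id

  structure(list(taxa = taxa, counts = counts, rank = rank, values = values),
            class = "abundance_table")
}

TAXON_RANKS <- c("otu", "species", "genus", "phylum")  # fine -> coarse
KINGDOMS <- c("bacteria", "fungi")

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa x %d samples, rank=%s, %s\n",
              nrow(x$counts), ncol(x$counts), x$rank, x$values))
  invisible(x)
}

#' @rdname abundance_table
#' @param x object to test.
#' @export
is_abundance_table <- function(x) inherits(x, "abundance_table")

sample_ids <- function(table) colnames(table$counts)

#' Read an abundance table from TSV
#'
#' The expected layout is one row per taxon: lineage columns (`taxon_id`
#' optional, then `kingdom`, `phylum`, `genus`, optionally `species`)
#' followed by one integer column per sample. Tab-separated, UTF-8, lines
#' starting with `#` are ignored. Row and column order are preserved.
#'
#' @param path file path.
#' @param kingdom if given, checked against the file's kingdom column.
#' @param rank row granularity recorded on the returned table.
#' @return an [abundance_table()].
#' @export
read_abundance_tsv <- function(path, kingdom = NULL, rank = "genus") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  lineage_cols <- intersect(c("taxon_id", "kingdom", "phylum", "genus", "species"),
                            names(df))
  if (!all(c("kingdom", "phylum") %in% lineage_cols))
    stop2("malformed header in ", path,
          ": need lineage columns kingdom, phylum (got: ",
          paste(names(df), collapse = ", "), ")")
  sample_cols <- setdiff(names(df), lineage_cols)
  if (!length(sample_cols))
    stop2("no sample columns found in ", path)
  if (anyDuplicated(sample_cols))
    stop2("duplicate sample IDs in header of ", path, ": ",
          paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", "))

  counts <- matrix(NA_real_, nrow(df), length(sample_cols),
                   dimnames = list(NULL, sample_cols))
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(df[[sample_cols[j]]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop2("non-numeric or negative count in ", path,
            ", sample '", sample_cols[j], "', taxon row ", bad[1],
            " (value '", df[[sample_cols[j]]][bad[1]], "')")
    counts[, j] <- v
  }

  taxa <- df[lineage_cols]
  if (!"taxon_id" %in% names(taxa)) {
    parts <- taxa[intersect(c("kingdom", "phylum", "genus", "species"), names(taxa))]
    taxa$taxon_id <- do.call(paste, c(parts, sep = "|"))
  }
  taxa[taxa == ""] <- NA_character_
  if (!is.null(kingdom)) {
    kingdom <- match.arg(kingdom, KINGDOMS)
    if (!all(taxa$kingdom == kingdom))
      stop2(path, " contains kingdom values other than '", kingdom, "'")
  }
  abundance_table(taxa, counts, rank = rank)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_tsv()]: the written file reads back to an
#' identical table.
#'
#' @param table an [abundance_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(table, path) {
  stopifnot(is_abundance_table(table))
  taxa <- table$taxa
  taxa[is.na(taxa)] <- ""
  df <- cbind(taxa, as.data.frame(table$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

rank_index <- function(rank) match(rank, TAXON_RANKS)

#' Aggregate an abundance table to a coarser rank
#'
#' Rows sharing the same lineage at the requested rank are summed. Per-sample
#' totals are conserved exactly (integer arithmetic).
#'
#' @param table an [abundance_table()].
#' @param rank target rank, coarser than or equal to `table$rank`.
#' @return an [abundance_table()] at the requested rank.
#' @export
aggregate_to_rank <- function(table, rank) {
  stopifnot(is_abundance_table(table))
  rank <- match.arg(rank, TAXON_RANKS)
  if (rank_index(rank) < rank_index(table$rank))
    stop2("cannot aggregate from rank '", table$rank,
          "' to finer rank '", rank, "'")
  if (rank == table$rank) return(table)

  key_cols <- switch(rank,
                     species = c("kingdom", "phylum", "genus", "species"),
                     genus = c("kingdom", "phylum", "genus"),
                     phylum = c("kingdom", "phylum"))
  key <- do.call(paste, c(table$taxa[key_cols], sep = "|"))
  keep <- !duplicated(key)
  counts <- rowsum(table$counts, group = key, reorder = FALSE)
  taxa <- table$taxa[keep, , drop = FALSE]
  taxa$taxon_id <- key[keep]
  if (rank == "phylum") taxa$genus <- NA_character_
  if (rank %in% c("genus", "phylum")) taxa$species <- NA_character_
  counts <- counts[taxa$taxon_id, , drop = FALSE]
  abundance_table(taxa, counts, rank = rank, values = table$values)
}

#' Convert counts to within-sample relative abundances
#'
#' Each sample (column) is divided by its total so columns sum to 1.
#'
#' @param table an [abundance_table()] of counts.
#' @return an [abundance_table()] with `values = "proportions"`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(is_abundance_table(table))
  totals <- colSums(table$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stop2("zero-total sample(s): ", paste(zero, collapse = ", "),
          " — remove before normalizing")
  props <- sweep(table$counts, 2, totals, "/")
  abundance_table(table$taxa, props, rank = table$rank, values = "proportions")
}

#' Drop taxa with zero total count
#' @param table an [abundance_table()].
#' @return the table without all-zero rows; dropped IDs are messaged.
#' @export
drop_empty_taxa <- function(table) {
  stopifnot(is_abundance_table(table))
  keep <- rowSums(table$counts) > 0
  if (all(keep)) return(table)
  log_msg("core", sum(!keep), " zero-total taxa dropped (",
          table$taxa$kingdom[1], ", rank ", table$rank, ")")
  abundance_table(table$taxa[keep, , drop = FALSE],
                  table$counts[keep, , drop = FALSE],
                  rank = table$rank, values = table$values)
}

subset_samples <- function(table, ids) {
  missing <- setdiff(ids, sample_ids(table))
  if (length(missing))
    stop2("samples absent from table: ", paste(missing, collapse = ", "))
  abundance_table(table$taxa, table$counts[, ids, drop = FALSE],
                  rank = table$rank, values = table$values)
}
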