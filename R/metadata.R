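#' Sample metadata
#'
#' Metadata is a data.frame with one row per sample: `sample_id`,
#' `patient_id`, `tissue` (`"tumor"` or `"nontumor"`), and optional clinical
#' covariates `t_stage` (`"low"` = T1-T2, `"high"` = T3-T4), `n_stage`
#' (`"negative"`, `"positive"`), `smoking` (`"current"`, `"past"`,
#' `"never"`), `age` (years) and `sex`. Unknown values are stored as `NA`
#' (empty string on disk); samples with an unknown grouping variable are
#' excluded from that grouping's analysis only.
#'
#' @param df data.frame with at least `sample_id`, `patient_id`, `tissue`.
#' @return validated, normalized metadata data.frame.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue")
  if (!all(need %in% names(df)))
    stop2("metadata needs columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$sample_id))
    stop2("duplicate sample_id in metadata: ",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))

  df$tissue <- normalize_enum(df$tissue, "tissue", list(
    tumor = c("tumor", "tt"),
    nontumor = c("nontumor", "non-tumor", "non_tumor", "normal", "ntt")),
    allow_na = FALSE)
  key <- paste(df$patient_id, df$tissue)
  if (anyDuplicated(key))
    stop2("duplicate (patient_id, tissue): ",
          paste(unique(key[duplicated(key)]), collapse = "; "))

  if (!is.null(df$t_stage))
    df$t_stage <- normalize_enum(df$t_stage, "t_stage", list(
      low = c("low", "t1", "t2", "t1-t2"),
      high = c("high", "t3", "t4", "t3-t4")))
  if (!is.null(df$n_stage))
    df$n_stage <- normalize_enum(df$n_stage, "n_stage", list(
      negative = c("negative", "n0"),
      positive = c("positive", "n1", "n2", "n1-n2")))
  if (!is.null(df$smoking))
    df$smoking <- normalize_enum(df$smoking, "smoking",
                                 list(current = "current", past = "past",
                                      never = "never"))
  if (!is.null(df$sex))
    df$sex <- normalize_enum(df$sex, "sex",
                             list(male = c("male", "m"), female = c("female", "f")))
  if (!is.null(df$age)) df$age <- suppressWarnings(as.numeric(df$age))
  rownames(df) <- NULL
  df
}

normalize_enum <- function(x, field, levels_map, allow_na = TRUE) {
  x <- trimws(tolower(as.character(x)))
  x[x == ""] <- NA_character_
  out <- rep(NA_character_, length(x))
  for (lv in names(levels_map)) out[x %in% levels_map[[lv]]] <- lv
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop2("unknown ", field, " value(s): ",
          paste(unique(x[bad]), collapse = ", "))
  if (!allow_na && anyNA(out)) stop2("missing ", field, " value")
  out
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `patient_id`, `tissue`; optional covariate
#' columns as in [sample_metadata()]. Values are case-normalized; empty
#' cells become `NA` (unknown).
#'
#' @param path file path.
#' @return validated metadata data.frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Write sample metadata to TSV
#' @param metadata validated metadata data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata_tsv <- function(metadata, path) {
  out <- metadata
  out[] <- lapply(out, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
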