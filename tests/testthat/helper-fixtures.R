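# Fixtures built in code; nothing on disk.

mk_taxa <- function(kingdom, genera, phyla = rep("p1", length(genera)),
                    species = NA_character_) {
  data.frame(taxon_id = genera, kingdom = rep(kingdom, length(genera)),
             phylum = phyla, genus = genera,
             species = rep(species, length.out = length(genera)),
             stringsAsFactors = FALSE)
}

# small handmade 2-kingdom cohort; counts_b/counts_f are taxa x samples with
# sample columns named <patient>_T / <patient>_N
mk_cohort <- function(counts_b, counts_f, t_stage = NULL) {
  patients <- unique(sub("_[TN]$", "", colnames(counts_b)))
  md <- data.frame(
    sample_id = colnames(counts_b),
    patient_id = sub("_[TN]$", "", colnames(counts_b)),
    tissue = ifelse(grepl("_T$", colnames(counts_b)), "tumor", "nontumor"),
    stringsAsFactors = FALSE)
  if (!is.null(t_stage)) md$t_stage <- t_stage[md$patient_id]
  b <- abundance_table(mk_taxa("bacteria", rownames(counts_b),
                               phyla = attr(counts_b, "phyla") %||%
                                 rep("bp1", nrow(counts_b))),
                       counts_b, rank = "genus")
  f <- abundance_table(mk_taxa("fungi", rownames(counts_f),
                               phyla = attr(counts_f, "phyla") %||%
                                 rep("fp1", nrow(counts_f))),
                       counts_f, rank = "genus")
  suppressMessages(build_cohort(b, f, md))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

named_mat <- function(data, taxa, samples) {
  matrix(data, length(taxa), length(samples),
         dimnames = list(taxa, samples))
}

# two-class Gaussian feature data for the RF layer
gauss_data <- function(n = 40, p = 112, n_informative = 0, shift = 0,
                       seed = 1) {
  set.seed(seed)
  y <- rep(c("nontumor", "tumor"), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  if (n_informative > 0)
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
      ifelse(y == "tumor", shift / 2, -shift / 2)
  list(x = x, y = y)
}

fake_rf_fit <- function(votes) {
  structure(list(votes = votes, oob_error = NA_real_,
                 importance = NULL, labels = NULL, positive = "tumor",
                 config = rf_config()),
            class = "rf_fit")
}

# default simulated cohort, computed once per test run
.sim_memo <- new.env(parent = emptyenv())
default_sim <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.sim_memo[[key]]))
    .sim_memo[[key]] <- suppressMessages(
      simulate_cohort(generator_config(seed = seed)))
  .sim_memo[[key]]
}
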