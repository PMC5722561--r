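#' Configuration for the paired-cohort simulator
#'
#' The generator emulates a paired oral tumor/non-tumor two-kingdom amplicon
#' study: matched tumor and adjacent-normal samples from each patient, a
#' bacteriome of 25 phyla / 90 genera and a mycobiome of 7 phyla / 22 genera
#' (112 genus features in total), tumor libraries systematically shallower
#' than non-tumor libraries, planted tumor-vs-normal compositional shifts,
#' and a tunable "field effect" that moves the normal-tissue composition of
#' high-T-stage patients toward their tumor composition.
#'
#' Counts are drawn Dirichlet-multinomial: expected compositions are built
#' on the log scale (shared baseline + patient offset + planted effects),
#' softmax-normalized, overdispersed by a Dirichlet draw with concentration
#' `overdispersion`, and sampled multinomially at a log-normally drawn
#' library depth.
#'
#' @param n_patients number of matched pairs (default 39).
#' @param n_bacterial_phyla,n_fungal_phyla phylum counts (25, 7).
#' @param n_bacterial_genera,n_fungal_genera genus counts (90, 22; total 112).
#' @param planted_effects data.frame with columns `kingdom`, `genus`
#'   (abundance-rank index within kingdom) and `log2fc` (tumor vs normal).
#'   The default plants a 10-genus signal led by a doubling of the dominant
#'   bacterial genus, concentrating tumor compositions onto fewer genera.
#' @param frac_high_tstage fraction of patients with high (T3-T4) disease.
#' @param field_attenuation_high in `[0,1]`: the normal-sample expected
#'   composition of high-T-stage patients is moved to
#'   `tumor + (1 - field_attenuation_high) * (normal - tumor)` on the log
#'   scale, so 0 leaves pairs untouched and 1 makes the pair difference pure
#'   sampling noise.
#' @param depth list of per-kingdom, per-tissue log-normal depth parameters
#'   (`median` reads and `sdlog`); defaults match a cohort whose tumor
#'   libraries are markedly shallower and more variable than the non-tumor
#'   ones (bacteria medians 6294 vs 13561 reads).
#' @param overdispersion Dirichlet concentration (larger = less dispersed).
#' @param patient_effect_sd log-scale SD of patient-level composition
#'   offsets.
#' @param covarying_pairs optional data.frame (`kingdom`, `genus1`,
#'   `genus2`, `sd`): each row adds a shared per-sample latent log-normal
#'   factor to both genera, planting a positive abundance correlation.
#' @param seed master seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 39,
                             n_bacterial_phyla = 25, n_fungal_phyla = 7,
                             n_bacterial_genera = 90, n_fungal_genera = 22,
                             planted_effects = default_planted_effects(),
                             frac_high_tstage = 0.54,
                             field_attenuation_high = 0.3,
                             depth = default_depth_model(),
                             overdispersion = 150,
                             patient_effect_sd = 0.7,
                             covarying_pairs = NULL,
                             seed = 1) {
  cfg <- list(n_patients = n_patients,
              n_bacterial_phyla = n_bacterial_phyla,
              n_fungal_phyla = n_fungal_phyla,
              n_bacterial_genera = n_bacterial_genera,
              n_fungal_genera = n_fungal_genera,
              planted_effects = planted_effects,
              frac_high_tstage = frac_high_tstage,
              field_attenuation_high = field_attenuation_high,
              depth = depth,
              overdispersion = overdispersion,
              patient_effect_sd = patient_effect_sd,
              covarying_pairs = covarying_pairs,
              seed = seed)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

default_planted_effects <- function() {
  data.frame(
    kingdom = c(rep("bacteria", 8), "fungi", "fungi"),
    genus = c(1, 2, 3, 5, 8, 13, 21, 34, 1, 3),
    log2fc = c(1, -1, -1, 1, -1.5, 1.5, -1.5, 2, -1, 1),
    stringsAsFactors = FALSE)
}

default_depth_model <- function() {
  list(bacteria = list(nontumor = c(median = 13561, sdlog = 0.586),
                       tumor = c(median = 6294, sdlog = 2.20)),
       fungi = list(nontumor = c(median = 3482, sdlog = 1.052),
                    tumor = c(median = 1806, sdlog = 1.158)))
}

validate_generator_config <- function(cfg) {
  stopifnot(is_count(cfg$n_patients), cfg$n_patients >= 2,
            is_count(cfg$n_bacterial_phyla), cfg$n_bacterial_phyla >= 1,
            is_count(cfg$n_fungal_phyla), cfg$n_fungal_phyla >= 1,
            is_count(cfg$n_bacterial_genera), is_count(cfg$n_fungal_genera))
  if (cfg$n_bacterial_genera < cfg$n_bacterial_phyla ||
      cfg$n_fungal_genera < cfg$n_fungal_phyla)
    stop2("each phylum needs at least one genus")
  if (cfg$field_attenuation_high < 0 || cfg$field_attenuation_high > 1)
    stop2("field_attenuation_high must lie in [0, 1]")
  if (!is.numeric(cfg$overdispersion) || cfg$overdispersion <= 0)
    stop2("overdispersion (Dirichlet concentration) must be > 0")
  if (cfg$frac_high_tstage < 0 || cfg$frac_high_tstage > 1)
    stop2("frac_high_tstage must lie in [0, 1]")
  pe <- cfg$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    stopifnot(all(pe$kingdom %in% KINGDOMS))
    gmax <- ifelse(pe$kingdom == "bacteria",
                   cfg$n_bacterial_genera, cfg$n_fungal_genera)
    if (any(pe$genus < 1 | pe$genus > gmax))
      stop2("planted_effects genus index out of range")
  }
  for (d in unlist(cfg$depth, recursive = FALSE))
    if (d[["median"]] <= 0 || d[["sdlog"]] < 0) stop2("invalid depth model")
  invisible(cfg)
}

#' Draw the two-kingdom taxonomy
#'
#' Genera are partitioned among phyla by a stick-breaking scheme in which
#' every phylum keeps at least one genus; genus index 1 is the most abundant
#' genus of its kingdom under the simulator's baseline composition.
#'
#' @param config a [generator_config()].
#' @param seed seed (defaults to the config's master seed).
#' @return list with `bacteria` and `fungi` lineage data.frames.
#' @export
make_taxonomy <- function(config, seed = config$seed) {
  with_seed(derive_seed(seed, "taxonomy"), {
    list(bacteria = one_kingdom_taxonomy("bacteria", config$n_bacterial_phyla,
                                         config$n_bacterial_genera),
         fungi = one_kingdom_taxonomy("fungi", config$n_fungal_phyla,
                                      config$n_fungal_genera))
  })
}

one_kingdom_taxonomy <- function(kingdom, n_phyla, n_genera) {
  if (n_phyla > n_genera) stop2("more phyla than genera for ", kingdom)
  pre <- substr(kingdom, 1, 3)
  phyla <- sprintf("%s_p%02d", pre, seq_len(n_phyla))
  genera <- sprintf("%s_g%03d", pre, seq_len(n_genera))
  # stick-breaking phylum sizes: each phylum seeded with one genus, the rest
  # allocated by sorted exponential stick weights
  w <- sort(stats::rexp(n_phyla), decreasing = TRUE)
  w <- w / sum(w)
  extra <- n_genera - n_phyla
  assign <- c(seq_len(n_phyla),
              if (extra > 0) sample(seq_len(n_phyla), extra,
                                    replace = TRUE, prob = w))
  assign <- sample(assign)  # decouple phylum from abundance rank
  data.frame(taxon_id = genera, kingdom = kingdom, phylum = phyla[assign],
             genus = genera, species = NA_character_,
             stringsAsFactors = FALSE)
}

#' Build a rooted genus tree nesting genera within phyla
#'
#' Leaves are the lineage's taxon IDs; each phylum forms a clade (singleton
#' phyla attach directly at the root); all branch lengths are positive.
#'
#' @param lineages a lineage data.frame (one kingdom) as produced by
#'   [make_taxonomy()].
#' @param seed seed controlling branch lengths.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
make_tree <- function(lineages, seed = 1) {
  if (nrow(lineages) < 2) stop2("need at least 2 leaves for a tree")
  if (anyDuplicated(lineages$taxon_id))
    stop2("duplicate leaf names: ",
          paste(unique(lineages$taxon_id[duplicated(lineages$taxon_id)]),
                collapse = ", "))
  with_seed(derive_seed(seed, "tree", lineages$kingdom[1]), {
    bl <- function(n) round(stats::runif(n, 0.2, 1), 4)
    clades <- vapply(split(lineages$taxon_id, lineages$phylum),
                     function(leaves) {
                       if (length(leaves) == 1)
                         return(paste0(leaves, ":", bl(1)))
                       inner <- paste0(leaves, ":", bl(length(leaves)),
                                       collapse = ",")
                       paste0("(", inner, "):", bl(1))
                     }, character(1))
    if (length(clades) == 1)
      newick <- paste0(sub(":[0-9.]+$", ";", clades))
    else
      newick <- paste0("(", paste(clades, collapse = ","), ");")
    ape::read.tree(text = newick)
  })
}

#' Simulate a paired two-kingdom cohort with known ground truth
#'
#' For each patient a log-scale composition offset (SD
#' `patient_effect_sd`) perturbs a shared baseline; the tumor expected
#' composition is additionally shifted by the planted log2 fold-changes; for
#' high-T-stage patients the normal composition is interpolated toward the
#' tumor composition by `field_attenuation_high` (field effect). Counts are
#' Dirichlet-multinomial at tissue-specific log-normal depths, so column
#' sums equal the drawn depths exactly and the whole cohort is reproducible
#' bit-for-bit under a fixed seed.
#'
#' @param config a [generator_config()].
#' @return list with elements `cohort` (a `paired_cohort`), `truth` (planted
#'   log2 fold-changes by feature, per-patient T-stage and attenuation, and
#'   the expected differential feature set), and `trees` (per-kingdom rooted
#'   genus trees).
#' @export
simulate_cohort <- function(config) {
  validate_generator_config(config)
  tax <- make_taxonomy(config)
  trees <- list(bacteria = make_tree(tax$bacteria, seed = config$seed),
                fungi = make_tree(tax$fungi, seed = config$seed))
  n <- config$n_patients
  patients <- sprintf("pt%03d", seq_len(n))

  with_seed(derive_seed(config$seed, "cohort"), {
    n_high <- round(config$frac_high_tstage * n)
    t_stage <- rep("low", n)
    t_stage[sample.int(n, n_high)] <- "high"
    n_stage <- sample(c("negative", "positive"), n, replace = TRUE,
                      prob = c(0.514, 0.486))
    smoking <- sample(c("current", "past", "never"), n, replace = TRUE,
                      prob = c(0.179, 0.487, 0.334))
    age <- round(stats::rnorm(n, 60.5, 13.2))
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.77, 0.23))

    kingdoms <- list(
      bacteria = list(tax = tax$bacteria, decay = 1.05,
                      G = config$n_bacterial_genera),
      fungi = list(tax = tax$fungi, decay = 0.9,
                   G = config$n_fungal_genera))
    base_log <- lapply(kingdoms, function(k) -k$decay * log(seq_len(k$G)))
    fc <- lapply(kingdoms, function(k) numeric(k$G))
    pe <- config$planted_effects
    if (!is.null(pe))
      for (i in seq_len(NROW(pe)))
        fc[[pe$kingdom[i]]][pe$genus[i]] <- pe$log2fc[i]

    samples_t <- paste0(patients, "_T")
    samples_n <- paste0(patients, "_N")
    ids <- c(rbind(samples_t, samples_n))
    counts <- lapply(kingdoms, function(k)
      matrix(0, k$G, 2 * n, dimnames = list(k$tax$taxon_id, ids)))

    one_sample <- function(logp, kingdom, tissue) {
      cp <- config$covarying_pairs
      if (!is.null(cp))
        for (i in seq_len(NROW(cp)))
          if (cp$kingdom[i] == kingdom) {
            z <- stats::rnorm(1, 0, cp$sd[i])
            logp[c(cp$genus1[i], cp$genus2[i])] <-
              logp[c(cp$genus1[i], cp$genus2[i])] + z
          }
      p <- exp(logp - max(logp))
      p <- p / sum(p)
      dp <- config$depth[[kingdom]][[tissue]]
      depth <- max(1, round(stats::rlnorm(1, log(dp[["median"]]), dp[["sdlog"]])))
      g <- stats::rgamma(length(p), shape = config$overdispersion * p)
      g[g <= 0 | !is.finite(g)] <- 1e-12
      stats::rmultinom(1, depth, g / sum(g))[, 1]
    }

    for (i in seq_len(n)) {
      for (kd in names(kingdoms)) {
        offset <- stats::rnorm(kingdoms[[kd]]$G, 0, config$patient_effect_sd)
        normal_log <- base_log[[kd]] + offset
        tumor_log <- normal_log + log(2) * fc[[kd]]
        if (t_stage[i] == "high")
          normal_log <- tumor_log +
            (1 - config$field_attenuation_high) * (normal_log - tumor_log)
        counts[[kd]][, samples_t[i]] <- one_sample(tumor_log, kd, "tumor")
        counts[[kd]][, samples_n[i]] <- one_sample(normal_log, kd, "nontumor")
      }
    }

    metadata <- sample_metadata(data.frame(
      sample_id = ids,
      patient_id = rep(patients, each = 2),
      tissue = rep(c("tumor", "nontumor"), n),
      t_stage = rep(t_stage, each = 2),
      n_stage = rep(n_stage, each = 2),
      smoking = rep(smoking, each = 2),
      age = rep(age, each = 2),
      sex = rep(sex, each = 2),
      stringsAsFactors = FALSE))

    cohort <- build_cohort(
      abundance_table(tax$bacteria, counts$bacteria, rank = "genus"),
      abundance_table(tax$fungi, counts$fungi, rank = "genus"),
      metadata)

    fc_named <- c(stats::setNames(fc$bacteria,
                                  paste0("bacteria:", tax$bacteria$genus)),
                  stats::setNames(fc$fungi,
                                  paste0("fungi:", tax$fungi$genus)))
    truth <- list(
      log2fc = fc_named,
      differential_features = names(fc_named)[fc_named != 0],
      t_stage = stats::setNames(t_stage, patients),
      attenuation = stats::setNames(
        ifelse(t_stage == "high", config$field_attenuation_high, 0), patients),
      seed = config$seed)

    list(cohort = cohort, truth = truth, trees = trees)
  })
}

#' Deterministically subsample a cohort for fast worked examples
#'
#' Picks `n_patients` pairs (and optionally a total of `n_genera` genus
#' rows, split across kingdoms in proportion to their sizes) under a fixed
#' seed, preserving the pairing.
#'
#' @param cohort a `paired_cohort`.
#' @param n_patients pairs to keep (at least 2).
#' @param n_genera optional total number of genus rows to keep.
#' @param seed subsampling seed.
#' @return the subsampled `paired_cohort`.
#' @export
degrade_to_worked_example <- function(cohort, n_patients, n_genera = NULL,
                                      seed = 1) {
  stopifnot(is_paired_cohort(cohort))
  if (n_patients < 2) stop2("need at least 2 pairs")
  if (n_patients > nrow(cohort$pairs))
    stop2("requested more pairs than the cohort holds")
  with_seed(derive_seed(seed, "degrade"), {
    keep <- sort(sample(cohort$pairs$patient_id, n_patients))
    out <- subset_cohort(cohort, keep)
    if (!is.null(n_genera)) {
      gb <- nrow(out$bacteria$counts)
      gf <- nrow(out$fungi$counts)
      if (n_genera > gb + gf) stop2("requested more genera than available")
      nb <- max(1, min(gb, round(n_genera * gb / (gb + gf))))
      nf <- n_genera - nb
      pick <- function(tab, k) {
        rows <- sort(sample.int(nrow(tab$counts), k))
        abundance_table(tab$taxa[rows, , drop = FALSE],
                        tab$counts[rows, , drop = FALSE],
                        rank = tab$rank, values = tab$values)
      }
      out$bacteria <- pick(out$bacteria, nb)
      out$fungi <- pick(out$fungi, nf)
    }
    out
  })
}

#' Write a simulated cohort and its ground truth to a directory
#'
#' Emits `bacteria.tsv`, `fungi.tsv`, `metadata.tsv`, per-kingdom newick
#' trees and `truth.json`.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_tsv(sim$cohort$bacteria, file.path(dir, "bacteria.tsv"))
  write_abundance_tsv(sim$cohort$fungi, file.path(dir, "fungi.tsv"))
  write_metadata_tsv(sim$cohort$metadata, file.path(dir, "metadata.tsv"))
  ape::write.tree(sim$trees$bacteria, file.path(dir, "tree_bacteria.nwk"))
  ape::write.tree(sim$trees$fungi, file.path(dir, "tree_fungi.nwk"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
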