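#' Pipeline configuration
#'
#' Bundles input locations (or a generator configuration), the output
#' directory, stage toggles, thresholds and the random-forest settings for
#' [run_pipeline()]. Exactly one of `generator` or the three file paths
#' (`bacteria`, `fungi`, `metadata`) must be supplied.
#'
#' @param out_dir output directory for all artifacts.
#' @param bacteria,fungi,metadata input TSV paths (see
#'   [read_abundance_tsv()], [read_metadata_tsv()]).
#' @param tree_bacteria,tree_fungi optional newick paths enabling
#'   unweighted-UniFrac ordination.
#' @param generator optional [generator_config()]; when given, the cohort
#'   is simulated instead of read.
#' @param seed master seed for every stochastic stage.
#' @param min_reads bacterial read-depth pair filter threshold (default 50).
#' @param alpha significance threshold for reporting (default 0.05).
#' @param rf an [rf_config()].
#' @param correlation_rank rank for the correlation screens (default
#'   `"phylum"`; genus-level screens test thousands of pairs).
#' @param stages character vector of stages to run, in pipeline order.
#' @param importance_null run the label-permutation importance null.
#' @param selection_in_bootstrap run backward selection inside each
#'   bootstrap resample (slow; the full-data selection always runs).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            bacteria = NULL, fungi = NULL, metadata = NULL,
                            tree_bacteria = NULL, tree_fungi = NULL,
                            generator = NULL, seed = 1,
                            min_reads = 50, alpha = 0.05,
                            rf = rf_config(seed = seed),
                            correlation_rank = "phylum",
                            stages = c("filter", "diversity", "ordination",
                                       "differential", "correlation", "rf",
                                       "field_effect"),
                            importance_null = FALSE,
                            selection_in_bootstrap = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop2("alpha must lie in (0, 1)")
  have_files <- !is.null(bacteria) && !is.null(fungi) && !is.null(metadata)
  if (is.null(generator) == !have_files)
    stop2("supply either 'generator' or the three input paths")
  structure(list(out_dir = out_dir, bacteria = bacteria, fungi = fungi,
                 metadata = metadata, tree_bacteria = tree_bacteria,
                 tree_fungi = tree_fungi, generator = generator,
                 seed = seed, min_reads = min_reads, alpha = alpha,
                 rf = rf, correlation_rank = correlation_rank,
                 stages = stages, importance_null = importance_null,
                 selection_in_bootstrap = selection_in_bootstrap),
            class = "pipeline_config")
}

#' Run the full paired-microbiome pipeline
#'
#' Stages execute in order: load (or simulate) the cohort; depth-filter
#' pairs; diversity and richness comparisons; Bray-Curtis (and, with trees,
#' unweighted UniFrac) ordination and UPGMA dendrograms; per-taxon
#' differential abundance at phylum and genus rank; correlation screens;
#' the random-forest layer (fit, backward selection, 0.632+ bootstrap); and
#' the vote-fraction-difference field-effect test. Every stage writes its
#' machine-readable artifact under `out_dir`; identical configuration and
#' seed reproduce byte-identical outputs. A stage failure aborts with the
#' stage name, leaving `report.json` marked incomplete.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list), invisibly written as `report.json` and
#'   rendered to `report.md`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  report <- list(
    package = "biomepair",
    version = as.character(utils::packageVersion("biomepair")),
    seed = config$seed,
    parameters = list(min_reads = config$min_reads, alpha = config$alpha,
                      ntree = config$rf$ntree, mtry = config$rf$mtry,
                      n_bootstrap = config$rf$n_bootstrap,
                      drop_fraction = config$rf$drop_fraction),
    stages = list(), warnings = character())
  logs <- character()
  finish <- function(report) {
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    writeLines(logs, out("log.txt"))
    writeLines(render_report(report), out("report.md"))
    report
  }
  run_stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        report$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
        report$complete <<- FALSE
        finish(report)
        stop2("stage '", name, "' failed: ", conditionMessage(e))
      }),
      message = function(m) {
        logs <<- c(logs, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }
  enabled <- function(name) name %in% config$stages
  alpha <- config$alpha

  ## load ------------------------------------------------------------------
  loaded <- run_stage("load", {
    if (!is.null(config$generator)) {
      sim <- simulate_cohort(config$generator)
      jsonlite::write_json(sim$truth, out("truth.json"),
                           auto_unbox = TRUE, digits = NA)
      list(cohort = sim$cohort, trees = sim$trees)
    } else {
      b <- read_abundance_tsv(config$bacteria, kingdom = "bacteria")
      f <- read_abundance_tsv(config$fungi, kingdom = "fungi")
      md <- read_metadata_tsv(config$metadata)
      list(cohort = build_cohort(b, f, md),
           trees = list(
             bacteria = if (!is.null(config$tree_bacteria))
               ape::read.tree(config$tree_bacteria),
             fungi = if (!is.null(config$tree_fungi))
               ape::read.tree(config$tree_fungi)))
    }
  })
  cohort <- loaded$cohort
  trees <- loaded$trees
  report$stages$load <- list(status = "complete",
                             n_pairs = nrow(cohort$pairs),
                             n_samples = nrow(cohort$metadata))

  ## filter ----------------------------------------------------------------
  if (enabled("filter")) {
    cohort <- run_stage("filter",
                        filter_low_depth_pairs(cohort, config$min_reads))
    removed <- attr(cohort, "removed_pairs")
    report$stages$filter <- list(status = "complete",
                                 min_reads = config$min_reads,
                                 n_pairs_removed = nrow(removed),
                                 removed_patients = removed$patient_id,
                                 n_pairs_retained = nrow(cohort$pairs))
  }

  ## diversity -------------------------------------------------------------
  if (enabled("diversity")) {
    div <- run_stage("diversity", {
      tests <- do.call(rbind, lapply(c("phylum", "genus"), function(rk)
        rbind(diversity_comparison(cohort, rk, "shannon"),
              diversity_comparison(cohort, rk, "richness"))))
      per_sample <- do.call(rbind, lapply(c("bacteria", "fungi"), function(kd) {
        d <- sample_diversity(aggregate_to_rank(cohort[[kd]], "genus"))
        cbind(kingdom = kd, d)
      }))
      utils::write.table(tests, out("diversity_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(per_sample, out("diversity_samples.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tests
    })
    report$stages$diversity <- list(
      status = "complete", n_tests = nrow(div),
      significant = sprintf("%s %s %s (p=%.4g)", div$kingdom, div$rank,
                            div$metric, div$p)[div$p < alpha])
  }

  ## ordination ------------------------------------------------------------
  if (enabled("ordination")) {
    run_stage("ordination", {
      for (kd in c("bacteria", "fungi")) {
        tab <- to_relative_abundance(aggregate_to_rank(cohort[[kd]], "genus"))
        bc <- bray_curtis(tab)
        write_distance_tsv(bc, out(paste0("bray_curtis_", kd, ".tsv")))
        pc <- pcoa_ordination(bc, k = 2)
        utils::write.table(
          data.frame(sample_id = rownames(pc$coordinates), pc$coordinates),
          out(paste0("pcoa_", kd, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(upgma_dendrogram(bc)$newick,
                   out(paste0("dendrogram_", kd, ".nwk")))
        if (!is.null(trees[[kd]])) {
          uf <- unweighted_unifrac(cohort[[kd]], trees[[kd]])
          write_distance_tsv(uf, out(paste0("unifrac_", kd, ".tsv")))
        }
      }
    })
    report$stages$ordination <- list(
      status = "complete",
      unifrac = !is.null(trees$bacteria) || !is.null(trees$fungi))
  }

  ## differential ----------------------------------------------------------
  if (enabled("differential")) {
    diff_res <- run_stage("differential", {
      res <- lapply(c("phylum", "genus"), function(rk) {
        r <- per_taxon_differential(cohort, rk, grouping = "tissue")
        utils::write.table(r, out(paste0("differential_", rk, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        r
      })
      names(res) <- c("phylum", "genus")
      res
    })
    sig <- lapply(diff_res, function(r) r[r$p_adj < alpha, , drop = FALSE])
    report$stages$differential <- list(
      status = "complete",
      n_significant_phyla_bacteria = sum(sig$phylum$kingdom == "bacteria"),
      n_significant_phyla_fungi = sum(sig$phylum$kingdom == "fungi"),
      n_significant_genera = nrow(sig$genus),
      top_taxa = utils::head(sig$genus[c("kingdom", "taxon_id", "p_adj",
                                         "direction")], 10))
  }

  ## correlation -----------------------------------------------------------
  if (enabled("correlation")) {
    corr <- run_stage("correlation", {
      combos <- expand.grid(
        tissue = c("nontumor", "tumor"),
        scope = c("intra_bacteria", "intra_fungi", "inter_kingdom"),
        stringsAsFactors = FALSE)
      all <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
        cs <- correlation_screen(cohort, rank = config$correlation_rank,
                                 tissue = combos$tissue[i],
                                 scope = combos$scope[i])
        cbind(tissue = cs$tissue, scope = cs$scope, cs$pairs)
      }))
      utils::write.table(all, out("correlations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      all
    })
    report$stages$correlation <- list(
      status = "complete", rank = config$correlation_rank,
      n_pairs_tested = nrow(corr),
      n_significant = sum(corr$p_adj < alpha, na.rm = TRUE))
  } else {
    report$stages$correlation <- list(status = "skipped")
  }

  ## rf --------------------------------------------------------------------
  fit <- NULL
  if (enabled("rf")) {
    rf_out <- run_stage("rf", {
      merged <- merge_genus_tables(cohort)
      labels <- cohort$metadata$tissue
      fit <- fit_rf(merged$features, labels, config$rf)
      utils::write.table(
        data.frame(sample_id = names(fit$votes), vote_tumor = fit$votes,
                   tissue = labels,
                   predicted = ifelse(fit$votes > 0.5, "tumor", "nontumor")),
        out("rf_votes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(feature = names(fit$importance),
                   mean_decrease_accuracy = fit$importance),
        out("rf_importance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      nullres <- NULL
      if (config$importance_null)
        nullres <- importance_null(merged$features, labels, config$rf)
      sel <- backward_variable_selection(merged$features, labels, config$rf)
      utils::write.table(
        data.frame(size = sel$sizes, oob_error = sel$oob_errors),
        out("rf_selection_curve.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      boot <- bootstrap_632plus(merged$features, labels, config$rf,
                                with_selection = config$selection_in_bootstrap)
      if (!is.null(boot$selection_frequency))
        utils::write.table(
          data.frame(feature = names(boot$selection_frequency),
                     selection_frequency = boot$selection_frequency),
          out("rf_selection_frequency.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      summary <- list(
        n_features = ncol(merged$features),
        oob_error = fit$oob_error,
        selected_size = sel$selected_size,
        selected_vars = sel$selected_vars,
        oob_error_selected = sel$oob_errors[sel$sizes == sel$selected_size],
        err_bar = boot$err_bar, err1 = boot$err1, gamma = boot$gamma,
        R = boot$R, w = boot$w, err_632plus = boot$err_632plus,
        importance_null_rank1_observed =
          if (!is.null(nullres)) nullres$observed[1],
        importance_null_rank1_null_mean =
          if (!is.null(nullres)) nullres$null_mean[1])
      jsonlite::write_json(summary, out("rf_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      c(summary, list(fit = fit))
    })
    fit <- rf_out$fit
    report$stages$rf <- c(list(status = "complete"),
                          rf_out[c("n_features", "oob_error", "selected_size",
                                   "err_bar", "err1", "gamma",
                                   "err_632plus")])
  }

  ## field effect ----------------------------------------------------------
  if (enabled("field_effect") && !is.null(fit)) {
    fe <- run_stage("field_effect", {
      vd <- vote_fraction_differences(fit, cohort)
      utils::write.table(vd, out("vote_differences.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ft <- field_effect_test(vd, grouping = "t_stage")
      jsonlite::write_json(
        list(grouping = ft$grouping, means = as.list(ft$means),
             statistic = ft$statistic, p_value = ft$p_value,
             direction = ft$direction,
             mean_d = mean(vd$d),
             frac_correct_direction = mean(vd$correct_direction)),
        out("field_effect.json"), auto_unbox = TRUE, digits = NA)
      list(vd = vd, ft = ft)
    })
    report$stages$field_effect <- list(
      status = "complete",
      mean_d = mean(fe$vd$d),
      frac_correct_direction = mean(fe$vd$correct_direction),
      group_means = as.list(fe$ft$means),
      p_value = fe$ft$p_value,
      direction = fe$ft$direction)
  }

  report$complete <- TRUE
  invisible(finish(report))
}

#' Render a run report as markdown
#'
#' Sections mirror the analysis order: cohort, diversity, ordination,
#' differential abundance, correlations, random forest, field effect.
#' Skipped stages appear with a skipped marker. Rendering is deterministic
#' under a fixed report.
#'
#' @param report a [run_pipeline()] report list.
#' @return character vector of markdown lines.
#' @export
render_report <- function(report) {
  lines <- c(sprintf("# biomepair run report (v%s, seed %s)",
                     report$version, report$seed),
             "",
             sprintf("- complete: %s", isTRUE(report$complete)))
  stage_block <- function(name, title, body = NULL) {
    st <- report$stages[[name]]
    if (is.null(st)) return(c(sprintf("## %s", title), "", "_skipped_", ""))
    if (!identical(st$status, "complete"))
      return(c(sprintf("## %s", title), "",
               sprintf("_%s_%s", st$status,
                       if (!is.null(st$error)) paste0(": ", st$error) else ""),
               ""))
    c(sprintf("## %s", title), "", body(st), "")
  }
  lines <- c(
    lines, "",
    stage_block("load", "Cohort", function(st)
      sprintf("- %d matched pairs (%d samples) loaded", st$n_pairs,
              st$n_samples)),
    stage_block("filter", "Read-depth filter", function(st)
      c(sprintf("- %d pair(s) removed at <%d bacterial reads; %d retained",
                st$n_pairs_removed, st$min_reads, st$n_pairs_retained),
        if (length(st$removed_patients))
          sprintf("- removed: %s", paste(st$removed_patients, collapse = ", ")))),
    stage_block("diversity", "Diversity and richness", function(st)
      c(sprintf("- %d comparisons run", st$n_tests),
        if (length(st$significant))
          paste0("- significant: ", paste(st$significant, collapse = "; "))
        else "- no significant comparison")),
    stage_block("ordination", "Ordination and clustering", function(st)
      sprintf("- Bray-Curtis PCoA and UPGMA dendrograms written%s",
              if (isTRUE(st$unifrac)) "; unweighted UniFrac included" else "")),
    stage_block("differential", "Differential abundance", function(st) {
      top <- st$top_taxa
      c(sprintf("- significant phyla: %d bacterial, %d fungal",
                st$n_significant_phyla_bacteria,
                st$n_significant_phyla_fungi),
        sprintf("- significant genera: %d", st$n_significant_genera),
        if (NROW(top)) c("", "| kingdom | taxon | adj. p | direction |",
                         "|---|---|---|---|",
                         sprintf("| %s | %s | %.3g | %s |", top$kingdom,
                                 top$taxon_id, top$p_adj, top$direction)))
    }),
    stage_block("correlation", "Correlation screens", function(st)
      sprintf("- %d pairs tested at %s rank; %d significant (BH)",
              st$n_pairs_tested, st$rank, st$n_significant)),
    stage_block("rf", "Random forest", function(st)
      c(sprintf("- %d genus features; OOB error %.3f", st$n_features,
                st$oob_error),
        sprintf("- 0.632+ error %.3f (apparent %.3f, bootstrap %.3f, no-information %.3f)",
                st$err_632plus, st$err_bar, st$err1, st$gamma),
        sprintf("- backward selection optimum: %d variables",
                st$selected_size))),
    stage_block("field_effect", "Vote-fraction field effect", function(st)
      c(sprintf("- mean d = %.3f; %.0f%% of pairs trend in the correct direction",
                st$mean_d, 100 * st$frac_correct_direction),
        sprintf("- group means (%s): %s; p = %.4g, smaller d in '%s'",
                "t_stage",
                paste(sprintf("%s=%.3f", names(st$group_means),
                              unlist(st$group_means)), collapse = ", "),
                st$p_value, st$direction))))
  lines
}
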