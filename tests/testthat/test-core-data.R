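test_that("abundance TSV round-trips losslessly and preserves order", {
  taxa <- mk_taxa("bacteria", c("g1", "g2", "g3"), phyla = c("p1", "p1", "p2"))
  counts <- named_mat(c(5, 1, 0, 0, 2, 7), c("g1", "g2", "g3"), c("s1", "s2"))
  tab <- abundance_table(taxa, counts, rank = "genus")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_tsv(tab, path)
  back <- read_abundance_tsv(path, kingdom = "bacteria")
  expect_identical(back$counts, tab$counts)
  expect_identical(back$taxa, tab$taxa)
  expect_identical(colnames(back$counts), c("s1", "s2"))

  # species-rank rows keep the species column through the round trip
  sp <- abundance_table(mk_taxa("fungi", c("a", "b"), species = c("x", "y")),
                        named_mat(1:4, c("a", "b"), c("s1", "s2")),
                        rank = "species")
  write_abundance_tsv(sp, path)
  expect_identical(read_abundance_tsv(path, rank = "species")$taxa$species,
                   c("x", "y"))

  # empty-taxa table writes a header-only file
  empty <- abundance_table(mk_taxa("bacteria", character(0),
                                   phyla = character(0)),
                           matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("s1", "s2"))))
  write_abundance_tsv(empty, path)
  expect_length(readLines(path), 1L)
})

test_that("malformed abundance files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("kingdom\tphylum\tgenus\ts1\ts2",
               "bacteria\tp1\tg1\t5\t-3"), path)
  expect_error(read_abundance_tsv(path), "negative")
  writeLines(c("kingdom\tphylum\tgenus\ts1\ts2",
               "bacteria\tp1\tg1\t5\tabc"), path)
  expect_error(read_abundance_tsv(path), "s2")
  writeLines(c("genus\ts1", "g1\t5"), path)
  expect_error(read_abundance_tsv(path), "malformed header")
  expect_error(abundance_table(mk_taxa("bacteria", c("g1", "g1")),
                               named_mat(1:4, c("a", "b"), c("s1", "s2"))),
               "duplicate taxon_id")
})

test_that("metadata parsing validates and normalizes enums", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpatient_id\ttissue\tt_stage",
               "a_T\ta\tTumor\tT3",
               "a_N\ta\tNon-Tumor\t",
               "b_T\tb\ttumor\tt1",
               "b_N\tb\tnormal\tlow"), path)
  md <- read_metadata_tsv(path)
  expect_equal(md$tissue, c("tumor", "nontumor", "tumor", "nontumor"))
  expect_equal(md$t_stage, c("high", NA, "low", "low"))

  writeLines(c("sample_id\tpatient_id\ttissue",
               "a1\ta\ttumor", "a2\ta\ttumor"), path)
  expect_error(read_metadata_tsv(path), "duplicate \\(patient_id, tissue\\)")
  writeLines(c("sample_id\tpatient_id\ttissue", "a1\ta\tstroma"), path)
  expect_error(read_metadata_tsv(path), "unknown tissue")
})

test_that("build_cohort keeps only complete pairs present in both kingdoms", {
  b <- abundance_table(mk_taxa("bacteria", "g1"),
                       named_mat(1:6, "g1",
                                 c("a_T", "a_N", "b_T", "b_N", "c_T", "c_N")))
  f <- abundance_table(mk_taxa("fungi", "h1"),
                       named_mat(1:5, "h1",
                                 c("a_T", "a_N", "b_T", "b_N", "c_N")))
  md <- data.frame(
    sample_id = c("a_T", "a_N", "b_T", "b_N", "c_T", "c_N"),
    patient_id = rep(c("a", "b", "c"), each = 2),
    tissue = rep(c("tumor", "nontumor"), 3))
  expect_message(co <- build_cohort(b, f, md), "absent from one or both")
  expect_equal(nrow(co$pairs), 2)
  expect_setequal(co$pairs$patient_id, c("a", "b"))
  expect_equal(nrow(co$metadata), 4)

  # metadata sample absent from the tables -> that patient excluded
  md2 <- rbind(md, data.frame(sample_id = c("d_T", "d_N"), patient_id = "d",
                              tissue = c("tumor", "nontumor")))
  expect_message(co2 <- build_cohort(b, f, md2), "absent")
  expect_false("d" %in% co2$pairs$patient_id)

  # zero complete pairs -> error
  expect_error(suppressMessages(
    build_cohort(b, f, md[md$tissue == "tumor", ])), "no patient")
})

test_that("rank aggregation is additive and conserves per-sample totals", {
  taxa <- mk_taxa("bacteria", c("g1", "g2", "g3"), phyla = c("p1", "p1", "p2"))
  counts <- named_mat(c(3, 4, 2, 1, 0, 5), c("g1", "g2", "g3"), c("s1", "s2"))
  tab <- abundance_table(taxa, counts, rank = "genus")
  ph <- aggregate_to_rank(tab, "phylum")
  expect_equal(nrow(ph$counts), 2)
  expect_equal(unname(ph$counts["bacteria|p1", "s1"]), 7)
  expect_identical(colSums(ph$counts), colSums(tab$counts))
  expect_identical(aggregate_to_rank(tab, "genus"), tab)
  expect_error(aggregate_to_rank(ph, "genus"), "finer")
})

test_that("relative abundance columns sum to one", {
  tab <- abundance_table(mk_taxa("bacteria", c("g1", "g2", "g3")),
                         named_mat(c(2, 2, 4, 1, 0, 0),
                                   c("g1", "g2", "g3"), c("s1", "s2")))
  rel <- to_relative_abundance(tab)
  expect_equal(unname(rel$counts[, "s1"]), c(0.25, 0.25, 0.5))
  expect_equal(unname(rel$counts[, "s2"]), c(1, 0, 0))
  set.seed(42)
  rnd <- abundance_table(mk_taxa("fungi", paste0("g", 1:8)),
                         named_mat(rpois(40, 20) + 1, paste0("g", 1:8),
                                   paste0("s", 1:5)))
  expect_true(all(abs(colSums(to_relative_abundance(rnd)$counts) - 1) < 1e-9))
  zero <- abundance_table(mk_taxa("bacteria", "g1"),
                          named_mat(c(1, 0), "g1", c("ok", "empty")))
  expect_error(to_relative_abundance(zero), "empty")
})

test_that("low-depth pair filter removes whole pairs on bacterial totals", {
  counts_b <- named_mat(c(40, 20000, 50, 50, 800, 900), "g1",
                        c("a_T", "a_N", "b_T", "b_N", "c_T", "c_N"))
  counts_f <- named_mat(rep(100, 6), "h1", colnames(counts_b))
  co <- mk_cohort(counts_b, counts_f)
  expect_message(kept <- filter_low_depth_pairs(co, 50), "removed")
  expect_setequal(kept$pairs$patient_id, c("b", "c"))  # (50,50) retained
  expect_equal(attr(kept, "removed_pairs")$patient_id, "a")
  expect_false("a_T" %in% sample_ids(kept$bacteria))

  expect_equal(filter_low_depth_pairs(co, 0)$pairs, co$pairs)  # identity

  # idempotent, and monotone in min_reads
  again <- filter_low_depth_pairs(kept, 50)
  expect_equal(again$pairs, kept$pairs)
  expect_message(strict <- filter_low_depth_pairs(co, 600), "removed")
  expect_true(all(strict$pairs$patient_id %in% kept$pairs$patient_id))
  expect_error(suppressMessages(filter_low_depth_pairs(co, 1e9)), "all pairs")
})

test_that("genus merging normalizes per kingdom and prefixes features", {
  counts_b <- named_mat(c(6, 2, 3, 1, 4, 4, 2, 2), c("g1", "g2"),
                        c("a_T", "a_N", "b_T", "b_N"))
  counts_f <- named_mat(c(1, 1, 2, 6, 3, 1, 5, 5), c("h1", "h2"),
                        colnames(counts_b))
  co <- mk_cohort(counts_b, counts_f)
  m <- merge_genus_tables(co)
  expect_equal(ncol(m$features), 4)
  expect_true(all(grepl("^(bacteria|fungi):", colnames(m$features))))
  bsum <- rowSums(m$features[, grepl("^bacteria:", colnames(m$features))])
  fsum <- rowSums(m$features[, grepl("^fungi:", colnames(m$features))])
  expect_true(all(abs(bsum - 1) < 1e-9) && all(abs(fsum - 1) < 1e-9))
  # joint normalization: all features together sum to 1
  mj <- merge_genus_tables(co, joint = TRUE)
  expect_true(all(abs(rowSums(mj$features) - 1) < 1e-9))

  co2 <- co
  co2$fungi <- subset_samples(co2$fungi, c("a_T", "a_N", "b_T"))
  expect_error(merge_genus_tables(co2), "differ")
})
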