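test_that("Kruskal-Wallis H matches the hand rank computation", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1)
  same <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("exact permutation p agrees with the exhaustive oracle", {
  set.seed(21)
  cases <- list(list(c(1, 2, 3), c(4, 5, 6)),
                list(rnorm(4), rnorm(4)),
                list(rnorm(3), rnorm(5)),
                list(c(1, 1, 2), c(2, 3, 3)))  # with ties
  for (gs in cases) {
    mine <- kruskal_wallis(gs, p_method = "exact")
    expect_equal(mine$p_value, kw_permutation_oracle(gs[[1]], gs[[2]]),
                 tolerance = 1e-12)
  }
  # the chi-square approximation is in the oracle's neighborhood
  approx <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$p_value
  expect_lt(abs(approx - 0.1), 0.08)
})

test_that("Dunn-Bonferroni post hoc follows Bonferroni arithmetic", {
  two <- dunn_bonferroni(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(nrow(two), 1)
  expect_equal(two$p_adj, two$p)             # factor 1 for one comparison
  three <- dunn_bonferroni(list(a = rnorm(4), b = rnorm(4), c = rnorm(4)))
  expect_equal(nrow(three), 3)
  expect_equal(three$p_adj, pmin(1, three$p * 3))
  swapped <- dunn_bonferroni(list(a = c(4, 5, 6), b = c(1, 2, 3)))
  orig <- dunn_bonferroni(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(swapped$z, -orig$z)
  expect_equal(swapped$p, orig$p)
})

test_that("adjustments are order-preserving and capped at one", {
  set.seed(31)
  p <- runif(40)^3
  for (meth in c("bonferroni", "BH")) {
    adj <- p.adjust(p, meth)
    expect_true(all(adj <= 1) && all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))
  }
})

test_that("per-taxon screen finds planted shifts and skips empty taxa", {
  counts_b <- named_mat(
    c(80, 10, 10,  75, 15, 10,  70, 10, 20,  20, 40, 40,
      25, 35, 40,  15, 45, 40,  78, 12, 10,  22, 38, 40),
    c("g1", "g2", "g3"),
    c("a_T", "a_N", "b_T", "b_N", "c_T", "c_N", "d_T", "d_N"))
  counts_f <- named_mat(rep(c(5, 5), 8), c("h1", "h2"), colnames(counts_b))
  co <- mk_cohort(counts_b, counts_f)
  res <- per_taxon_differential(co, "genus")
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  g1 <- res[res$taxon_id == "g1", ]
  expect_equal(g1$direction, "tumor_up")
  expect_gt(g1$mean_tumor, g1$mean_nontumor)
  expect_equal(res$p_adj[res$kingdom == "bacteria"],
               pmin(1, res$p[res$kingdom == "bacteria"] * 3))

  # a taxon observed only in samples excluded by the grouping is not tested
  ts <- c(a = "low", b = "low", c = "high", d = NA)
  counts_b2 <- rbind(counts_b,
                     gx = c(0, 0, 0, 0, 0, 0, 9, 9))  # only patient d
  co2 <- mk_cohort(counts_b2, counts_f, t_stage = ts)
  expect_message(res2 <- per_taxon_differential(co2, "genus",
                                                grouping = "t_stage"),
                 "all-zero")
  expect_false("gx" %in% res2$taxon_id)
})

test_that("diversity comparisons degenerate correctly on identical groups", {
  counts_b <- named_mat(rep(c(10, 5, 2), 4), c("g1", "g2", "g3"),
                        c("a_T", "a_N", "b_T", "b_N"))
  counts_f <- named_mat(rep(c(4, 4), 4), c("h1", "h2"), colnames(counts_b))
  co <- mk_cohort(counts_b, counts_f)
  res <- diversity_comparison(co, "genus", "shannon")
  expect_equal(res$p, c(1, 1))

  rich <- diversity_comparison(co, "genus", "richness")
  co10 <- co
  co10$bacteria$counts <- co10$bacteria$counts * 10
  co10$fungi$counts <- co10$fungi$counts * 10
  expect_equal(diversity_comparison(co10, "genus", "richness")[-1],
               rich[-1])  # richness blind to depth rescaling
})

test_that("correlation screens respect closure and report constants as NA", {
  set.seed(41)
  n <- 6
  g1 <- rpois(2 * n, 60) + 10
  counts_b <- rbind(g1 = g1, g2 = 200 - g1)   # forced complementarity
  colnames(counts_b) <- c(rbind(paste0(letters[1:n], "_T"),
                                paste0(letters[1:n], "_N")))
  counts_f <- named_mat(c(rbind(rpois(n, 30) + 5, rep(7, n))),
                        c("h1", "h2"), colnames(counts_b))
  co <- mk_cohort(counts_b, counts_f)
  cs <- correlation_screen(co, "genus", tissue = "tumor",
                           scope = "intra_bacteria")
  expect_equal(unname(diag(cs$r)), c(1, 1))   # taxon against itself
  expect_equal(cs$pairs$r[1], -1)             # two-taxon closure
  expect_equal(max(abs(cs$r - t(cs$r))), 0)

  # h2 is constant in proportions only if depths are equal; force a constant
  co$fungi$counts["h2", ] <- 0
  co$fungi$counts["h1", ] <- 10
  co$fungi$counts["h2", 1] <- 0  # keep h2 all-zero -> dropped, h1 constant
  cs2 <- correlation_screen(co, "genus", tissue = "tumor",
                            scope = "inter_kingdom")
  expect_true(all(is.na(cs2$pairs$r[cs2$pairs$taxon2 == "h1"])))
})

test_that("a planted covarying genus pair is recovered across seeds", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- generator_config(
      covarying_pairs = data.frame(kingdom = "bacteria", genus1 = 11,
                                   genus2 = 12, sd = 2.5),
      seed = 400 + s)
    sim <- suppressMessages(simulate_cohort(cfg))
    cs <- suppressMessages(correlation_screen(sim$cohort, "genus",
                                              tissue = "tumor",
                                              scope = "intra_bacteria"))
    row <- cs$pairs[cs$pairs$taxon1 == "bac_g011" &
                      cs$pairs$taxon2 == "bac_g012", ]
    if (nrow(row) == 1 && !is.na(row$r) && row$r > 0 && row$p_adj < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_seeds)
})

test_that("group labels can be swapped without changing p-values", {
  set.seed(51)
  g1 <- rnorm(8); g2 <- rnorm(8, 1)
  expect_equal(kruskal_wallis(list(g1, g2))$p_value,
               kruskal_wallis(list(g2, g1))$p_value)
  expect_equal(kruskal_wallis(list(g1, g2))$statistic,
               kruskal_wallis(list(g2, g1))$statistic)
})
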