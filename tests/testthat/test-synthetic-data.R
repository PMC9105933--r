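# Synthetic generators: exact planted truths, determinism, distributional
# expectations.

test_that("generators are pure functions of the scenario seed", {
  sc <- synthetic_scenario(seed = 11, exclusion_fraction = 0.05)
  m1 <- make_chromosome(sc)
  m2 <- make_chromosome(sc)
  expect_identical(GenomicRanges::start(m1$exclusions),
                   GenomicRanges::start(m2$exclusions))

  q1 <- make_query_regions(sc, m1)
  q2 <- make_query_regions(sc, m1)
  expect_identical(GenomicRanges::start(q1), GenomicRanges::start(q2))

  spec <- sc$track_specs$miRNA
  t1 <- make_annotation_track(sc, m1, q1, spec)
  t2 <- make_annotation_track(sc, m1, q1, spec)
  expect_identical(GenomicRanges::start(t1), GenomicRanges::start(t2))
  expect_identical(names(t1), names(t2))

  s1 <- make_snp_table(sc, m1)
  s2 <- make_snp_table(sc, m1)
  expect_identical(s1, s2)

  g1 <- make_gene_universe(sc)
  g2 <- make_gene_universe(sc)
  expect_identical(g1, g2)
})

test_that("default chromosome is 155 Mb with no exclusions; fractions are honored", {
  sc <- synthetic_scenario(seed = 3)
  m <- make_chromosome(sc)
  expect_identical(m$length, 155000000L)
  expect_length(m$exclusions, 0)

  sc10 <- synthetic_scenario(seed = 3, exclusion_fraction = 0.1)
  m10 <- make_chromosome(sc10)
  frac <- sum(GenomicRanges::width(m10$exclusions)) / m10$length
  expect_lt(abs(frac - 0.1), 0.001)
  expect_true(GenomicRanges::isDisjoint(m10$exclusions))

  expect_error(synthetic_scenario(exclusion_fraction = 1), "< 1")
})

test_that("query sets hit the planted region count and total width exactly", {
  sc <- synthetic_scenario(seed = 21)
  model <- make_chromosome(sc)
  q <- make_query_regions(sc, model)
  expect_length(q, 62)
  expect_identical(sum(GenomicRanges::width(q)), 9300000L)
  expect_true(GenomicRanges::isDisjoint(q))
  expect_identical(summarize_region_set(q)$total_width_mb, 9.3)

  sc1 <- synthetic_scenario(seed = 21, n_query_regions = 1,
                            query_total_width = 123456)
  q1 <- make_query_regions(sc1, make_chromosome(sc1))
  expect_length(q1, 1)
  expect_identical(GenomicRanges::width(q1), 123456L)
})

test_that("query regions avoid exclusion zones", {
  sc <- synthetic_scenario(seed = 22, exclusion_fraction = 0.2,
                           n_query_regions = 20, query_total_width = 2e6)
  model <- make_chromosome(sc)
  q <- make_query_regions(sc, model)
  expect_true(all(GenomicRanges::countOverlaps(q, model$exclusions) == 0L))
})

test_that("null-fold tracks place midpoints uniformly; fold 0 plants exact depletion", {
  sc <- synthetic_scenario(seed = 31)
  model <- make_chromosome(sc)
  query <- make_query_regions(sc, model)

  spec <- track_spec("circRNA", 1e5, 200, 2000, enrichment_fold = 1,
                     name = "calib")
  tr <- make_annotation_track(sc, model, query, spec)
  expect_length(tr, 1e5)
  p0 <- sum(GenomicRanges::width(query)) / model$length
  in_query <- sum(GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(model$name,
                           IRanges::IRanges(S4Vectors::mcols(tr)$midpoint,
                                            width = 1)), query) > 0)
  se <- sqrt(p0 * (1 - p0) / 1e5)
  expect_lt(abs(in_query / 1e5 - p0), 3 * se)

  depleted <- make_annotation_track(sc, model, query,
                                    track_spec("lncRNA", 5000, 200, 60000,
                                               enrichment_fold = 0,
                                               name = "depleted"))
  expect_identical(count_overlapping_elements(depleted, query)$count, 0L)

  empty <- make_annotation_track(sc, model, query,
                                 track_spec("miRNA", 0, 22, 100))
  expect_length(empty, 0)
})

test_that("background SNP p-values pass the nominal threshold at the expected rate", {
  # 200 scenario replicates without signal clusters: passing counts are
  # Binomial(n_snps, 5e-4); compare the pooled total to 3 SEs
  n_snps <- 2000
  total <- 0L
  for (r in 1:200) {
    sc <- synthetic_scenario(seed = 5000 + r,
                             snp_spec = list(n_snps = n_snps,
                                             n_signal_clusters = 0,
                                             snps_per_cluster = 0,
                                             signal_p_scale = 1))
    snps <- make_snp_table(sc)
    total <- total + sum(snps$p < 5e-4)
  }
  expected <- 200 * n_snps * 5e-4
  se <- sqrt(200 * n_snps * 5e-4 * (1 - 5e-4))
  expect_lt(abs(total - expected), 3 * se)
})

test_that("planted signal clusters become regions under default flank/merge", {
  sc <- synthetic_scenario(seed = 42)   # 5 clusters of 10 SNPs, 1 Mb apart
  model <- make_chromosome(sc)
  snps <- make_snp_table(sc, model)
  expect_identical(nrow(snps), 500L)
  r <- build_regions_from_snps(snps, model)
  expect_length(r, 5)
})

test_that("gene universes plant the candidate/curated overlap exactly", {
  sc <- synthetic_scenario(seed = 51)
  g <- make_gene_universe(sc)
  expect_length(g$universe, 800)
  expect_length(g$curated, 9)
  expect_length(g$candidates, 20)
  expect_identical(length(intersect(g$candidates, g$curated)), 2L)

  sc0 <- synthetic_scenario(seed = 51,
                            gene_spec = list(n_universe = 100, n_curated = 5,
                                             n_candidates = 10,
                                             planted_overlap = 0))
  g0 <- make_gene_universe(sc0)
  r <- geneset_bootstrap(g0$candidates, g0$curated, g0$universe,
                         n_iter = 100, seed = 1)
  expect_identical(r$p_emp, 1)

  expect_error(make_gene_universe(
    synthetic_scenario(gene_spec = list(n_universe = 100, n_curated = 5,
                                        n_candidates = 10,
                                        planted_overlap = 6))),
    "planted_overlap")
})

test_that("the curated differentially methylated gene fixture ships intact", {
  genes <- curated_dmg_genes()
  expect_length(genes, 9)
  expect_true(all(c("PQBP1", "PIM2", "ATP6AP2") %in% genes))
})
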