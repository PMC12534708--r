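test_that("hypergeometric enrichment matches the worked 2x2 table", {
  universe <- sprintf("u%03d", 1:100)
  query <- universe[1:10]
  ann <- list(hit = c(universe[1:8], universe[11:22]))  # overlap 8 of 20
  res <- fisher_set_enrichment(query, ann, universe)
  expect_equal(res$a, 8)
  expect_equal(res$odds_ratio, (8 * 78) / (2 * 12))  # = 26
  expect_equal(res$log2_or, log2(26), tolerance = 1e-4)
  expect_equal(res$p_value, oracle_hyper_p(8, 20, 100, 10), tolerance = 1e-12)
  # annotation = universe is degenerate: continuity-corrected OR 1, p 1
  res2 <- fisher_set_enrichment(query, list(all = universe), universe)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p_value, 1)
  expect_error(fisher_set_enrichment("zz", ann, universe), "empty")
})

test_that("enrichment equals the direct-summation oracle on random small tables", {
  set.seed(23)
  for (i in 1:25) {
    N <- sample(20:200, 1)
    universe <- sprintf("u%03d", seq_len(N))
    query <- sample(universe, sample(3:(N / 2), 1))
    ann <- list(x = sample(universe, sample(3:(N / 2), 1)))
    res <- fisher_set_enrichment(query, ann, universe)
    expect_equal(res$p_value,
                 oracle_hyper_p(res$a, res$a + res$c, N, length(query)),
                 tolerance = 1e-12)
  }
})

test_that("interval colocalization expands, clamps and counts half-open overlaps", {
  # point SNP at 6000 expands to [1000, 11001)
  snp <- data.frame(chrom = "chr1", start = 6000L, end = 6001L, name = "rs1")
  ex <- ternarycode:::expand_intervals(snp, 5000)
  expect_equal(c(ex$start, ex$end), c(1000L, 11001L))
  # clamping at zero
  near0 <- ternarycode:::expand_intervals(
    data.frame(chrom = "chr1", start = 999L, end = 1000L, name = "c"), 5000)
  expect_equal(near0$start, 0L)

  uni <- data.frame(chrom = "chr1", start = c(999L, 50000L),
                    end = c(1000L, 50001L), name = c("cpg1", "cpg2"))
  res <- interval_colocalization(uni[1, ], list(trait = snp), uni,
                                 expand_bp = 5000)
  expect_equal(res$a, 1)  # [0,6000) overlaps [1000,11001)
  res0 <- interval_colocalization(uni[1, ], list(trait = snp), uni,
                                  expand_bp = 0)
  expect_equal(res0$a, 0)
  bad <- list(trait = data.frame(chrom = "chrZ", start = 1L, end = 2L, name = "x"))
  expect_error(interval_colocalization(uni[1, ], bad, uni), "chrZ")
})

test_that("planted interval enrichment is recovered near its odds ratio", {
  cfg <- sim_config(n_probes = 2000, n_samples = 6, replicate_frac = 0,
                    seed = 24)
  sim <- simulate_cohort(cfg)
  universe <- sim$manifest$probe_id
  query <- sample(universe, 300)
  ors <- vapply(1:5, function(s) {
    ann <- simulate_annotations(universe, query, n_sets = 1,
                                enrichment_factor = 3, base_rate = 0.15,
                                seed = 100 + s)
    fisher_set_enrichment(query, ann$sets, universe)$odds_ratio
  }, numeric(1))
  expect_gte(stats::median(ors), 3 / 1.5)
  expect_lte(stats::median(ors), 3 * 1.5)
})

test_that("enrichment score follows the running-sum definition and exhaustive null", {
  # query on top of the list maxes out at ES = 1
  ranked <- sprintf("r%02d", 1:10)
  top <- ranked_set_enrichment(ranked, ranked[1:2], n_permutations = 50, seed = 1)
  expect_equal(top$es, 1)
  expect_gte(top$p_value, 1 / 51)
  # uniform spread shrinks toward 0 as N grows
  big <- sprintf("r%04d", 1:1000)
  spread <- ranked_set_enrichment(big, big[seq(5, 1000, by = 10)],
                                  n_permutations = 10, seed = 1)
  expect_lt(abs(spread$es), 0.05)
  # step-by-step oracle agreement on random placements
  set.seed(25)
  for (i in 1:20) {
    member <- rep(FALSE, 30); member[sample(30, 7)] <- TRUE
    expect_equal(ternarycode:::es_from_positions(which(member), 30),
                 oracle_es(member, 30), tolerance = 1e-12)
  }
  # N = 10, |Q| = 2: sampled permutation p matches exhaustive enumeration
  q <- ranked[c(3, 4)]
  obs <- ranked_set_enrichment(ranked, q, n_permutations = 2000, seed = 2)
  combs <- utils::combn(10, 2)
  all_es <- apply(combs, 2, function(idx) ternarycode:::es_from_positions(idx, 10))
  exact_p <- mean(abs(all_es) >= abs(obs$es))
  expect_equal(obs$p_value, exact_p, tolerance = 0.05)
  expect_error(ranked_set_enrichment(ranked, ranked, seed = 1), "proper subset")
})

test_that("tissue rank context reproduces midranks and the closed-form H", {
  bm <- rbind(p1 = c(0.1, 0.5, 0.9, 0.2, 0.6, 0.95),
              p2 = c(0.3, 0.3, 0.8, 0.1, 0.7, 0.85))
  colnames(bm) <- sprintf("s%d", 1:6)
  g <- rep(c("A", "B", "C"), 2)
  out <- tissue_rank_context(bm, c("p1", "p2"), setNames(g, colnames(bm)))
  # ranks of p1: 0.1,0.5,0.9,0.2,0.6,0.95 -> 1,3,5,2,4,6; A mean (1+2)/2
  mr <- out$mean_ranks
  expect_equal(mr$mean_rank[mr$probe_id == "p1" & mr$tissue == "A"], 1.5)
  # midranks for ties: p2 has 0.3 twice -> ranks 2.5
  expect_equal(mr$mean_rank[mr$probe_id == "p2" & mr$tissue == "A"],
               mean(c(2.5, 1)))
  # H on the pooled tie-free mean-rank distributions matches the textbook formula
  h_oracle <- oracle_kw_h(mr$mean_rank, mr$tissue)
  if (!any(duplicated(mr$mean_rank))) {
    expect_equal(out$kruskal$statistic, h_oracle, tolerance = 1e-9)
  }
  expect_equal(nrow(out$dunn), choose(3, 2))
  expect_true(all(out$dunn$q_value >= out$dunn$p_value - 1e-12))
})

test_that("probe-gene linking respects the window and many-to-many pairs", {
  man <- data.frame(chrom = "chr1", start = c(5000L, 15000L), end = c(5001L, 15001L),
                    probe_id = c("cgA", "cgB"))
  genes <- data.frame(chrom = "chr1", start = c(10000L, 100000L),
                      end = c(20000L, 110000L), name = c("G1", "G2"))
  linked <- link_probes_to_genes(man, genes, window_bp = 10000)
  expect_true(all(c("cgA", "cgB") %in% linked$probe_id[linked$gene == "G1"]))
  expect_false("G2" %in% linked$gene)
  # window 0: only containment/overlap links
  linked0 <- link_probes_to_genes(man, genes, window_bp = 0)
  expect_identical(linked0$probe_id, "cgB")
  expect_error(link_probes_to_genes(man,
                                    data.frame(chrom = "chr1", start = 5L,
                                               end = 2L, name = "bad"), 0),
               "malformed")
})

test_that("CpG-gene correlation handles affine, null and degenerate pairs", {
  tissues <- sprintf("t%d", 1:8)
  bm <- toy_bm(runif(3 * 8, 0.2, 0.8), 3, 8, probes = c("cg1", "cg2", "cg3"),
               samples = tissues)
  expr <- rbind(gA = 100 * bm["cg1", ], gConst = rep(5, 8),
                gNull = runif(8))
  colnames(expr) <- tissues
  pairs <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                      gene = c("gA", "gConst", "gNull"))
  out <- cpg_gene_correlation(bm, expr, pairs)
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_true(is.na(out$r[2]))  # zero-variance expression
  # planted independence: mean r over many null pairs is near 0
  set.seed(26)
  bm_big <- toy_bm(runif(60 * 8), 60, 8, samples = tissues)
  expr_big <- matrix(runif(60 * 8), 60, 8,
                     dimnames = list(paste0("g", 1:60), tissues))
  pairs_big <- data.frame(probe_id = rownames(bm_big), gene = rownames(expr_big))
  out_big <- cpg_gene_correlation(bm_big, expr_big, pairs_big)
  expect_lt(abs(mean(out_big$r, na.rm = TRUE)), 0.15)
})
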