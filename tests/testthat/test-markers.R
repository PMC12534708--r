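test_that("complete separation gives AUC 1, the exact enumeration p, and hyper direction", {
  bm <- rbind(pA = c(0.9, 0.8, 0.85, 0.1, 0.2, 0.15, 0.05),
              pB = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  colnames(bm) <- sprintf("s%d", 1:7)
  g <- rep(c("T", "R"), c(3, 4))
  res <- one_vs_rest_markers(bm, g, "T")
  a <- res[res$probe_id == "pA", ]
  expect_equal(a$auc, 1)
  expect_equal(a$delta_beta, mean(c(0.9, 0.8, 0.85)) - mean(c(0.1, 0.2, 0.15, 0.05)))
  expect_equal(a$direction, "hyper")
  expect_equal(a$p_value, 2 / 35, tolerance = 1e-12)
  # fully tied probe: p = 1, AUC = 0.5, not selected
  b <- res[res$probe_id == "pB", ]
  expect_equal(b$auc, 0.5)
  expect_false(b$selected)
})

test_that("U, p and AUC match exhaustive-enumeration oracles over small group sizes", {
  set.seed(7)
  for (n1 in 2:5) for (n2 in 2:5) {
    x <- runif(n1); y <- runif(n2)
    bm <- matrix(c(x, y), 1, dimnames = list("p1", sprintf("s%d", seq_len(n1 + n2))))
    res <- one_vs_rest_markers(bm, rep(c("T", "R"), c(n1, n2)), "T", min_n = 2)
    expect_equal(res$p_value, oracle_wilcox_p(x, y), tolerance = 1e-12)
    expect_equal(res$auc, oracle_auc(x, y), tolerance = 1e-12)
    expect_equal(res$auc, res$U / (n1 * n2))
  }
  # midranks under ties still agree with pair counting
  x <- c(0.5, 0.5, 0.8); y <- c(0.5, 0.2, 0.2, 0.1)
  bm <- matrix(c(x, y), 1, dimnames = list("p1", sprintf("s%d", 1:7)))
  res <- one_vs_rest_markers(bm, rep(c("T", "R"), c(3, 4)), "T")
  expect_equal(res$auc, oracle_auc(x, y), tolerance = 1e-12)
})

test_that("NA filtering follows the 10%/50% rules and the usable-sample floor", {
  set.seed(1)
  bm <- toy_bm(runif(40), 2, 20)
  g <- rep(c("T", "R"), each = 10)
  bm["p01", 1:2] <- NA            # 20% NA in target -> dropped
  bm["p02", 11:15] <- NA          # 50% NA in rest -> kept (rule is strict >)
  res <- one_vs_rest_markers(bm, g, "T")
  expect_false("p01" %in% res$probe_id)
  expect_true("p02" %in% res$probe_id)
  expect_equal(res$n_rest_used[res$probe_id == "p02"], 5)
  expect_warning(one_vs_rest_markers(bm[, 1:11], c(rep("T", 10), "R"), "T"),
                 "skipped")
})

test_that("design-mode cap returns exactly 80 markers balanced across directions", {
  cfg <- sim_config(n_probes = 1500, n_celltypes = 5, n_samples = 25,
                    n_markers_per_type = 120, marker_delta = 0.4,
                    noise_sd = 0.05, na_rate = 0, replicate_frac = 0, seed = 44)
  sim <- simulate_cohort(cfg)
  res <- one_vs_rest_markers(sim$modc, setNames(sim$sheet$tissue, sim$sheet$sample_id),
                             "T1", min_auc = 1, min_delta = 0.3, cap = 80)
  sel <- res[res$selected, ]
  expect_identical(nrow(sel), 80L)
  expect_lte(abs(sum(sel$direction == "hyper") - sum(sel$direction == "hypo")), 1)
  # capped selection is deterministic
  res2 <- one_vs_rest_markers(sim$modc, setNames(sim$sheet$tissue, sim$sheet$sample_id),
                              "T1", min_auc = 1, min_delta = 0.3, cap = 80)
  expect_identical(sel$probe_id, res2$probe_id[res2$selected])
})

test_that("shuffled labels yield no markers and uniform p-values on null data", {
  set.seed(11)
  bm <- toy_bm(runif(1200 * 60), 1200, 60)
  g <- sample(rep(c("A", "B"), each = 30))
  res <- one_vs_rest_markers(bm, g, "A")
  expect_lt(mean(res$selected), 0.005)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("hierarchical contrasts find subtype markers only at their level", {
  set.seed(12)
  n <- 24
  tree <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     major = rep(c("M1", "M2"), each = 12),
                     sub = rep(c("A", "B", "C", "D"), each = 6))
  bm <- toy_bm(runif(n * 3, 0.45, 0.55), 3, n, probes = c("maj", "sub", "null"),
               samples = tree$sample_id)
  bm["maj", tree$major == "M1"] <- 0.9; bm["maj", tree$major == "M2"] <- 0.1
  # subtype marker: differs between A and B but averages out at major level
  bm["sub", tree$sub == "A"] <- 0.9; bm["sub", tree$sub == "B"] <- 0.1
  res <- hierarchical_contrasts(bm, tree, min_auc = 0.8, min_delta = 0.2)
  lvl1 <- res$major$root$M1
  expect_true(lvl1$selected[lvl1$probe_id == "maj"])
  expect_false(lvl1$selected[lvl1$probe_id == "sub"])
  lvl2 <- res$sub$M1$A
  expect_true(lvl2$selected[lvl2$probe_id == "sub"])
  # flat tree reduces to plain one-vs-rest over all groups
  flat <- data.frame(sample_id = tree$sample_id, major = tree$major)
  expect_identical(hierarchical_contrasts(bm, flat)$major$root$M1,
                   one_vs_rest_markers(bm, setNames(tree$major, tree$sample_id), "M1"))
  bad <- tree; bad$major[bad$sub == "C"][1] <- "M1"
  expect_error(hierarchical_contrasts(bm, bad), "non-tree")
})

test_that("constitutive and intermediate screens apply their thresholds per sample", {
  bm <- rbind(u = c(0.1, 0.15, 0.05), m = c(0.85, 0.9, NA),
              n = c(0.1, 0.85, 0.2), i = c(0.5, 0.5, 0.5),
              x = c(0.5, 0.75, 0.5))
  colnames(bm) <- c("a", "b", "c")
  cs <- constitutive_screen(bm)
  expect_identical(cs$unmodified, "u")
  expect_identical(cs$modified, "m")
  expect_setequal(intermediate_screen(bm), c("i"))
  # 2-of-3 fraction admits the row with one excursion
  expect_setequal(intermediate_screen(bm, min_frac_samples = 2 / 3), c("i", "x"))
  # absolute-count design variant: 139 of 140 required samples fails
  big <- matrix(0.5, 2, 180, dimnames = list(c("in140", "in139"),
                                             sprintf("t%03d", 1:180)))
  big["in140", 1:40] <- 0.9; big["in139", 1:42] <- 0.9
  expect_identical(intermediate_screen(big, min_n_samples = 140), "in140")
})

test_that("variability ranking is SD-ordered with deterministic ties and an autosome filter", {
  bm <- rbind(const = rep(0.4, 4), spread = c(0, 1, 0, 1),
              mid = c(0.4, 0.6, 0.4, 0.6), sexp = c(0, 1, 0, 1))
  colnames(bm) <- sprintf("s%d", 1:4)
  man <- data.frame(chrom = c("chr1", "chr2", "chr3", "chrX"),
                    start = 1:4 * 10, end = 1:4 * 10 + 2,
                    probe_id = rownames(bm))
  vr <- variability_rank(bm)
  expect_identical(vr$probe_id[1:2], c("sexp", "spread"))  # tie -> probe_id order
  expect_equal(vr$sd[1], sd(c(0, 1, 0, 1)))
  expect_identical(vr$probe_id[4], "const")
  vr_auto <- variability_rank(bm, man, chrom_filter = "autosomes")
  expect_false("sexp" %in% vr_auto$probe_id)
})

test_that("tissue-specific feature selection works on single-column groups", {
  expr <- rbind(liver_gene = c(100, 1, 1, 1, 1),
                flat_gene = c(5, 5, 5, 5, 5))
  colnames(expr) <- c("liver", "brain", "lung", "heart", "colon")
  sets <- tissue_specific_features(expr)
  expect_true("liver_gene" %in% sets$liver$probe_id)
  expect_false("flat_gene" %in% unlist(lapply(sets, `[[`, "probe_id")))
  # AUC on single-observation groups matches the pair-counting oracle
  expect_equal(sets$liver$auc[sets$liver$probe_id == "liver_gene"],
               oracle_auc(100, c(1, 1, 1, 1)))
})
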