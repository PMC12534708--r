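test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(n_probes = 200, n_samples = 12, seed = 5)
  expect_identical(simulate_references(cfg), simulate_references(cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  refs <- simulate_references(cfg)$betas
  expect_identical(simulate_mixtures(refs, n_samples = 5, seed = 3),
                   simulate_mixtures(refs, n_samples = 5, seed = 3))
})

test_that("zero-noise archetypes sit exactly at mode values with planted deltas", {
  cfg <- sim_config(n_probes = 300, n_celltypes = 3, marker_delta = 0.4,
                    noise_sd = 0, seed = 8)
  refs <- simulate_references(cfg)
  expect_true(all(refs$betas %in% c(0.1, 0.9, 0.5)))
  # one-vs-rest mean difference at each planted marker equals marker_delta
  for (i in seq_len(nrow(refs$truth$markers))) {
    m <- refs$truth$markers[i, ]
    row <- refs$betas[m$probe_id, ]
    d <- row[m$celltype] - mean(row[setdiff(names(row), m$celltype)])
    expect_equal(abs(unname(d)), 0.4, tolerance = 1e-12)
    expect_equal(unname(sign(d)), if (m$direction == "hyper") 1 else -1)
  }
  expect_error(sim_config(marker_delta = 0, seed = 1), "marker_delta")
})

test_that("mixtures are convex combinations with valid proportions", {
  refs <- toy_bm(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2, samples = c("A", "B"))
  # identity mixture reproduces the reference column
  mix <- simulate_mixtures(refs, props = matrix(c(1, 0), 1), noise_sd = 0, seed = 1)
  expect_equal(unname(mix$betas[, 1]), c(1, 1, 0, 0))
  # convex combination on the toy two-type panel
  mix2 <- simulate_mixtures(refs, props = matrix(c(0.3, 0.7), 1),
                            noise_sd = 0, seed = 1)
  expect_equal(unname(mix2$betas[, 1]), c(0.3, 0.3, 0.7, 0.7))
  # Dirichlet draws normalize exactly
  mix3 <- simulate_mixtures(refs, n_samples = 20, dirichlet_alpha = 1, seed = 2)
  expect_true(all(abs(rowSums(mix3$props) - 1) < 1e-12))
  expect_error(simulate_mixtures(refs, props = matrix(c(-0.1, 1.1), 1), seed = 1),
               "negative")
})

test_that("cohort plants age, sex, imprinting and a bounded 5hmC layer", {
  cfg <- sim_config(n_probes = 400, n_samples = 24, n_celltypes = 4,
                    noise_sd = 0.2, seed = 21)
  sim <- simulate_cohort(cfg)
  expect_silent(validate_beta_matrix(sim$modc))
  expect_silent(validate_beta_matrix(sim$hmc))
  expect_silent(validate_manifest(sim$manifest))
  # pre-noise constraint 0 <= 5hmC <= 5modC holds cell-wise
  expect_true(all(sim$truth$hmc_pre >= 0))
  expect_true(all(sim$truth$hmc_pre <= sim$truth$modc_pre + 1e-12))
  # age-CpGs gain beta linearly: slope * span on the pre-noise matrix
  ac <- sim$truth$age_cpgs[1, ]
  ages <- sim$sheet$age
  pre <- sim$truth$modc_pre[ac$probe_id, ]
  fit <- lm(pre ~ ages)
  expect_equal(unname(coef(fit)[2]), ac$slope, tolerance = 1e-9)
  # imprinted probes stay at 0.5 pre-noise
  expect_true(all(sim$truth$modc_pre[sim$truth$imprinted, ] == 0.5))
  # sex offset equals sex_delta pre-noise
  hy <- sim$truth$sex_cpgs$male_hyper[1]
  is_m <- sim$sheet$sex == "M"
  expect_equal(mean(sim$truth$modc_pre[hy, is_m]) -
                 mean(sim$truth$modc_pre[hy, !is_m]), cfg$sex_delta)
})

test_that("the 5hmC layer scales with retention and vanishes at scale 0", {
  cfg <- sim_config(n_probes = 100, n_samples = 8, n_celltypes = 2,
                    noise_sd = 0, na_rate = 0, seed = 3)
  sim <- simulate_cohort(cfg)
  # the layer is linear in the retention scale (1 - proliferation), so
  # dividing it out and re-applying scale 0 gives a zero global 5hmC mean
  scaled <- sweep(sim$truth$hmc_pre, 2, sim$truth$hmc_scale, "/")
  expect_equal(mean(sweep(scaled, 2, rep(0, 8), "*")), 0)
  expect_equal(sim$truth$hmc_scale, 1 - sim$truth$proliferation)
  rescaled <- sweep(scaled, 2, sim$truth$hmc_scale * 0.5, "*")
  expect_equal(mean(rescaled), 0.5 * mean(sim$truth$hmc_pre), tolerance = 1e-12)
})

test_that("two-platform split yields exact copies at rho = 1 and a functional map", {
  cfg <- sim_config(n_probes = 400, n_samples = 10, seed = 4, na_rate = 0)
  sim <- simulate_cohort(cfg)
  modc <- collapse_replicates(sim$modc, sim$manifest)
  tw <- simulate_two_platform(modc, n_query = 30, rho = 1, seed = 6)
  expect_false(anyDuplicated(tw$truth$query_id) > 0)
  for (i in seq_len(5)) {
    expect_equal(unname(tw$query[tw$truth$query_id[i], ]),
                 unname(modc[tw$truth$neighbor_id[i], ]))
  }
  expect_error(simulate_two_platform(modc, 5, rho = 1.5, seed = 1), "rho")
})

test_that("planted annotation odds ratios average to the null at factor 1", {
  universe <- sprintf("cg%04d", 1:500)
  query <- universe[1:100]
  ors <- vapply(1:20, function(s) {
    ann <- simulate_annotations(universe, query, n_sets = 1,
                                enrichment_factor = 1, seed = s)
    a <- length(intersect(query, ann$sets[[1]]))
    b <- length(query) - a
    c <- length(ann$sets[[1]]) - a
    d <- length(universe) - a - b - c
    (a * d) / (b * c)
  }, numeric(1))
  expect_equal(mean(ors), 1, tolerance = 0.15)
  # interval output follows the sorted half-open BED contract
  man <- data.frame(chrom = rep(c("chr2", "chr1"), each = 250),
                    start = rep(seq(10, by = 100, length.out = 250), 2),
                    end = rep(seq(12, by = 100, length.out = 250), 2),
                    probe_id = universe)
  ann <- simulate_annotations(universe, query, n_sets = 2,
                              enrichment_factor = 2, seed = 1, manifest = man)
  iv <- ann$intervals[[1]]
  expect_true(all(iv$start < iv$end) && all(iv$start >= 0))
  expect_false(is.unsorted(iv$start[iv$chrom == "chr1"]))
})
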