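#' Simulation configuration
#'
#' Collects the parameters of the synthetic-data generator with the study
#' conditions as defaults: a cohort of bimodal tissue-structured betas with
#' planted cell-type markers, linear age effects, sex effects, an additive
#' 5hmC layer bounded by 5modC and scaled by a per-sample proliferation
#' factor, imprinted loci near 0.5, replicate probes, and MCAR missingness.
#'
#' @param n_probes number of probe positions before replicate expansion.
#' @param n_celltypes number of cell/tissue archetypes.
#' @param n_samples cohort size.
#' @param marker_delta planted one-vs-rest beta difference at marker CpGs.
#' @param n_markers_per_type markers planted per cell type (split evenly
#'   between hyper and hypo).
#' @param noise_sd per-sample Gaussian noise SD on the logit scale.
#' @param age_range cohort age span in years.
#' @param frac_age_cpgs fraction of probes gaining methylation with age.
#' @param age_slope_range per-year beta gain range at age-CpGs.
#' @param sex_delta beta offset at sex-associated autosomal-style CpGs.
#' @param n_sex_cpgs number of sex CpGs (half male-hyper, half male-hypo).
#' @param p_female probability a sample is female.
#' @param hmc_fraction_by_group mean 5hmC/5modC ratio for the low- and
#'   high-5hmC probe groups (named vector low/high).
#' @param frac_high_hmc fraction of probes in the high-5hmC group.
#' @param dirichlet_alpha concentration for mixture proportion sampling.
#' @param n_imprinted probes planted at a stable 0.5 (imprinting-like).
#' @param replicate_frac fraction of probes expanded into replicate groups.
#' @param replicate_noise_sd additive beta-scale noise among replicates.
#' @param na_rate missing-completely-at-random rate.
#' @param seed mandatory integer seed; every stochastic call is seeded.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 5000, n_celltypes = 5, n_samples = 40,
                       marker_delta = 0.4, n_markers_per_type = 20,
                       noise_sd = 0.5, age_range = c(20, 95),
                       frac_age_cpgs = 0.02, age_slope_range = c(0.002, 0.005),
                       sex_delta = 0.5, n_sex_cpgs = 20, p_female = 0.47,
                       hmc_fraction_by_group = c(low = 0.05, high = 0.35),
                       frac_high_hmc = 0.3, dirichlet_alpha = 1,
                       n_imprinted = 10, replicate_frac = 0.02,
                       replicate_noise_sd = 0.02, na_rate = 0.01, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (marker_delta <= 0) stop("marker_delta must be positive")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate cell-type reference archetypes
#'
#' Background probes sit at a bimodal baseline (low mode 0.1, high mode
#' 0.9); each cell type receives planted hyper markers (rest at 0.1, target
#' at 0.1 + delta) and hypo markers (rest at 0.9, target at 0.9 - delta), so
#' the one-vs-rest mean difference at a marker is exactly `marker_delta`
#' before noise. `noise_sd > 0` perturbs the archetypes on the logit scale.
#'
#' @param cfg a [sim_config()].
#' @return list with `betas` (probes x cell types beta matrix) and `truth`
#'   (markers data.frame, baseline modes).
#' @export
simulate_references <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_probes; k <- cfg$n_celltypes
  probe_ids <- sprintf("cg%06d", seq_len(n))
  types <- paste0("T", seq_len(k))
  modes <- sample(c(0.1, 0.9), n, replace = TRUE)
  betas <- matrix(modes, n, k, dimnames = list(probe_ids, types))

  n_mark <- cfg$n_markers_per_type
  need <- n_mark * k
  if (need > n) stop("not enough probes for requested markers")
  marker_rows <- sample.int(n, need)
  markers <- data.frame(probe_id = character(0), celltype = character(0),
                        direction = character(0))
  pos <- 1L
  for (t in seq_len(k)) {
    rows <- marker_rows[pos:(pos + n_mark - 1L)]; pos <- pos + n_mark
    nh <- ceiling(n_mark / 2)
    hyper <- rows[seq_len(nh)]
    hypo <- rows[setdiff(seq_len(n_mark), seq_len(nh))]
    betas[hyper, ] <- 0.1
    betas[hyper, t] <- 0.1 + cfg$marker_delta
    betas[hypo, ] <- 0.9
    betas[hypo, t] <- 0.9 - cfg$marker_delta
    modes[rows] <- betas[rows, t]  # record planted values
    markers <- rbind(markers, data.frame(
      probe_id = probe_ids[c(hyper, hypo)],
      celltype = types[t],
      direction = rep(c("hyper", "hypo"), c(length(hyper), length(hypo)))
    ))
  }
  betas <- logit_noise(betas, cfg$noise_sd)
  validate_beta_matrix(betas)
  list(betas = betas, truth = list(markers = markers, modes = modes,
                                   marker_rows = marker_rows))
}

# sample rows from Dirichlet(alpha) over k components
rdirichlet <- function(n, alpha, k) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
  g / rowSums(g)
}

#' Simulate bulk mixtures of reference archetypes
#'
#' Bulk betas are convex combinations of the reference columns,
#' `sum_k p_k ref_k`, plus logit-scale noise.
#'
#' @param refs probes x cell types reference beta matrix.
#' @param props samples x cell types proportion matrix (rows sum to 1), or
#'   NULL to draw from Dirichlet(`dirichlet_alpha`).
#' @param n_samples number of bulks when `props` is NULL.
#' @param dirichlet_alpha Dirichlet concentration.
#' @param noise_sd logit-scale noise SD.
#' @param seed RNG seed.
#' @return list with `betas` (probes x samples) and `props` (the mixture
#'   proportions used, samples x cell types).
#' @export
simulate_mixtures <- function(refs, props = NULL, n_samples = 50,
                              dirichlet_alpha = 1, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  k <- ncol(refs)
  if (is.null(props)) {
    props <- rdirichlet(n_samples, dirichlet_alpha, k)
  } else {
    props <- as.matrix(props)
    if (any(props < 0)) stop("negative mixture proportion")
    if (any(abs(rowSums(props) - 1) > 1e-8)) stop("proportion rows must sum to 1")
  }
  colnames(props) <- colnames(refs)
  rownames(props) <- sprintf("bulk%03d", seq_len(nrow(props)))
  bulk <- refs %*% t(props)
  bulk[] <- pmin(pmax(bulk, 0), 1)
  bulk <- logit_noise(bulk, noise_sd)
  validate_beta_matrix(bulk)
  list(betas = bulk, props = props)
}

#' Simulate a full cohort with matched 5modC and 5hmC matrices
#'
#' Builds noiseless tissue archetypes, assigns each sample a tissue, age
#' (uniform over `age_range`), and sex, and plants: linear age effects at a
#' random subset of probes; sex offsets (`sex_delta`, half male-hyper and
#' half male-hypo, placed on chrX-like probes); imprinted probes constant at
#' 0.5. The 5hmC layer is built pre-noise as
#' `5hmC = (1 - proliferation_s) * fraction_g(probe) * 5modC`, which
#' guarantees 0 <= 5hmC <= 5modC before noise; because 5hmC is not copied
#' at mitosis, the per-tissue proliferation rate dilutes global 5hmC (the
#' multiplicative retention scale `1 - proliferation` is stored in the
#' ground truth as `hmc_scale`; scale 0 is the no-5hmC limit). Independent
#' logit noise is then added to both matrices (post-noise 5hmC > 5modC
#' violations are left in deliberately to exercise downstream clamping),
#' replicate probes are expanded, and MCAR missingness injected.
#'
#' @param cfg a [sim_config()].
#' @return list with `modc`, `hmc` (beta matrices, replicate-expanded),
#'   `sheet` (sample_id, tissue, age, sex), `manifest` (BED-style probe
#'   table with replicate_prefix), and `truth` (markers, age/sex/imprinted
#'   CpGs, proliferation scalars, pre-noise matrices, replicate map).
#' @export
simulate_cohort <- function(cfg) {
  ref_cfg <- cfg; ref_cfg$noise_sd <- 0
  refs <- simulate_references(ref_cfg)
  n <- cfg$n_probes; ns <- cfg$n_samples; k <- cfg$n_celltypes
  probe_ids <- rownames(refs$betas)
  set.seed(derive_seed(cfg$seed, "cohort"))

  tissue <- paste0("T", rep_len(seq_len(k), ns))
  sample_ids <- sprintf("S%03d", seq_len(ns))
  age <- runif(ns, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(runif(ns) < cfg$p_female, "F", "M")

  base <- refs$betas[, match(tissue, colnames(refs$betas)), drop = FALSE]
  colnames(base) <- sample_ids

  taken <- refs$truth$marker_rows
  free <- setdiff(seq_len(n), taken)
  n_age <- round(cfg$frac_age_cpgs * n)
  age_rows <- sample(free, n_age); free <- setdiff(free, age_rows)
  sex_rows <- sample(free, cfg$n_sex_cpgs); free <- setdiff(free, sex_rows)
  imp_rows <- sample(free, cfg$n_imprinted)

  slopes <- runif(n_age, cfg$age_slope_range[1], cfg$age_slope_range[2])
  # age-CpGs start from a low baseline so the span stays inside [0,1]
  base[age_rows, ] <- 0.1 + outer(slopes, age - cfg$age_range[1])
  nh <- ceiling(length(sex_rows) / 2)
  male_hyper <- sex_rows[seq_len(nh)]
  male_hypo <- sex_rows[setdiff(seq_along(sex_rows), seq_len(nh))]
  is_m <- sex == "M"
  base[male_hyper, ] <- 0.2
  base[male_hyper, is_m] <- 0.2 + cfg$sex_delta
  base[male_hypo, ] <- 0.2 + cfg$sex_delta
  base[male_hypo, is_m] <- 0.2
  base[imp_rows, ] <- 0.5
  base[] <- pmin(pmax(base, 0), 1)

  # 5hmC layer: high-5hmC group (gene-body-like) vs low group. 5hmC is not
  # copied at mitosis, so it dilutes with proliferation: the multiplicative
  # retention scale is 1 - proliferation rate (scale 0 = no 5hmC at all)
  hmc_group <- ifelse(runif(n) < cfg$frac_high_hmc, "high", "low")
  frac_g <- cfg$hmc_fraction_by_group[hmc_group]
  prolif_by_tissue <- setNames(runif(k, 0, 0.9), paste0("T", seq_len(k)))
  hmc_scale_by_tissue <- 1 - prolif_by_tissue
  hmc_scale <- hmc_scale_by_tissue[tissue]
  hmc_pre <- base * (frac_g %o% hmc_scale)

  modc <- logit_noise(base, cfg$noise_sd)
  hmc <- logit_noise(hmc_pre, cfg$noise_sd)

  # replicate expansion: chosen probes appear as prefix_A / prefix_B rows
  n_rep <- round(cfg$replicate_frac * n)
  rep_rows <- sort(sample.int(n, n_rep))
  expand <- function(m) {
    if (n_rep == 0) {
      rownames(m) <- probe_ids
      return(m)
    }
    extra <- m[rep_rows, , drop = FALSE] +
      matrix(rnorm(n_rep * ns, 0, cfg$replicate_noise_sd), n_rep, ns)
    extra[] <- pmin(pmax(extra, 0), 1)
    first <- m[rep_rows, , drop = FALSE] +
      matrix(rnorm(n_rep * ns, 0, cfg$replicate_noise_sd), n_rep, ns)
    first[] <- pmin(pmax(first, 0), 1)
    m[rep_rows, ] <- first
    out <- rbind(m, extra)
    rownames(out) <- c(ifelse(seq_len(n) %in% rep_rows,
                              paste0(probe_ids, "_A"), probe_ids),
                       paste0(probe_ids[rep_rows], "_B"))
    out
  }
  modc <- expand(modc); hmc <- expand(hmc)

  # MCAR missingness (same pattern class, independent draws per matrix)
  inject_na <- function(m) {
    na_idx <- which(runif(length(m)) < cfg$na_rate)
    m[na_idx] <- NA_real_
    m
  }
  modc <- inject_na(modc); hmc <- inject_na(hmc)

  # manifest: probes laid along chr1..chr22 plus chrX for sex CpGs
  prefix <- sub("_[AB]$", "", rownames(modc))
  ord_prefix_row <- match(prefix, probe_ids)
  chrom <- rep("chr1", n)
  chrom[seq_len(n)] <- paste0("chr", rep_len(1:22, n))
  chrom[sex_rows] <- "chrX"
  start <- integer(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    start[idx] <- seq(1000L, by = 1000L, length.out = length(idx))
  }
  manifest <- data.frame(
    chrom = chrom[ord_prefix_row],
    start = start[ord_prefix_row],
    end = start[ord_prefix_row] + 2L,
    probe_id = rownames(modc),
    replicate_prefix = prefix,
    stringsAsFactors = FALSE
  )
  sheet <- data.frame(sample_id = sample_ids, tissue = tissue,
                      age = age, sex = sex, stringsAsFactors = FALSE)
  truth <- list(
    markers = refs$truth$markers,
    age_cpgs = data.frame(probe_id = probe_ids[age_rows], slope = slopes),
    sex_cpgs = list(male_hyper = probe_ids[male_hyper],
                    male_hypo = probe_ids[male_hypo]),
    imprinted = probe_ids[imp_rows],
    proliferation = setNames(unname(prolif_by_tissue[tissue]), sample_ids),
    hmc_scale = setNames(unname(hmc_scale), sample_ids),
    prolif_by_tissue = prolif_by_tissue,
    hmc_scale_by_tissue = hmc_scale_by_tissue,
    hmc_group = setNames(hmc_group, probe_ids),
    modc_pre = base, hmc_pre = hmc_pre,
    replicate_prefixes = probe_ids[rep_rows]
  )
  list(modc = modc, hmc = hmc, sheet = sheet, manifest = manifest,
       truth = truth)
}

#' Simulate a two-platform probe split with correlated neighbors
#'
#' Emulates a legacy/new platform pair: every probe of `refs` is a retained
#' (new-platform) site; `n_query` query (legacy-only) sites are generated as
#' noisy copies of randomly chosen retained sites, with logit-scale noise
#' calibrated so the cross-sample Pearson correlation is approximately
#' `rho`. `rho = 1` gives exact copies; `rho = 0` gives independent bimodal
#' draws.
#'
#' @param refs reference methylome collection (probes x samples).
#' @param n_query number of query sites.
#' @param rho target cross-sample correlation in (-1, 1\].
#' @param seed RNG seed.
#' @return list with `retained` (= refs), `query` (n_query x samples), and
#'   `truth` (data.frame query_id, neighbor_id).
#' @export
simulate_two_platform <- function(refs, n_query, rho, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (rho <= -1 || rho > 1) stop("rho must be in (-1, 1]")
  set.seed(seed)
  ns <- ncol(refs)
  neighbor <- sample.int(nrow(refs), n_query, replace = nrow(refs) < n_query)
  query_ids <- sprintf("q%06d", seq_len(n_query))
  q <- matrix(NA_real_, n_query, ns,
              dimnames = list(query_ids, colnames(refs)))
  eps <- 1e-6
  for (i in seq_len(n_query)) {
    v <- refs[neighbor[i], ]
    if (rho == 0) {
      mode <- sample(c(0.1, 0.9), 1)
      q[i, ] <- logistic(logit(mode) + rnorm(ns, 0, 1))
    } else if (rho == 1) {
      q[i, ] <- v
    } else {
      l <- logit(pmin(pmax(v, eps), 1 - eps))
      s <- sd(l)
      if (!is.finite(s) || s == 0) s <- 1
      sigma <- s * sqrt(1 / rho^2 - 1)
      q[i, ] <- logistic(l + rnorm(ns, 0, sigma))
    }
  }
  list(retained = refs, query = q,
       truth = data.frame(query_id = query_ids,
                          neighbor_id = rownames(refs)[neighbor]))
}

#' Simulate annotation probe sets at a controlled odds ratio
#'
#' Builds `n_sets` annotation sets over a probe universe. The first set is
#' constructed so membership odds for probes inside `query` are
#' `enrichment_factor` times the baseline odds (a planted odds ratio); the
#' remaining sets are drawn at OR = 1. If a manifest is supplied, matching
#' genomic interval sets are emitted as well.
#'
#' @param universe character vector of probe IDs.
#' @param query character vector, the designated query set (subset of
#'   universe).
#' @param n_sets number of annotation sets.
#' @param enrichment_factor planted odds ratio for the first set.
#' @param base_rate baseline membership probability.
#' @param seed RNG seed.
#' @param manifest optional manifest to derive intervals from.
#' @return list with `sets` (named list of probe ID vectors) and
#'   `intervals` (named list of interval data.frames, or NULL).
#' @export
simulate_annotations <- function(universe, query, n_sets = 5,
                                 enrichment_factor = 1, base_rate = 0.2,
                                 seed, manifest = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  stopifnot(all(query %in% universe))
  in_q <- universe %in% query
  odds0 <- base_rate / (1 - base_rate)
  p_enriched <- (enrichment_factor * odds0) / (1 + enrichment_factor * odds0)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("ann%02d", seq_len(n_sets))
  for (s in seq_len(n_sets)) {
    p <- rep(base_rate, length(universe))
    if (s == 1L) p[in_q] <- p_enriched
    sets[[s]] <- universe[runif(length(universe)) < p]
  }
  intervals <- NULL
  if (!is.null(manifest)) {
    intervals <- lapply(sets, function(ids) {
      m <- manifest[manifest$probe_id %in% ids, c("chrom", "start", "end", "probe_id")]
      names(m)[4] <- "name"
      m[order(m$chrom, m$start), ]
    })
  }
  list(sets = sets, intervals = intervals)
}
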