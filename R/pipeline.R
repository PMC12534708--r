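#' Default pipeline configuration
#'
#' Returns the full configuration of the synthetic end-to-end workflow with
#' every threshold at its headline value: marker selection at AUC >= 0.8
#' and |delta beta| >= 0.2 with the 10%/50% NA caps, neighbor gate r > 0.5,
#' interval expansion 5 kb, elastic-net alpha 0.5 with 10 inner folds and
#' 50 features per fold. Unknown keys passed to [run_pipeline()] overrides
#' are rejected.
#'
#' @param seed global seed; per-stage seeds are derived from it via
#'   [derive_seed()] so stages can be rerun in isolation.
#' @return nested named list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = list(simulate = TRUE, ternary = TRUE, markers = TRUE,
                  deconv = TRUE, impute = TRUE, enrich = TRUE,
                  ewas = TRUE, clock = TRUE, sex = TRUE),
    sim = list(n_probes = 5000, n_celltypes = 5, n_samples = 40,
               marker_delta = 0.4, noise_sd = 0.5,
               n_mixtures = 50, mixture_noise_sd = 0.3,
               n_query = 500, neighbor_rho = 0.9,
               n_annotation_sets = 5, annotation_or = 3),
    markers = list(min_auc = 0.8, min_delta = 0.2, max_na_target = 0.10,
                   max_na_rest = 0.50, cap = NULL),
    impute = list(k = 50, r_min = 0.5),
    enrich = list(expand_bp = 5000, n_permutations = 200),
    clock = list(n_features = 50, alpha = 0.5, inner_folds = 10)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base)) stop("unknown config key: ", path, key)
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(path, key, "."))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

config_hash <- function(config) {
  fnv1a_hex(paste(deparse(config), collapse = "\n"))
}

#' Run the end-to-end synthetic workflow
#'
#' Executes the stages in dependency order — simulate, ternary
#' decomposition, marker discovery, deconvolution, cross-platform
#' imputation, enrichment, EWAS, clock, sex scoring — writing each stage's
#' tables under `out_dir` together with the resolved configuration (and
#' its hash) and a machine-readable `summary.json`. All randomness derives
#' from the single config seed, so a rerun with an identical config is
#' bit-identical.
#'
#' @param config configuration list; missing keys take [default_config()]
#'   values, unknown keys are rejected.
#' @param out_dir output directory (created).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  writeLines(c(paste0("# config hash: ", hash),
               yaml::as.yaml(cfg)), file.path(out_dir, "config_echo.yaml"))
  summary <- list(config_hash = hash)
  st <- cfg$stages
  if (!any(unlist(st))) {
    return(invisible(summary))
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sim <- NULL
  if (st$simulate) {
    sim <- run_stage("simulate", {
      sc <- sim_config(n_probes = cfg$sim$n_probes,
                       n_celltypes = cfg$sim$n_celltypes,
                       n_samples = cfg$sim$n_samples,
                       marker_delta = cfg$sim$marker_delta,
                       noise_sd = cfg$sim$noise_sd,
                       seed = derive_seed(cfg$seed, "simulate"))
      out <- simulate_cohort(sc)
      write_beta_matrix(out$modc, file.path(out_dir, "modc.tsv"))
      write_beta_matrix(out$hmc, file.path(out_dir, "hmc.tsv"))
      data.table::fwrite(out$sheet, file.path(out_dir, "sample_sheet.csv"))
      data.table::fwrite(out$manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
      out$config <- sc
      out
    })
    summary$n_probes <- nrow(sim$modc)
    summary$n_samples <- ncol(sim$modc)
  }
  if (is.null(sim)) {
    return(invisible(summary))  # downstream stages need the simulation
  }
  # collapse replicate probes once; all downstream stages use prefix space
  modc <- collapse_replicates(sim$modc, sim$manifest)
  hmc <- collapse_replicates(sim$hmc, sim$manifest)

  if (st$ternary) {
    run_stage("ternary", {
      tp <- ternary_decompose(modc, hmc)
      write_ternary(tp, file.path(out_dir, "ternary"))
      gm <- global_ternary_means(tp, sim$sheet)
      data.table::fwrite(gm, file.path(out_dir, "ternary_group_means.csv"))
      rb <- ratio_by_hmc_bin(tp, bins = seq(0, 1, 0.1))
      data.table::fwrite(rb, file.path(out_dir, "ratio_by_hmc_bin.csv"))
      summary$clamped_fraction <- clamped_fraction(tp)
    })
  }
  marker_sets <- NULL
  if (st$markers) {
    run_stage("markers", {
      res <- all_contrasts(modc, setNames(sim$sheet$tissue, sim$sheet$sample_id),
                           min_auc = cfg$markers$min_auc,
                           min_delta = cfg$markers$min_delta,
                           max_na_target = cfg$markers$max_na_target,
                           max_na_rest = cfg$markers$max_na_rest,
                           cap = cfg$markers$cap)
      tab <- do.call(rbind, res)
      data.table::fwrite(tab, file.path(out_dir, "markers.tsv"), sep = "\t")
      marker_sets <- res
      summary$n_markers_selected <- sum(tab$selected)
    })
  }
  if (st$deconv) {
    run_stage("deconv", {
      ref_cfg <- sim$config; ref_cfg$noise_sd <- 0
      refs <- simulate_references(ref_cfg)
      mix <- simulate_mixtures(refs$betas, n_samples = cfg$sim$n_mixtures,
                               noise_sd = cfg$sim$mixture_noise_sd,
                               seed = derive_seed(cfg$seed, "mixtures"))
      marker_ids <- unique(refs$truth$markers$probe_id)
      panel <- build_reference(refs$betas, marker_ids)
      props <- rpc_deconvolve(mix$betas, panel)
      data.table::fwrite(props, file.path(out_dir, "proportions.csv"))
      k <- ncol(panel)
      est <- as.matrix(props[, colnames(panel)])
      summary$deconv_rmse <- sqrt(mean((est - mix$props)^2))
    })
  }
  if (st$impute) {
    run_stage("impute", {
      tw <- simulate_two_platform(modc, n_query = cfg$sim$n_query,
                                  rho = cfg$sim$neighbor_rho,
                                  seed = derive_seed(cfg$seed, "two_platform"))
      reference <- rbind(tw$retained, tw$query)
      map <- build_neighbor_map(reference, rownames(tw$retained),
                                rownames(tw$query), k = cfg$impute$k,
                                r_min = cfg$impute$r_min)
      data.table::fwrite(map, file.path(out_dir, "neighbor_map.tsv"), sep = "\t")
      summary$imputable_fraction <- mean(map$retained)
      summary$neighbor_map_accuracy <-
        mean(map$neighbor_id == tw$truth$neighbor_id[match(map$query_id,
                                                           tw$truth$query_id)])
    })
  }
  if (st$enrich && !is.null(marker_sets)) {
    run_stage("enrich", {
      universe <- rownames(modc)
      query <- marker_sets[[1]]$probe_id[marker_sets[[1]]$selected]
      if (length(query) > 1) {
        ann <- simulate_annotations(universe, query,
                                    n_sets = cfg$sim$n_annotation_sets,
                                    enrichment_factor = cfg$sim$annotation_or,
                                    seed = derive_seed(cfg$seed, "annotations"))
        fe <- fisher_set_enrichment(query, ann$sets, universe)
        data.table::fwrite(fe, file.path(out_dir, "enrichment_fisher.tsv"), sep = "\t")
        summary$planted_or_estimate <- fe$odds_ratio[fe$annotation == "ann01"]
      }
      vr <- variability_rank(modc, sim$manifest, chrom_filter = "autosomes")
      qset <- intersect(vr$probe_id[seq_len(min(50, nrow(vr)))], vr$probe_id)
      sea <- ranked_set_enrichment(vr$probe_id, qset,
                                   n_permutations = cfg$enrich$n_permutations,
                                   seed = derive_seed(cfg$seed, "sea"))
      summary$sea_es_top_variable <- sea$es
    })
  }
  ewas_tab <- NULL
  if (st$ewas) {
    run_stage("ewas", {
      ewas_tab <- fit_linear_ewas(modc, sim$sheet)
      data.table::fwrite(ewas_tab, file.path(out_dir, "ewas.tsv"), sep = "\t")
      age <- ewas_tab[ewas_tab$term == "age", ]
      summary$n_age_hits_fdr05 <- sum(age$q_value < 0.05, na.rm = TRUE)
    })
  }
  if (st$clock) {
    run_stage("clock", {
      cl <- loocv_clock(modc, sim$sheet,
                        n_features = cfg$clock$n_features,
                        alpha = cfg$clock$alpha,
                        inner_folds = cfg$clock$inner_folds,
                        seed = derive_seed(cfg$seed, "clock"))
      data.table::fwrite(cl$predictions, file.path(out_dir, "clock_predictions.csv"))
      wdf <- data.frame(probe_id = names(cl$model$weights),
                        weight = unname(cl$model$weights))
      data.table::fwrite(wdf, file.path(out_dir, "clock_model.csv"))
      summary$clock_mae <- cl$mae
      summary$clock_pearson_r <- cl$pearson_r
    })
  }
  if (st$sex) {
    run_stage("sex", {
      sx <- sex_score(modc, sim$truth$sex_cpgs$male_hyper,
                      sim$truth$sex_cpgs$male_hypo)
      data.table::fwrite(sx, file.path(out_dir, "sex_scores.csv"))
      truth_sex <- sim$sheet$sex[match(sx$sample_id, sim$sheet$sample_id)]
      summary$sex_accuracy <- mean(sx$predicted_sex == truth_sex)
    })
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
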