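# Core one-vs-rest rank statistics for a single probe/feature.
# Midrank U statistic; exact two-sided p (pwilcox) when both sides <= 10
# and no ties, else normal approximation with tie correction and
# continuity correction.
ovr_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nties <- table(r)
  has_ties <- any(nties > 1)
  if (!has_ties && max(n1, n2) <= 10) {
    p <- if (U > n1 * n2 / 2) {
      2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * pwilcox(U, n1, n2)
    }
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    sig2 <- (n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      cc <- sign(z) * 0.5
      p <- min(1, 2 * pnorm(-abs((z - cc) / sqrt(sig2))))
    }
  }
  c(U = U, p = p, auc = U / (n1 * n2))
}

#' One-vs-rest differentially methylated marker discovery
#'
#' For each probe, tests the target group against the pooled remainder with
#' a two-sided Wilcoxon rank-sum test (midranks; exact null distribution
#' when both sides have <= 10 samples and no ties, otherwise normal
#' approximation with tie and continuity corrections). The discriminative
#' effect is summarized by AUC = U / (n1 n2) (> 0.5 means the target tends
#' higher) and the effect size by delta beta = mean(target) - mean(rest).
#' Probes with NA in more than `max_na_target` of the target group or more
#' than `max_na_rest` of the rest are dropped before testing. A probe is
#' selected as a marker when AUC >= `min_auc` or AUC <= 1 - `min_auc`
#' (distance from 0.5, so hypomethylated markers qualify symmetrically) and
#' |delta beta| >= `min_delta`. With `cap`, markers are ranked by (AUC
#' distance from 0.5, |delta|, probe_id) and picked alternately from the
#' hyper and hypo lists while both are non-empty, so directions stay
#' balanced when possible.
#'
#' @param bm beta (or any numeric feature) matrix, features x samples.
#' @param groups character vector of group labels, one per column of `bm`
#'   (or named by sample ID).
#' @param target the group label to contrast against the rest.
#' @param min_auc AUC selection threshold (default 0.8).
#' @param min_delta |delta beta| selection threshold (default 0.2).
#' @param max_na_target max NA fraction tolerated in the target group.
#' @param max_na_rest max NA fraction tolerated in the rest group.
#' @param cap optional maximum number of selected markers.
#' @param min_n minimum usable samples required on each side (default 2).
#' @return data.frame with per-probe statistics (probe_id, contrast, U,
#'   p_value, q_value, auc, delta_beta, direction, n_target_used,
#'   n_rest_used) and a logical `selected` column marking the final marker
#'   set; NULL (with a warning) when either side has too few samples.
#' @export
one_vs_rest_markers <- function(bm, groups, target, min_auc = 0.8,
                                min_delta = 0.2, max_na_target = 0.10,
                                max_na_rest = 0.50, cap = NULL, min_n = 2) {
  if (!is.null(names(groups))) groups <- groups[colnames(bm)]
  stopifnot(length(groups) == ncol(bm))
  if (!target %in% groups) stop("target label not present: ", target)
  in_t <- which(groups == target)
  in_r <- which(groups != target)
  if (length(in_t) < min_n || length(in_r) < min_n) {
    warning("contrast ", target, " skipped: fewer than ", min_n,
            " samples on one side")
    return(NULL)
  }
  res <- vector("list", nrow(bm))
  for (i in seq_len(nrow(bm))) {
    xt <- bm[i, in_t]; xr <- bm[i, in_r]
    na_t <- mean(is.na(xt)); na_r <- mean(is.na(xr))
    if (na_t > max_na_target || na_r > max_na_rest) next
    xt <- xt[!is.na(xt)]; xr <- xr[!is.na(xr)]
    if (length(xt) < min_n || length(xr) < min_n) next
    st <- ovr_test(xt, xr)
    res[[i]] <- data.frame(
      probe_id = rownames(bm)[i], contrast = target,
      U = st[["U"]], p_value = st[["p"]], auc = st[["auc"]],
      delta_beta = mean(xt) - mean(xr),
      n_target_used = length(xt), n_rest_used = length(xr)
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    warning("no probes passed the NA filters for contrast ", target)
    return(NULL)
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$delta_beta > 0, "hyper", "hypo")
  pass <- (out$auc >= min_auc | out$auc <= 1 - min_auc) &
    abs(out$delta_beta) >= min_delta
  out$selected <- pass
  if (!is.null(cap) && sum(pass) > cap) {
    out$selected <- apply_marker_cap(out, cap)
  }
  rownames(out) <- NULL
  out[, c("probe_id", "contrast", "U", "p_value", "q_value", "auc",
          "delta_beta", "direction", "n_target_used", "n_rest_used",
          "selected")]
}

# deterministic capped selection with hyper/hypo balancing
apply_marker_cap <- function(out, cap) {
  cand <- which(out$selected)
  ord_key <- function(idx) {
    idx[order(-abs(out$auc[idx] - 0.5), -abs(out$delta_beta[idx]),
              out$probe_id[idx])]
  }
  hyper <- ord_key(cand[out$direction[cand] == "hyper"])
  hypo <- ord_key(cand[out$direction[cand] == "hypo"])
  picked <- integer(0)
  take_hyper <- TRUE
  while (length(picked) < cap && (length(hyper) > 0 || length(hypo) > 0)) {
    if ((take_hyper && length(hyper) > 0) || length(hypo) == 0) {
      picked <- c(picked, hyper[1]); hyper <- hyper[-1]
    } else {
      picked <- c(picked, hypo[1]); hypo <- hypo[-1]
    }
    take_hyper <- !take_hyper
  }
  sel <- rep(FALSE, nrow(out))
  sel[picked] <- TRUE
  sel
}

#' Run one-vs-rest marker discovery for every group
#'
#' @inheritParams one_vs_rest_markers
#' @param ... passed to [one_vs_rest_markers()].
#' @return named list of per-contrast data.frames.
#' @export
all_contrasts <- function(bm, groups, ...) {
  labs <- unique(if (!is.null(names(groups))) groups[colnames(bm)] else groups)
  res <- lapply(labs, function(g) one_vs_rest_markers(bm, groups, g, ...))
  names(res) <- labs
  res[!vapply(res, is.null, TRUE)]
}

#' Hierarchical one-vs-rest contrasts
#'
#' Applies one-vs-rest marker discovery at each level of a nested grouping:
#' at the top level across all samples, then within each parent group using
#' only its samples and the child labels as contrasts (subtype markers are
#' discovered against their sibling set only).
#'
#' @param bm beta matrix.
#' @param tree data.frame with `sample_id` followed by one column per
#'   level, ordered coarse to fine.
#' @param ... thresholds passed to [one_vs_rest_markers()].
#' @return nested list: level -> node -> contrast -> result data.frame.
#' @export
hierarchical_contrasts <- function(bm, tree, ...) {
  if (!"sample_id" %in% names(tree)) stop("tree needs a sample_id column")
  levels_cols <- setdiff(names(tree), "sample_id")
  tree <- tree[match(colnames(bm), tree$sample_id), , drop = FALSE]
  if (anyNA(tree$sample_id)) stop("samples missing from tree")
  # consistency: each fine label must map to exactly one parent label
  for (li in seq_along(levels_cols)[-1]) {
    tab <- unique(tree[, levels_cols[c(li - 1, li)]])
    if (anyDuplicated(tab[[2]])) stop("non-tree label structure: a label at level ",
                                      li, " has multiple parents")
  }
  res <- list()
  res[[levels_cols[1]]] <- list(root = all_contrasts(bm, tree[[levels_cols[1]]], ...))
  for (li in seq_along(levels_cols)[-1]) {
    parent_col <- levels_cols[li - 1]; child_col <- levels_cols[li]
    nodes <- list()
    for (par in unique(tree[[parent_col]])) {
      cols <- which(tree[[parent_col]] == par)
      sibs <- unique(tree[[child_col]][cols])
      if (length(sibs) < 2) next  # no sibling contrast possible
      nodes[[par]] <- all_contrasts(bm[, cols, drop = FALSE],
                                    tree[[child_col]][cols], ...)
    }
    res[[child_col]] <- nodes
  }
  res
}

#' Constitutively unmodified / modified probe screen
#'
#' A probe is constitutively unmodified when every non-NA beta is below
#' `lo` across all samples, and constitutively modified when every non-NA
#' beta is above `hi`. All-NA probes are excluded from both lists.
#'
#' @param bm beta matrix.
#' @param lo unmodified threshold (default 0.2).
#' @param hi modified threshold (default 0.8).
#' @return list with `unmodified` and `modified` probe ID vectors.
#' @export
constitutive_screen <- function(bm, lo = 0.2, hi = 0.8) {
  n_ok <- rowSums(!is.na(bm))
  all_lo <- rowSums(bm < lo, na.rm = TRUE) == n_ok & n_ok > 0
  all_hi <- rowSums(bm > hi, na.rm = TRUE) == n_ok & n_ok > 0
  list(unmodified = rownames(bm)[all_lo], modified = rownames(bm)[all_hi])
}

#' Intermediate-methylation probe screen
#'
#' Retains probes whose betas lie strictly inside (`lo`, `hi`) in at least
#' `min_frac_samples` of the non-NA samples — candidates for monoallelic /
#' imprinted methylation near 0.5. `per_sample_means = TRUE` gives the
#' design-time variant operating on per-sample mean methylation with an
#' absolute sample-count threshold via `min_n_samples` (e.g. 140 of 180).
#'
#' @param bm beta matrix (or matrix of per-sample means).
#' @param lo,hi open interval bounds (defaults 0.3, 0.7).
#' @param min_frac_samples required fraction of non-NA samples inside the
#'   interval (default 1.0 = all samples).
#' @param min_n_samples optional absolute count threshold; when set it
#'   overrides `min_frac_samples` and counts samples inside the interval
#'   against this number.
#' @return character vector of retained probe IDs.
#' @export
intermediate_screen <- function(bm, lo = 0.3, hi = 0.7,
                                min_frac_samples = 1.0, min_n_samples = NULL) {
  inside <- rowSums(bm > lo & bm < hi, na.rm = TRUE)
  n_ok <- rowSums(!is.na(bm))
  keep <- if (!is.null(min_n_samples)) {
    inside >= min_n_samples
  } else {
    n_ok > 0 & inside >= min_frac_samples * n_ok
  }
  rownames(bm)[keep]
}

#' Rank probes by cross-sample variability
#'
#' Sample standard deviation (n-1 denominator) over non-NA betas, sorted
#' descending (ties broken by probe ID); the ranked list feeds set
#' enrichment of trait probes against inter-individual variability.
#'
#' @param bm beta matrix.
#' @param manifest optional manifest (needed for the autosome filter).
#' @param chrom_filter "autosomes" to drop chrX/chrY probes, or NULL.
#' @return data.frame (probe_id, sd) in rank order.
#' @export
variability_rank <- function(bm, manifest = NULL, chrom_filter = NULL) {
  if (!is.null(chrom_filter)) {
    chrom_filter <- match.arg(chrom_filter, "autosomes")
    if (is.null(manifest)) stop("chrom_filter requires a manifest")
    chrom <- manifest$chrom[match(rownames(bm), manifest$probe_id)]
    bm <- bm[!chrom %in% c("chrX", "chrY", "X", "Y"), , drop = FALSE]
  }
  sds <- apply(bm, 1, sd, na.rm = TRUE)
  ord <- order(-sds, rownames(bm))
  data.frame(probe_id = rownames(bm)[ord], sd = sds[ord], row.names = NULL)
}

#' Tissue-specific feature selection on arbitrary numeric tables
#'
#' The one-vs-rest machinery applied to any features x groups table (e.g.
#' genes x tissues TPM): per group, features with AUC >= `min_auc` (distance
#' from 0.5) and |delta| >= `min_delta` on the table's own scale are
#' selected. Columns are the observations, so single-column groups use the
#' per-group values directly (one observation per group).
#'
#' @param expr numeric matrix, features x observation columns.
#' @param groups group label per column (defaults to the column names, one
#'   group per column).
#' @param min_auc AUC threshold (default 0.8).
#' @param min_delta effect threshold on the table's scale (default 1.0).
#' @return named list of per-group selected feature data.frames.
#' @export
tissue_specific_features <- function(expr, groups = colnames(expr),
                                     min_auc = 0.8, min_delta = 1.0) {
  res <- lapply(unique(groups), function(g) {
    r <- one_vs_rest_markers(expr, groups, g, min_auc = min_auc,
                             min_delta = min_delta, max_na_target = 0,
                             max_na_rest = 0, min_n = 1)
    if (is.null(r)) return(NULL)
    r[r$selected, , drop = FALSE]
  })
  names(res) <- unique(groups)
  res[!vapply(res, is.null, TRUE)]
}
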