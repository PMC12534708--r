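# 2x2 odds ratio with 0.5 continuity correction only when a zero cell
# occurs; a degenerate margin (annotation empty or equal to the universe,
# or likewise for the query) carries no association signal, so OR = 1
odds_ratio_cc <- function(a, b, c, d) {
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Probe-set enrichment by one-sided hypergeometric test
#'
#' Tests a query probe set for over-representation in each annotation set,
#' against a stated universe (all probes on the platform in the headline
#' analyses). The 2x2 table per annotation is: a = query & annotation,
#' b = query only, c = annotation only, d = neither; the one-sided p-value
#' is P(overlap >= a) under the hypergeometric null, and q-values are
#' Benjamini-Hochberg across the annotation family.
#'
#' @param query character vector of probe IDs (must be within universe).
#' @param annotations named list of probe ID vectors (intersected with the
#'   universe).
#' @param universe character vector, the background probe set.
#' @return data.frame (annotation, a, b, c, d, odds_ratio, log2_or,
#'   p_value, q_value).
#' @export
fisher_set_enrichment <- function(query, annotations, universe) {
  query <- intersect(query, universe)
  if (length(query) == 0) stop("query empty after universe intersection")
  N <- length(universe)
  nq <- length(query)
  res <- lapply(names(annotations), function(an) {
    ann <- intersect(annotations[[an]], universe)
    K <- length(ann)
    a <- length(intersect(query, ann))
    b <- nq - a
    c <- K - a
    d <- N - nq - c
    or <- odds_ratio_cc(a, b, c, d)
    p <- phyper(a - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(annotation = an, a = a, b = b, c = c, d = d,
               odds_ratio = or, log2_or = log2(or), p_value = p)
  })
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

# expand intervals by +/- bp, clamped at 0 (half-open coordinates)
expand_intervals <- function(ivs, bp) {
  ivs$start <- pmax(0L, ivs$start - bp)
  ivs$end <- ivs$end + bp
  ivs
}

# which rows of `a` overlap any interval of `b` (half-open, per chromosome)
overlaps_any <- function(a, b) {
  hit <- logical(nrow(a))
  for (cc in unique(a$chrom)) {
    ai <- which(a$chrom == cc)
    bi <- which(b$chrom == cc)
    if (length(bi) == 0) next
    qr <- IRanges::IRanges(start = a$start[ai] + 1L, end = a$end[ai])
    sr <- IRanges::IRanges(start = b$start[bi] + 1L, end = b$end[bi])
    hit[ai] <- IRanges::overlapsAny(qr, sr)
  }
  hit
}

#' Genomic colocalization of interval sets (e.g. GWAS SNPs vs marker CpGs)
#'
#' Both the query intervals and each feature interval set are expanded by
#' `expand_bp` on each side (clamped at 0); an overlap is any shared base
#' under half-open semantics. Counts of overlapping vs non-overlapping
#' universe intervals feed the same 2x2 machinery as
#' [fisher_set_enrichment()], with the universe being the full collection
#' of query-side intervals (e.g. all tissue-signature CpG intervals).
#'
#' @param query_intervals data.frame (chrom, start, end, name) — the
#'   interval subset being tested.
#' @param feature_intervals named list of interval data.frames (e.g. one
#'   per GWAS trait).
#' @param universe_intervals data.frame of all query-side intervals.
#' @param expand_bp symmetric expansion in bp (default 5000).
#' @return data.frame as in [fisher_set_enrichment()].
#' @export
interval_colocalization <- function(query_intervals, feature_intervals,
                                    universe_intervals, expand_bp = 5000) {
  uchr <- unique(universe_intervals$chrom)
  for (an in names(feature_intervals)) {
    bad <- setdiff(unique(feature_intervals[[an]]$chrom), uchr)
    if (length(bad) > 0) {
      stop("chromosome names in '", an, "' absent from universe: ",
           paste(bad, collapse = ", "))
    }
  }
  uni <- expand_intervals(universe_intervals, expand_bp)
  in_query <- uni$name %in% query_intervals$name
  if (!any(in_query)) stop("query intervals absent from universe")
  res <- lapply(names(feature_intervals), function(an) {
    feat <- expand_intervals(feature_intervals[[an]], expand_bp)
    hit <- overlaps_any(uni, feat)
    a <- sum(hit & in_query)
    b <- sum(!hit & in_query)
    c <- sum(hit & !in_query)
    d <- sum(!hit & !in_query)
    or <- odds_ratio_cc(a, b, c, d)
    K <- a + c
    p <- phyper(a - 1, K, b + d, a + b, lower.tail = FALSE)
    data.frame(annotation = an, a = a, b = b, c = c, d = d,
               odds_ratio = or, log2_or = log2(or), p_value = p)
  })
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

# running-sum enrichment score from hit positions (1-based) in a list of
# length N: +1/|Q| at hits, -1/(N-|Q|) at misses; signed max deviation
es_from_positions <- function(pos, N) {
  q <- length(pos)
  pos <- sort(pos)
  i <- seq_len(q)
  at_hit <- i / q - (pos - i) / (N - q)        # just after each hit
  before_hit <- (i - 1) / q - (pos - i) / (N - q)  # just before each hit
  mx <- max(at_hit)
  mn <- min(before_hit, 0)
  if (mx >= -mn) mx else mn
}

#' Ranked-list set enrichment with a permutation null
#'
#' Unweighted Kolmogorov-Smirnov style enrichment of a probe set within a
#' ranked probe list: the running sum gains 1/|Q| at each query member and
#' loses 1/(N-|Q|) elsewhere; the enrichment score ES is the signed maximum
#' deviation (ES = 1 when the query occupies the top of the list). The
#' p-value is estimated by uniformly permuting query membership:
#' p = (1 + #{|ES*| >= |ES|}) / (n_permutations + 1). When the positive and
#' negative extremes of the running sum tie in magnitude, the positive
#' score is reported.
#'
#' @param ranked_probes probe IDs in rank order (best first).
#' @param query probe set, subset of `ranked_probes`, non-empty and proper.
#' @param n_permutations number of membership permutations (default 1000).
#' @param seed RNG seed (mandatory).
#' @return list (es, p_value, n_permutations, n_query).
#' @export
ranked_set_enrichment <- function(ranked_probes, query, n_permutations = 1000,
                                  seed) {
  if (missing(seed)) stop("seed is mandatory")
  N <- length(ranked_probes)
  pos <- which(ranked_probes %in% query)
  q <- length(pos)
  if (q == 0 || q == N) stop("query must be a non-empty proper subset of the ranked list")
  es <- es_from_positions(pos, N)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    es_from_positions(sample.int(N, q), N)
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(es))) / (n_permutations + 1)
  list(es = es, p_value = p, n_permutations = n_permutations, n_query = q)
}

#' Tissue-context analysis of trait-associated CpGs by beta-value ranks
#'
#' For each trait CpG, samples are ranked by beta (midranks for ties) and
#' each tissue's mean rank over its samples is computed; pooling those
#' per-CpG tissue mean ranks gives one distribution per tissue. Differences
#' across tissues are tested by Kruskal-Wallis (tie-corrected) and Dunn's
#' rank-sum z post hoc with Benjamini-Hochberg adjustment.
#'
#' @param bm beta matrix.
#' @param trait_probes probe IDs of the trait set (intersected with `bm`).
#' @param groups tissue label per sample (named by sample ID or in column
#'   order).
#' @return list with `mean_ranks` (data.frame tissue, probe_id, mean_rank),
#'   `kruskal` (statistic, df, p_value), `dunn` (pairwise z, p, q).
#' @export
tissue_rank_context <- function(bm, trait_probes, groups) {
  if (!is.null(names(groups))) groups <- groups[colnames(bm)]
  probes <- intersect(trait_probes, rownames(bm))
  if (length(probes) == 0) stop("no trait probes present in the matrix")
  keep <- !is.na(groups)
  sub <- bm[probes, keep, drop = FALSE]
  grp <- groups[keep]
  tissues <- unique(grp)
  rows <- list()
  for (p in probes) {
    rk <- rank(sub[p, ], na.last = "keep")
    mr <- tapply(rk, grp, mean, na.rm = TRUE)
    rows[[p]] <- data.frame(tissue = names(mr), probe_id = p,
                            mean_rank = as.numeric(mr), row.names = NULL)
  }
  mean_ranks <- do.call(rbind, rows)
  mean_ranks <- mean_ranks[!is.na(mean_ranks$mean_rank), ]
  kw <- kruskal.test(mean_ranks$mean_rank, factor(mean_ranks$tissue))
  dunn <- dunn_test(mean_ranks$mean_rank, factor(mean_ranks$tissue))
  list(mean_ranks = mean_ranks,
       kruskal = data.frame(statistic = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p_value = kw$p.value),
       dunn = dunn)
}

#' Dunn's post-hoc pairwise rank-sum test
#'
#' Standard Dunn z statistics on the pooled ranks with tie correction,
#' two-sided p-values and Benjamini-Hochberg adjustment across pairs.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @return data.frame (group1, group2, z, p_value, q_value).
#' @export
dunn_test <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(factor(g[ok]))
  n <- length(x)
  rk <- rank(x)
  nties <- table(rk)
  tie_corr <- sum(nties^3 - nties) / (12 * (n - 1))
  mean_rk <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_rk[[i]] - mean_rk[[j]]) / se
    data.frame(group1 = i, group2 = j, z = z,
               p_value = 2 * pnorm(-abs(z)))
  })
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Link probes to genes by windowed interval overlap
#'
#' A probe is linked to every gene whose interval overlaps the probe
#' interval expanded by `window_bp` on each side (half-open semantics,
#' clamped at 0); many-to-many links are allowed.
#'
#' @param manifest probe manifest (chrom, start, end, probe_id).
#' @param genes interval data.frame (chrom, start, end, name).
#' @param window_bp symmetric window around the probe (e.g. 10000 for
#'   marker-gene linking, 50000 for correlation pairing).
#' @return data.frame (probe_id, gene).
#' @export
link_probes_to_genes <- function(manifest, genes, window_bp) {
  if (any(genes$start > genes$end) || any(genes$start < 0)) {
    stop("malformed gene intervals")
  }
  out <- list()
  for (cc in unique(manifest$chrom)) {
    mi <- which(manifest$chrom == cc)
    gi <- which(genes$chrom == cc)
    if (length(gi) == 0) next
    pr <- IRanges::IRanges(start = pmax(0L, manifest$start[mi] - window_bp) + 1L,
                           end = manifest$end[mi] + window_bp)
    gr <- IRanges::IRanges(start = genes$start[gi] + 1L, end = genes$end[gi])
    ov <- IRanges::findOverlaps(pr, gr)
    if (length(ov) == 0) next
    out[[cc]] <- data.frame(
      probe_id = manifest$probe_id[mi][S4Vectors::queryHits(ov)],
      gene = genes$name[gi][S4Vectors::subjectHits(ov)]
    )
  }
  if (length(out) == 0) {
    return(data.frame(probe_id = character(0), gene = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate per-tissue CpG methylation with gene expression
#'
#' For each (probe, gene) pair, the Pearson correlation of per-tissue mean
#' betas with per-tissue expression across shared tissues, with the
#' two-sided t-test p-value. Pairs with fewer than 3 complete tissue pairs
#' or zero variance on either side are emitted with NA.
#'
#' @param bm_by_group matrix of per-tissue mean betas (probes x tissues).
#' @param expr expression matrix (genes x tissues), same tissue columns.
#' @param pairs data.frame (probe_id, gene).
#' @return data.frame (probe_id, gene, r, p_value, n_tissues).
#' @export
cpg_gene_correlation <- function(bm_by_group, expr, pairs) {
  tissues <- intersect(colnames(bm_by_group), colnames(expr))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs$probe_id[i]; g <- pairs$gene[i]
    row <- data.frame(probe_id = p, gene = g, r = NA_real_,
                      p_value = NA_real_, n_tissues = 0L)
    if (!p %in% rownames(bm_by_group) || !g %in% rownames(expr)) return(row)
    b <- bm_by_group[p, tissues]; e <- expr[g, tissues]
    ok <- !is.na(b) & !is.na(e)
    row$n_tissues <- sum(ok)
    if (sum(ok) < 3 || sd(b[ok]) == 0 || sd(e[ok]) == 0) return(row)
    ct <- cor.test(b[ok], e[ok], method = "pearson")
    row$r <- unname(ct$estimate); row$p_value <- ct$p.value
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
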