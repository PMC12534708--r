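#' Collapse replicate probes to one row per replicate group
#'
#' Arrays may carry several probe designs targeting the same genomic CpG;
#' designs in a group share an ID prefix and differ in suffix (chemistry /
#' strand). Methylation is averaged over the non-NA replicate betas of each
#' group; an all-NA group yields NA. Output rows are named by the prefix, so
#' the operation is idempotent (singleton groups pass through).
#'
#' @param bm beta matrix with probe IDs as rownames.
#' @param manifest manifest data.frame with `probe_id` and
#'   `replicate_prefix` columns covering every probe in `bm`.
#' @param method collapsing method; only "mean" is provided (selection by
#'   signal intensity requires raw intensities, unavailable at beta level).
#' @return beta matrix with one row per replicate prefix.
#' @export
collapse_replicates <- function(bm, manifest, method = c("mean")) {
  method <- match.arg(method)
  idx <- match(rownames(bm), manifest$probe_id)
  if (anyNA(idx)) {
    stop("probes missing from manifest: ",
         paste(head(rownames(bm)[is.na(idx)], 3), collapse = ", "))
  }
  prefix <- manifest$replicate_prefix[idx]
  if (is.null(prefix)) stop("manifest lacks replicate_prefix")
  groups <- split(seq_len(nrow(bm)), prefix)
  out <- matrix(NA_real_, length(groups), ncol(bm),
                dimnames = list(names(groups), colnames(bm)))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- bm[rows, ]
    } else {
      out[g, ] <- colMeans(bm[rows, , drop = FALSE], na.rm = TRUE)
    }
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Within-sample standard deviation of replicate probe groups
#'
#' For each replicate group (>= 2 probes) the sample SD (n-1 denominator) of
#' its betas is taken within every sample, then averaged over samples. As a
#' contrast, the same statistic is computed for randomly paired
#' non-replicate probes, giving the background disagreement level that
#' replicate probes should sit far below.
#'
#' @param bm beta matrix.
#' @param manifest manifest with `replicate_prefix`.
#' @param n_background number of random non-replicate pairs for the
#'   contrast distribution.
#' @param seed RNG seed for the background pairing.
#' @return list with `replicate` (data.frame prefix, mean_sd, n_probes) and
#'   `background_sd` (numeric vector of non-replicate pair SDs).
#' @export
replicate_sd_profile <- function(bm, manifest, n_background = 1000, seed = 1) {
  idx <- match(rownames(bm), manifest$probe_id)
  prefix <- manifest$replicate_prefix[idx]
  groups <- split(seq_len(nrow(bm)), prefix)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (length(groups) == 0) {
    warning("no replicate groups with >= 2 probes")
    return(list(replicate = data.frame(prefix = character(), mean_sd = numeric(),
                                       n_probes = integer()),
                background_sd = numeric()))
  }
  mean_sd <- vapply(groups, function(rows) {
    sds <- apply(bm[rows, , drop = FALSE], 2, sd, na.rm = TRUE)
    mean(sds, na.rm = TRUE)
  }, numeric(1))
  rep_df <- data.frame(prefix = names(groups), mean_sd = unname(mean_sd),
                       n_probes = vapply(groups, length, 1L), row.names = NULL)

  set.seed(seed)
  grp_of <- prefix
  bg <- numeric(0)
  if (nrow(bm) >= 2) {
    i <- sample.int(nrow(bm), n_background, replace = TRUE)
    j <- sample.int(nrow(bm), n_background, replace = TRUE)
    keep <- i != j & grp_of[i] != grp_of[j]
    i <- i[keep]; j <- j[keep]
    bg <- vapply(seq_along(i), function(k) {
      sds <- apply(bm[c(i[k], j[k]), , drop = FALSE], 2, sd, na.rm = TRUE)
      mean(sds, na.rm = TRUE)
    }, numeric(1))
  }
  list(replicate = rep_df, background_sd = bg)
}

# count CG dinucleotides in a sequence by sliding window (overlaps counted)
count_cg <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < 2) return(0L)
  sum(chars[-length(chars)] == "C" & chars[-1] == "G")
}

#' Probe-sequence quality filters
#'
#' Flags probe designs likely to hybridize unreliably: sequences with more
#' than six CG dinucleotides besides the assayed CpG (variable methylation
#' of neighbors interferes with hybridization) and sequences carrying a
#' common SNP within 5 nt of the 3' end (offset 1 = terminal base). Both
#' failure reasons can co-occur. Decisions depend only on the sequence and
#' SNP offsets, never on measured betas.
#'
#' @param manifest manifest data.frame; needs `sequence` and/or the
#'   precomputed columns `cpg_count_extra` and `snp_offsets_from_3prime`.
#' @param max_extra_cpg maximum tolerated additional CpGs (default 6).
#' @param snp_window_nt 3'-end window within which a SNP disqualifies the
#'   probe (default 5; offsets 1..5 fail).
#' @return data.frame (probe_id, pass, reasons); `reasons` is a list column
#'   of character vectors.
#' @export
probe_sequence_qc <- function(manifest, max_extra_cpg = 6, snp_window_nt = 5) {
  n <- nrow(manifest)
  has_seq <- "sequence" %in% names(manifest)
  has_cpg <- "cpg_count_extra" %in% names(manifest)
  has_snp <- "snp_offsets_from_3prime" %in% names(manifest)
  if (!has_seq && !has_cpg && !has_snp) {
    stop("probe_sequence_qc: need 'sequence' or precomputed 'cpg_count_extra'/",
         "'snp_offsets_from_3prime' columns")
  }
  extra_cpg <- if (has_cpg) {
    manifest$cpg_count_extra
  } else if (has_seq) {
    # the assayed CpG is itself one CG occurrence in the 50-mer
    vapply(manifest$sequence, function(s) max(0L, count_cg(s) - 1L), 1L,
           USE.NAMES = FALSE)
  } else {
    rep(NA_integer_, n)
  }
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character(0)
    if (!is.na(extra_cpg[i]) && extra_cpg[i] > max_extra_cpg) r <- c(r, "excess_cpg")
    if (has_snp) {
      offs <- manifest$snp_offsets_from_3prime[[i]]
      if (length(offs) > 0 && any(offs <= snp_window_nt & offs >= 1)) {
        r <- c(r, "snp_3prime")
      }
    }
    reasons[[i]] <- r
  }
  data.frame(probe_id = manifest$probe_id,
             pass = lengths(reasons) == 0L,
             reasons = I(reasons), row.names = NULL)
}
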