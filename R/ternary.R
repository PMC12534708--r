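#' Decompose matched 5modC and 5hmC betas into the ternary code
#'
#' Standard bisulfite conversion measures total modification (5modC = 5mC +
#' 5hmC); a matched APOBEC-based experiment measures 5hmC directly. True
#' 5mC is recovered by subtraction, and the unmodified fraction closes the
#' composition: `5mC = max(0, 5modC - 5hmC)`, `C = max(0, 1 - 5modC)`,
#' then C absorbs the remainder so 5mC + 5hmC + C = 1 per cell. Cells where
#' measurement noise drove 5modC - 5hmC negative are clamped to 0 and
#' flagged (not renormalized), keeping the 5hmC measurement as-is and the
#' violation auditable. NA in either input propagates to all components.
#'
#' @param modc beta matrix of total modification.
#' @param hmc matched beta matrix of 5hmC; same probes. Columns are paired
#'   via `pairs` (modc sample -> hmc sample); by default matched by
#'   identical column names.
#' @param pairs optional named character vector mapping modc sample IDs to
#'   hmc sample IDs.
#' @return object of class `ternary_profile`: list with matrices `five_mC`,
#'   `five_hmC`, `unmod_C` (indexed by modc sample IDs) and logical
#'   `clamped_mask`.
#' @export
ternary_decompose <- function(modc, hmc, pairs = NULL) {
  if (!setequal(rownames(modc), rownames(hmc))) {
    stop("modc and hmc must share probes")
  }
  hmc <- hmc[rownames(modc), , drop = FALSE]
  if (is.null(pairs)) {
    missing_s <- setdiff(colnames(modc), colnames(hmc))
    if (length(missing_s) > 0) {
      stop("unpaired samples (no 5hmC match): ", paste(missing_s, collapse = ", "))
    }
    pairs <- setNames(colnames(modc), colnames(modc))
  } else {
    bad <- setdiff(names(pairs), colnames(modc))
    bad2 <- setdiff(pairs, colnames(hmc))
    if (length(bad) + length(bad2) > 0) {
      stop("unpaired samples: ", paste(c(bad, bad2), collapse = ", "))
    }
  }
  h <- hmc[, pairs[colnames(modc)], drop = FALSE]
  colnames(h) <- colnames(modc)
  na_mask <- is.na(modc) | is.na(h)
  five_mC <- modc - h
  clamped <- !na_mask & (five_mC < 0)
  five_mC[clamped] <- 0  # pmax would drop the matrix shape
  five_hmC <- h
  # closure by construction: C takes the remainder, and since 5hmC <= 1 and
  # 5mC = max(0, modc - hmc) <= 1 - hmc + hmc, C is never negative
  unmod_C <- 1 - five_mC - five_hmC
  for (m in c("five_mC", "five_hmC", "unmod_C")) {
    x <- get(m); x[na_mask] <- NA_real_; assign(m, x)
  }
  clamped[na_mask] <- FALSE
  structure(list(five_mC = five_mC, five_hmC = five_hmC, unmod_C = unmod_C,
                 clamped_mask = clamped),
            class = "ternary_profile")
}

#' @export
print.ternary_profile <- function(x, ...) {
  cat(sprintf("ternary_profile: %d probes x %d samples, %.3f%% clamped cells\n",
              nrow(x$five_mC), ncol(x$five_mC),
              100 * mean(x$clamped_mask)))
  invisible(x)
}

#' Fraction of cells clamped during decomposition
#' @param tp a `ternary_profile`.
#' @return scalar fraction of non-NA cells where 5modC - 5hmC was negative.
#' @export
clamped_fraction <- function(tp) {
  mean(tp$clamped_mask[!is.na(tp$five_mC)])
}

#' Global ternary means per sample group
#'
#' Per-group means of the three components over all non-NA cells; the three
#' means sum to 1 (within numerical tolerance) because the per-cell
#' composition closes to 1 and the same NA pattern applies to all three.
#'
#' @param tp a `ternary_profile`.
#' @param sheet sample sheet with `sample_id` and the grouping column.
#' @param group_by grouping column name (default "tissue").
#' @return data.frame (group, mean_5mC, mean_5hmC, mean_C, n_samples).
#' @export
global_ternary_means <- function(tp, sheet, group_by = "tissue") {
  samp <- colnames(tp$five_mC)
  grp <- sheet[[group_by]][match(samp, sheet$sample_id)]
  if (anyNA(grp)) stop("samples missing from sheet: ",
                       paste(head(samp[is.na(grp)], 3), collapse = ", "))
  levs <- unique(grp)
  res <- lapply(levs, function(g) {
    cols <- which(grp == g)
    if (length(cols) == 0) return(NULL)
    mC <- tp$five_mC[, cols, drop = FALSE]
    data.frame(group = g,
               mean_5mC = mean(mC, na.rm = TRUE),
               mean_5hmC = mean(tp$five_hmC[, cols, drop = FALSE], na.rm = TRUE),
               mean_C = mean(tp$unmod_C[, cols, drop = FALSE], na.rm = TRUE),
               n_samples = length(cols))
  })
  do.call(rbind, res)
}

#' Mean 5mC/(5mC + C) ratio by binned 5hmC level
#'
#' Bins cells by their 5hmC value (left-closed, right-open; last bin closed)
#' and reports the average `5mC / (5mC + C)` within each bin. A rising
#' profile indicates 5hmC accumulates preferentially on methylated
#' background, i.e. 5mC is the substrate for 5hmC deposition. Cells with
#' 5mC + C = 0 have an undefined ratio and are excluded.
#'
#' @param tp a `ternary_profile`.
#' @param bins increasing numeric bin edges covering \[0, 1\].
#' @return data.frame (bin_lo, bin_hi, mean_ratio, n_cells).
#' @export
ratio_by_hmc_bin <- function(tp, bins = seq(0, 1, by = 0.1)) {
  if (is.unsorted(bins, strictly = TRUE)) stop("bin edges must be strictly increasing")
  h <- as.vector(tp$five_hmC)
  m <- as.vector(tp$five_mC)
  c0 <- as.vector(tp$unmod_C)
  keep <- !is.na(h) & !is.na(m) & !is.na(c0) & (m + c0) > 0
  h <- h[keep]; ratio <- m[keep] / (m[keep] + c0[keep])
  idx <- findInterval(h, bins, rightmost.closed = TRUE, all.inside = FALSE)
  idx[idx == length(bins)] <- length(bins) - 1L  # closed last bin
  valid <- idx >= 1L & idx <= length(bins) - 1L
  res <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1])
  agg_mean <- tapply(ratio[valid], factor(idx[valid], levels = seq_len(length(bins) - 1L)), mean)
  agg_n <- tapply(ratio[valid], factor(idx[valid], levels = seq_len(length(bins) - 1L)), length)
  res$mean_ratio <- as.numeric(agg_mean)
  res$n_cells <- ifelse(is.na(agg_n), 0L, as.integer(agg_n))
  res
}

#' Write ternary profile matrices to disk
#' @param tp a `ternary_profile`.
#' @param dir output directory (created if needed).
#' @export
write_ternary <- function(tp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(tp$five_mC, file.path(dir, "five_mC.tsv"))
  write_beta_matrix(tp$five_hmC, file.path(dir, "five_hmC.tsv"))
  write_beta_matrix(tp$unmod_C, file.path(dir, "unmod_C.tsv"))
  cm <- tp$clamped_mask * 1
  storage.mode(cm) <- "double"
  write_beta_matrix(cm, file.path(dir, "clamped_mask.tsv"))
  invisible(dir)
}
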