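#' Build a cross-platform nearest-neighbor probe map
#'
#' For each query (legacy-only) site, finds the retained (new-platform)
#' site with the lowest Euclidean distance across the reference-sample
#' vectors (NA cells mean-imputed per probe beforehand, since distances
#' need complete vectors) and records its cross-sample Pearson correlation.
#' A query is `retained` for downstream substitution only when r strictly
#' exceeds `r_min`. Distance ties are broken by higher r, then probe ID.
#' The search is exhaustive over all retained sites, which is exactly the
#' lowest-distance semantics a k-NN graph (k-candidate) construction
#' approximates.
#'
#' @param reference beta matrix over the reference methylome collection,
#'   covering both site lists (probes x samples, >= 3 samples).
#' @param retained_sites probe IDs available on the new platform.
#' @param query_sites probe IDs to map (absent from the new platform).
#' @param k number of nearest candidates considered per query (candidates
#'   beyond the single best neighbor only matter for tie-breaking; kept for
#'   interface compatibility with graph-based construction).
#' @param r_min correlation gate; neighbor kept only if r > r_min.
#' @return data.frame (query_id, neighbor_id, distance, r, retained).
#' @export
build_neighbor_map <- function(reference, retained_sites, query_sites,
                               k = 50, r_min = 0.5) {
  if (k < 1) stop("k must be >= 1")
  if (ncol(reference) < 3) stop("need >= 3 reference samples")
  missing_q <- setdiff(query_sites, rownames(reference))
  if (length(missing_q) > 0) {
    warning(length(missing_q), " query site(s) absent from reference, skipped: ",
            paste(head(missing_q, 3), collapse = ", "))
    query_sites <- setdiff(query_sites, missing_q)
  }
  missing_r <- setdiff(retained_sites, rownames(reference))
  if (length(missing_r) > 0) stop("retained sites absent from reference")

  imp <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx) > 0) m[idx] <- mu[idx[, 1]]
    m
  }
  R <- imp(reference[retained_sites, , drop = FALSE])
  Q <- imp(reference[query_sites, , drop = FALSE])

  # squared distances via the cross-product expansion, blocked over queries
  r2 <- rowSums(R^2)
  Rc <- R - rowMeans(R)
  Rn <- sqrt(rowSums(Rc^2))
  out <- vector("list", length(query_sites))
  block <- 512L
  for (s in seq(1, length(query_sites), by = block)) {
    e <- min(s + block - 1L, length(query_sites))
    Qb <- Q[s:e, , drop = FALSE]
    D2 <- outer(rowSums(Qb^2), r2, "+") - 2 * Qb %*% t(R)
    D2[D2 < 0] <- 0
    for (bi in seq_len(nrow(Qb))) {
      qi <- s + bi - 1L
      d <- D2[bi, ]
      # self-match allowed only if the query is literally retained
      if (query_sites[qi] %in% retained_sites) {
        best <- which(retained_sites == query_sites[qi])[1]
      } else {
        dmin <- min(d)
        cand <- which(d <= dmin + 1e-12)
        if (length(cand) > 1) {
          qc <- Qb[bi, ] - mean(Qb[bi, ])
          rs <- as.vector(Rc[cand, , drop = FALSE] %*% qc) /
            (Rn[cand] * sqrt(sum(qc^2)))
          rs[!is.finite(rs)] <- -Inf
          cand <- cand[order(-rs, retained_sites[cand])]
        }
        best <- cand[1]
      }
      qc <- Qb[bi, ] - mean(Qb[bi, ])
      denom <- Rn[best] * sqrt(sum(qc^2))
      r <- if (denom > 0) sum(Rc[best, ] * qc) / denom else NA_real_
      out[[qi]] <- data.frame(query_id = query_sites[qi],
                              neighbor_id = retained_sites[best],
                              distance = sqrt(d[best]), r = r,
                              retained = !is.na(r) && r > r_min)
    }
  }
  do.call(rbind, out)
}

#' Substitute neighbor betas for missing legacy probes
#'
#' Projects a new-platform beta matrix onto a legacy probe space: wanted
#' probes present on the new platform pass through unchanged; probes absent
#' but with a retained neighbor take the neighbor's betas under the legacy
#' probe's ID; the rest are emitted as NA rows.
#'
#' @param target beta matrix on the new platform.
#' @param map neighbor map from [build_neighbor_map()].
#' @param wanted legacy probe IDs to produce.
#' @return list with `betas` (wanted x samples) and `report` (tallies of
#'   pass-through / substituted / NA probes).
#' @export
substitute_betas <- function(target, map, wanted) {
  out <- matrix(NA_real_, length(wanted), ncol(target),
                dimnames = list(wanted, colnames(target)))
  pass <- wanted %in% rownames(target)
  out[pass, ] <- target[wanted[pass], , drop = FALSE]
  n_sub <- 0L
  midx <- match(wanted, map$query_id)
  for (i in which(!pass)) {
    mi <- midx[i]
    if (!is.na(mi) && map$retained[mi] && map$neighbor_id[mi] %in% rownames(target)) {
      out[i, ] <- target[map$neighbor_id[mi], ]
      n_sub <- n_sub + 1L
    }
  }
  list(betas = out,
       report = data.frame(pass_through = sum(pass), substituted = n_sub,
                           na_probes = length(wanted) - sum(pass) - n_sub))
}
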