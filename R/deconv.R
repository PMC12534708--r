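#' Build a reference panel from marker CpGs
#'
#' The panel row set is the union of the selected markers over all
#' contrasts; each cell is the mean beta of that cell type's reference
#' samples at the marker (non-NA mean).
#'
#' @param refs beta matrix of reference samples (probes x samples).
#' @param markers either a character vector of probe IDs or a list of
#'   marker result data.frames (rows with `selected == TRUE` are used).
#' @param celltypes cell-type label per reference sample (defaults to
#'   column names, one sample per type).
#' @return matrix markers x cell types of mean betas (the reference panel).
#' @export
build_reference <- function(refs, markers, celltypes = colnames(refs)) {
  if (is.list(markers) && !is.data.frame(markers)) {
    ids <- unique(unlist(lapply(markers, function(m) m$probe_id[m$selected])))
  } else if (is.data.frame(markers)) {
    ids <- unique(markers$probe_id[markers$selected])
  } else {
    ids <- unique(markers)
  }
  missing_ids <- setdiff(ids, rownames(refs))
  if (length(missing_ids) > 0) {
    warning(length(missing_ids), " marker(s) missing from reference, dropped: ",
            paste(head(missing_ids, 3), collapse = ", "))
    ids <- setdiff(ids, missing_ids)
  }
  if (length(ids) == 0) stop("no markers left to build a panel")
  sub <- refs[ids, , drop = FALSE]
  types <- unique(celltypes)
  panel <- matrix(NA_real_, length(ids), length(types),
                  dimnames = list(ids, types))
  for (t in types) {
    cols <- which(celltypes == t)
    panel[, t] <- rowMeans(sub[, cols, drop = FALSE], na.rm = TRUE)
  }
  panel[is.nan(panel)] <- NA_real_
  keep <- rowSums(!is.na(panel)) == ncol(panel)
  panel[keep, , drop = FALSE]
}

# robust (Huber) regression of y on X without intercept; falls back to OLS
# when the fit is (near-)exact, where the MAD scale estimate degenerates
huber_fit <- function(X, y, k = 1.345, maxit = 50, tol = 1e-6) {
  ols <- lm.fit(X, y)
  if (sqrt(mean(ols$residuals^2)) < 1e-8) {
    return(list(coef = ols$coefficients, converged = TRUE))
  }
  fit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = k, maxit = maxit,
                   acc = tol)
  list(coef = coef(fit), converged = fit$converged)
}

#' Cell-type deconvolution by robust partial correlations
#'
#' Per sample, bulk betas at the panel markers are regressed on the
#' reference cell-type profiles by iteratively reweighted least squares
#' with Huber weights (tuning constant `huber_c`, no intercept: betas
#' already share the \[0,1\] scale and the panel spans the mixture space).
#' Negative coefficients are truncated to 0 and the remainder renormalized
#' to sum to 1. Markers NA in a given sample are dropped pairwise for that
#' sample only.
#'
#' @param bulk beta matrix of bulk samples (probes x samples).
#' @param panel reference panel (markers x cell types) from
#'   [build_reference()].
#' @param huber_c Huber tuning constant (default 1.345, 95% Gaussian
#'   efficiency).
#' @param max_iter IRLS iteration cap (default 50).
#' @param tol convergence tolerance (default 1e-6).
#' @return data.frame with sample_id, one proportion column per cell type,
#'   `residual_norm`, `n_markers_used`, `converged`.
#' @export
rpc_deconvolve <- function(bulk, panel, huber_c = 1.345, max_iter = 50,
                           tol = 1e-6) {
  deconvolve_engine(bulk, panel, function(X, y) {
    huber_fit(X, y, k = huber_c, maxit = max_iter, tol = tol)
  })
}

#' Cell-type deconvolution by non-negative least squares
#'
#' Reference solver used as a cross-check for [rpc_deconvolve()] on
#' well-conditioned inputs: per sample, non-negative least squares of bulk
#' on the panel, then renormalization to a probability vector.
#'
#' @inheritParams rpc_deconvolve
#' @return same shape as [rpc_deconvolve()].
#' @export
nnls_deconvolve <- function(bulk, panel) {
  deconvolve_engine(bulk, panel, function(X, y) {
    list(coef = pracma::lsqnonneg(X, y)$x, converged = TRUE)
  })
}

deconvolve_engine <- function(bulk, panel, solver) {
  shared <- intersect(rownames(bulk), rownames(panel))
  k <- ncol(panel)
  if (length(shared) < k) stop("fewer shared markers than cell types")
  X_all <- panel[shared, , drop = FALSE]
  if (qr(X_all)$rank < k) {
    stop("rank-deficient panel; collinear cell types among: ",
         paste(colnames(panel), collapse = ", "))
  }
  B <- bulk[shared, , drop = FALSE]
  res <- lapply(seq_len(ncol(B)), function(j) {
    ok <- !is.na(B[, j]) & rowSums(is.na(X_all)) == 0
    if (sum(ok) < k) stop("sample ", colnames(B)[j],
                          ": fewer usable markers than cell types")
    fit <- solver(X_all[ok, , drop = FALSE], B[ok, j])
    co <- pmax(fit$coef, 0)
    tot <- sum(co)
    props <- if (tot > 0) co / tot else rep(1 / k, k)
    resid <- B[ok, j] - X_all[ok, , drop = FALSE] %*% props
    c(props, sqrt(sum(resid^2)), sum(ok), as.numeric(fit$converged))
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c(colnames(panel), "residual_norm", "n_markers_used", "converged")
  out$converged <- out$converged == 1
  data.frame(sample_id = colnames(B), out, check.names = FALSE,
             row.names = NULL)
}
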