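#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef complete.cases cor cor.test kruskal.test lm.fit
#'   p.adjust pchisq phyper pnorm pt pwilcox qnorm rbeta rbinom rnorm runif
#'   sd setNames var predict
#' @importFrom utils head modifyList
#' @importFrom data.table fread fwrite
NULL

.datatable.aware <- TRUE

logit <- function(p) log(p / (1 - p))

logistic <- function(x) 1 / (1 + exp(-x))

#' Add Gaussian noise on the logit scale
#'
#' Beta values are perturbed as `logistic(logit(beta) + e)`, `e ~ N(0, sd)`,
#' which keeps values inside (0, 1) and reproduces the heteroskedastic error
#' profile of array betas (small variance near 0 and 1, larger mid-range).
#' Values exactly 0 or 1 are nudged by 1e-6 before the logit.
#'
#' @param beta numeric vector or matrix of beta values in \[0, 1\].
#' @param sd noise standard deviation on the logit scale; 0 returns the
#'   input unchanged.
#' @return object of the same shape as `beta`.
#' @export
logit_noise <- function(beta, sd) {
  if (sd == 0) return(beta)
  eps <- 1e-6
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- logistic(logit(b) + rnorm(length(b), 0, sd))
  if (is.matrix(beta)) {
    out <- matrix(out, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  }
  out[is.na(beta)] <- NA_real_
  out
}

#' Derive a per-stage seed from a global seed and a label
#'
#' Deterministically expands one user-facing seed into independent seeds for
#' pipeline stages and LOOCV folds, so any stage can be rerun in isolation.
#' Uses an FNV-1a style hash of the label folded into the seed, kept below
#' 2^31 so it is always a valid R integer.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the stage or fold.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(as.character(label))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# FNV-1a hash of a character scalar, hex string; used for config fingerprints
fnv1a_hex <- function(x) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(x)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
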