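# Independent oracles used across tests; all are brute-force or closed-form
# and never share code with the implementation they check.

# toy beta matrix with dimnames
toy_bm <- function(values, nr, nc, probes = sprintf("p%02d", seq_len(nr)),
                   samples = sprintf("s%02d", seq_len(nc))) {
  matrix(values, nr, nc, dimnames = list(probes, samples))
}

# exact two-sided Wilcoxon p by enumeration over all C(n1+n2, n1) rank
# assignments: 2 * min(P(U <= u), P(U >= u)), capped at 1
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# AUC as the probability-of-superiority estimate by exhaustive pair counting
oracle_auc <- function(x, y) {
  tot <- 0
  for (xi in x) for (yj in y) tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# one-sided hypergeometric p by direct summation
oracle_hyper_p <- function(a, K, N, nq) {
  xs <- a:min(K, nq)
  sum(choose(K, xs) * choose(N - K, nq - xs)) / choose(N, nq)
}

# running-sum enrichment score computed step by step (independent of the
# hit-position shortcut in the package); on a magnitude tie between the
# positive and negative extremes the positive one is reported
oracle_es <- function(member, N) {
  q <- sum(member)
  s <- 0; path <- numeric(N)
  for (i in seq_len(N)) {
    s <- s + if (member[i]) 1 / q else -1 / (N - q)
    path[i] <- s
  }
  mx <- max(path, 0); mn <- min(path, 0)
  if (mx >= -mn) mx else mn
}

# Kruskal-Wallis H from the textbook formula (no tie correction; use on
# tie-free data only)
oracle_kw_h <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
}
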