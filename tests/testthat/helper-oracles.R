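# Independent oracles used across the suite. Each is deliberately written as
# plain, slow, closed-form or enumerative code, not sharing any helper with
# the package implementation it checks.

# Personalized PageRank by direct linear solve: s = (1-d) (I - d P)^{-1} e.
# Requires a graph without degree-zero nodes.
oracle_pagerank <- function(g, seeds, damping = 0.85) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  stopifnot(all(colSums(A) > 0))
  P <- sweep(A, 2, colSums(A), "/")
  e <- numeric(n)
  e[match(seeds, nodes)] <- 1 / length(seeds)
  s <- solve(diag(n) - damping * P, (1 - damping) * e)
  stats::setNames(s / sum(s), nodes)
}

# Upper-tail hypergeometric by exhaustive enumeration of all n-subsets of a
# universe of size N containing K marked elements (N <= 12).
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# ssGSEA running sum, gene by gene, with explicit accumulators.
oracle_ssgsea <- function(x, genes, set, alpha = 0.25) {
  N <- length(genes)
  ord <- order(-x, genes)
  sorted_genes <- genes[ord]
  r <- N - seq_len(N) + 1
  in_set <- sorted_genes %in% set
  denom_hit <- sum(r[in_set]^alpha)
  n_miss <- N - sum(in_set)
  es <- 0; p_hit <- 0; p_miss <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) p_hit <- p_hit + r[i]^alpha / denom_hit
    else p_miss <- p_miss + 1 / n_miss
    es <- es + (p_hit - p_miss)
  }
  es
}

# AUROC by exhaustive pair counting with half credit for ties.
oracle_auc_pairs <- function(y, prob) {
  pos <- prob[y == 1]; neg <- prob[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by enumerating all 2x2 tables with the observed
# margins and summing point probabilities <= the observed one.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  point <- function(a) stats::dhyper(a, c1, n - c1, r1)
  p_obs <- point(tab[1, 1])
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  pts <- vapply(a_range, point, numeric(1))
  sum(pts[pts <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of ranks.
oracle_mw_exact <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  obs_u <- sum(rank(c(a, b))[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  vals <- c(a, b)
  combos <- utils::combn(n, n_a)
  us <- apply(combos, 2, function(idx) {
    sum(rank(vals)[idx]) - n_a * (n_a + 1) / 2
  })
  mu <- n_a * (n - n_a) / 2
  mean(abs(us - mu) >= abs(obs_u - mu) - 1e-9)
}

# Exact two-sided Spearman p by enumerating all permutations (n <= 6).
oracle_spearman_exact <- function(a, b) {
  n <- length(a)
  rho_obs <- stats::cor(rank(a), rank(b))
  perms <- gtools_permutations(n)
  rb <- rank(b)
  rhos <- apply(perms, 1, function(p) stats::cor(p, rb))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-9))
}

# All permutations of 1..n, written out to avoid extra dependencies.
gtools_permutations <- function(n) {
  perm_of <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      out <- rbind(out, cbind(v[i], perm_of(v[-i])))
    }
    out
  }
  unname(perm_of(seq_len(n)))
}

# Kaplan-Meier product-limit by an explicit loop over distinct event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Two-group log-rank chi-square from the observed-minus-expected table.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  grp <- c(rep(1, length(time_a)), rep(2, length(time_b)))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    n1 <- sum(time >= t & grp == 1); n2 <- sum(time >= t & grp == 2)
    n <- n1 + n2
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Writes a temporary whitespace-delimited edge file and returns its path.
write_edge_file <- function(lines, header = NULL) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(header, lines), f)
  f
}

# Small labeled feature matrix with a clean linear signal.
separable_toy <- function(n = 20, seed = 11) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(f1 = y * 4 + rnorm(n, sd = 0.3), f2 = rnorm(n))
  rownames(X) <- sprintf("S%02d", seq_len(n))
  list(X = X, y = y)
}
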