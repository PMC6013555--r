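# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (closed formula, brute-force enumeration) kept separate from
# the implementation paths it checks.

# Welch two-sample t-test from the textbook formulae.
oracle_welch_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(t_stat), df)
}

# Benjamini-Hochberg step-up, written out longhand: sort ascending, multiply
# by m/rank, enforce monotonicity from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in seq(m - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Brute-force descendant reachability: term plus every node from which a
# directed is_a walk reaches it, found by repeated edge scans.
oracle_descendants <- function(edges, term) {
  out <- term
  repeat {
    more <- edges$child[edges$parent %in% out]
    new <- setdiff(more, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  sort(out)
}

# Random DAG on n nodes: edges only from higher-numbered to lower-numbered
# nodes, so acyclicity holds by construction.
random_dag <- function(n, p_edge = 0.02) {
  terms <- sprintf("T%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  data.frame(child = terms[pairs[keep, 2]], parent = terms[pairs[keep, 1]],
             stringsAsFactors = FALSE) |>
    (\(e) list(terms = terms, edges = e))()
}

# A BIP-shaped GO fixture: four terms with the published snapshot sizes and
# within-pool overlap.
bip_fixture_spec <- function(seed = 1L) {
  go_fixture_spec(
    c("GO:0051568" = 32L, "GO:0007129" = 23L, "GO:0090066" = 54L,
      "GO:0070192" = 362L),
    redundant_memberships = 23L, seed = seed)
}
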