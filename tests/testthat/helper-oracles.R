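# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (and the survival package) so agreement is a
# genuine cross-check, not a tautology.

# Textbook log-rank test by explicit risk-set enumeration: at every event
# time accumulate observed events in the "high" group, the hypergeometric
# expectation and variance, then compare the chi-square to its 1-df tail.
logrank_oracle_p <- function(time, event, high) {
  stopifnot(length(time) == length(event), length(time) == length(high))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & high)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  1 - pchisq(chisq, df = 1)
}

# Brute-force over-representation p-value: enumerate every possible query
# of size n drawn from the universe and count how often the overlap with
# the gene set reaches at least k_obs. Feasible only for small universes.
ora_oracle_p <- function(k_obs, set_genes, universe, n_query) {
  combos <- combn(universe, n_query)
  hits <- apply(combos, 2, function(q) sum(q %in% set_genes) >= k_obs)
  mean(hits)
}

# Step-up Benjamini-Hochberg by hand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Small deterministic cohort builder for unit tests.
make_cohort <- function(times, events = TRUE, stage = "IIIC",
                        ids = sprintf("S%03d", seq_along(times))) {
  clinical_cohort(
    subject_id = ids, days_to_death = times,
    event = events, stage = stage
  )
}

# Tiny expression matrix builder: values is features x subjects.
make_expr <- function(values, features, subjects, transform = "normalized") {
  m <- matrix(values, nrow = length(features), ncol = length(subjects))
  rownames(m) <- features
  colnames(m) <- subjects
  expression_matrix(m, transform = transform)
}
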