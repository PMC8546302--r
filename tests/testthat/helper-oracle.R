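# Independent oracles used by the mixture tests. These deliberately share
# no code with the package: partitions are enumerated by restricted-growth
# recursion and the classification likelihood is recomputed from its
# definition.

# all set partitions of n items into exactly K non-empty groups,
# as integer label vectors
oracle_partitions <- function(n, K) {
  res <- list()
  rec <- function(z, mx) {
    i <- length(z) + 1L
    if (i > n) {
      if (mx == K) res[[length(res) + 1L]] <<- z
      return(invisible())
    }
    for (k in seq_len(min(mx + 1L, K))) rec(c(z, k), max(mx, k))
  }
  rec(integer(0), 0L)
  res
}

# classification (hard-assignment) log-likelihood of a partition:
# weights are group sizes / n, each group mean is the inverse-variance
# weighted mean of its members
oracle_hard_loglik <- function(y, s, z) {
  n <- length(y)
  ll <- 0
  for (k in unique(z)) {
    idx <- z == k
    mu <- sum(y[idx] / s[idx]^2) / sum(1 / s[idx]^2)
    ll <- ll + sum(log(sum(idx) / n) + dnorm(y[idx], mu, s[idx], log = TRUE))
  }
  ll
}

# best classification log-likelihood over all partitions into K groups
oracle_best_loglik <- function(y, s, K) {
  max(vapply(oracle_partitions(length(y), K),
             function(z) oracle_hard_loglik(y, s, z), numeric(1)))
}

withr_local_tempfile <- function() tempfile(fileext = ".tsv")

# small two-map pair for projection tests: component anchors at 10 and 20
# map to consensus 20 and 40 (local scale factor 2)
toy_maps <- function() {
  consensus <- genetic_map(data.frame(
    marker = c("a1", "a2", "a3"), linkage_group = "1A",
    position_cM = c(20, 40, 60)), "consensus")
  component <- genetic_map(data.frame(
    marker = c("a1", "a2", "a3"), linkage_group = "1A",
    position_cM = c(10, 20, 30)), "comp")
  list(consensus = consensus, component = component)
}
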