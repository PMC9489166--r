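# small seeded cohorts used across tests; generated in code, never stored

# full 123-patient design at a reduced gene count
reduced_config <- function(..., n_genes = 2000, seed = 101) {
  synth_config(n_genes = n_genes, ..., seed = seed)
}

# two-group toy cohort for fast unit tests
tiny_config <- function(noise_sd = 0, n_genes = 300, seed = 5, ...) {
  synth_config(
    n_genes = n_genes,
    group_sizes = c("AC:NC" = 12, "SCC:CT" = 10),
    signature_sizes = c("AC:NC" = 5, "SCC:CT" = 4),
    noise_sd = noise_sd,
    immune_tolerant_count = 4,
    missing_stage_count = 1,
    seed = seed, ...)
}

# exhaustive minimum within-cluster sum of squares over all 2-partitions
brute_force_2means <- function(values) {
  n <- length(values)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    inA <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- values[inA]; b <- values[!inA]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best) best <- wss
  }
  best
}

# literal BH step-up definition: q_i = min_{j >= i} p_(j) * m / j
bh_stepup_literal <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
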