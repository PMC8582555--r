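# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: matrix-exponential propagation instead
# of ODE integration, per-event loops instead of vectorized binning, and
# exhaustive enumeration instead of greedy pairing.

# x(t) = expm(A t) x0, one matrix exponential per requested time
expm_solution <- function(A, x0, times) {
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(A * t) %*% x0), numeric(length(x0))))
}

# brute-force shell binning: explicit loop over events
brute_force_bin <- function(r, e, r0, d, n, n_primaries) {
  shells <- numeric(n)
  for (i in seq_along(r)) {
    if (r[i] < r0) next
    idx <- floor((r[i] - r0) / d) + 1
    if (idx > n) next
    shells[idx] <- shells[idx] + e[i]
  }
  shells / n_primaries
}

# maximum number of opposite-strand pairs within a bp window, by
# exhaustive recursion over all pairings (feasible for <= 10 breaks)
max_matching_bruteforce <- function(strand, bp, window) {
  n <- length(strand)
  best <- 0L
  recurse <- function(used, count) {
    best <<- max(best, count)
    i <- which(!used)[1L]
    if (is.na(i)) return()
    # either leave break i unpaired ...
    used_i <- used
    used_i[i] <- TRUE
    recurse(used_i, count)
    # ... or pair it with any compatible partner
    for (j in which(!used)) {
      if (j == i) next
      if (strand[j] != strand[i] && abs(bp[j] - bp[i]) <= window) {
        used_ij <- used_i
        used_ij[j] <- TRUE
        recurse(used_ij, count + 1L)
      }
    }
  }
  recurse(logical(n), 0L)
  best
}

# random small topology with blood + a few organs and random rates
random_topology_and_rates <- function(n_organs, rate_scale = 1) {
  organs <- paste0("organ", seq_len(n_organs))
  topo <- compartment_topology(systemic = organs)
  edges <- topo$edges
  transfer_rates(edges$donor, edges$receptor,
                 stats::runif(nrow(edges), 0, rate_scale))
}
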