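# Independent brute-force oracles used to validate the package's optimized
# implementations. These deliberately share no code with R/.

# Conditional profile by naive double loop over ordered (center, partner)
# pairs: center must carry a substitution; both ends inside the trimmed
# region.
oracle_profile <- function(symbol_list, d_max, trim) {
  N1 <- N0 <- numeric(d_max)
  for (x in symbol_list) {
    n <- length(x)
    if (n <= 2 * trim + 1) next
    for (cpos in seq_len(n)) {
      if (cpos <= trim || cpos > n - trim) next
      if (x[cpos] != 1) next
      for (d in seq_len(d_max)) {
        for (p in c(cpos - d, cpos + d)) {
          if (p <= trim || p > n - trim) next
          if (x[p] == 1) N1[d] <- N1[d] + 1 else N0[d] <- N0[d] + 1
        }
      }
    }
  }
  list(N1 = N1, N0 = N0, P = ifelse(N1 + N0 > 0, N1 / (N1 + N0), NaN))
}

# Avalanche partition by transitive closure of the event-event link relation.
oracle_avalanches <- function(m, adj, time_window, self_links) {
  ev <- which(m == 1, arr.ind = TRUE)
  n <- nrow(ev)
  if (n == 0) return(integer(0))
  link <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    same <- ev[a, 1] == ev[b, 1]
    ok <- (adj[ev[a, 1], ev[b, 1]] || (self_links && same)) &&
      abs(ev[a, 2] - ev[b, 2]) <= time_window
    link[a, b] <- ok
  }
  diag(link) <- TRUE
  repeat {
    nxt <- (link %*% link) > 0
    if (identical(nxt, link > 0)) break
    link <- nxt
  }
  # canonical component labels: index of first event in each closure class
  apply(link, 1, function(r) which(r)[1])
}

# Eq.-style negative binomial evaluated by hand in log space.
oracle_negbinom <- function(k, alpha, mean_k) {
  exp(lgamma(alpha + k) - lgamma(alpha) - lfactorial(k) +
        k * log(mean_k / (mean_k + alpha)) +
        alpha * log(alpha / (mean_k + alpha)))
}

# Naive Eq.-style rate evaluation: full sum over all ordered pairs.
oracle_site_rates <- function(state, map, r0_vec, J) {
  L <- map$L
  adj <- as.matrix(map)
  vapply(seq_len(L), function(i) {
    acc <- r0_vec[i]
    for (k in seq_len(L)) {
      if (adj[i, k] == 1 && state$mutated[k]) {
        lag <- state$time - state$t_last[k]
        if (lag <= 40) acc <- acc + J * exp(-lag)
      }
    }
    acc
  }, numeric(1))
}

band_map <- function(L, width = 2) {
  synthetic_contact_map(L, helix_spans = NULL, long_range_per_site = 0,
                        backbone_width = width, seed = 1)$map
}

# canonicalize a partition of events 1..n (labels -> sorted groups ordered by
# their smallest member) so two labelings can be compared structurally
partition_signature <- function(labels) {
  groups <- lapply(split(seq_along(labels), labels), sort)
  unname(groups[order(vapply(groups, `[`, numeric(1), 1))])
}
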