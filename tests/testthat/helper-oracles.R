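# Independent brute-force oracles used to cross-check the implementation.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# possible overlap counts (universes small enough to enumerate).
oracle_fisher_p <- function(n_universe, n_a, n_b, a_obs) {
  lo <- max(0L, n_a + n_b - n_universe)
  hi <- min(n_a, n_b)
  probs <- dhyper(lo:hi, n_a, n_universe - n_a, n_b)
  p_obs <- dhyper(a_obs, n_a, n_universe - n_a, n_b)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-tailed MWW p by exhaustive enumeration of all same-size subsets of
# the background (midranks; P(rank sum >= observed)).
oracle_mww_p <- function(background, query) {
  r <- rank(background)
  t_obs <- sum(r[match(query, background)])
  sums <- combn(length(background), length(query),
                function(i) sum(r[i]))
  mean(sums >= t_obs - 1e-9)
}

# Brute-force CDF-gap extremes: evaluate B(c) - Q(c) at every observed
# value plus a point below the minimum.
oracle_cdf_gap <- function(background, query) {
  grid <- c(min(background, query) - 1, sort(unique(c(background, query))))
  d <- vapply(grid, function(c) {
    mean(background <= c) - mean(query <= c)
  }, numeric(1))
  list(d_sup = max(d), d_inf = min(d),
       c_star = grid[which.max(d)])
}

# Brute-force leading edge: scan all candidate thresholds, take the query
# genes strictly above the gap-maximizing one.
oracle_leading_edge <- function(background, query_signals) {
  g <- oracle_cdf_gap(background, unname(query_signals))
  names(query_signals)[query_signals > g$c_star]
}

# Exhaustive complete-linkage agglomeration on a distance matrix; returns
# the sorted merge heights.
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# O(peaks x domains) overlap scan for the ChIP assignment (0-based
# half-open intervals).
oracle_assign_chip <- function(peaks_by_source, domains) {
  mat <- matrix(0, nrow(domains), length(peaks_by_source),
                dimnames = list(domains$symbol, names(peaks_by_source)))
  for (fac in names(peaks_by_source)) {
    sources <- peaks_by_source[[fac]]
    if (is.data.frame(sources)) sources <- list(sources)
    for (pk in sources) {
      for (p in seq_len(nrow(pk))) {
        for (g in seq_len(nrow(domains))) {
          if (pk$chrom[p] != domains$chrom[g]) next
          ov <- min(pk$end[p], domains$end[g]) -
            max(pk$start[p], domains$start[g])
          if (ov >= 1) {
            mat[g, fac] <- max(mat[g, fac], pk$signal_value[p])
          }
        }
      }
    }
  }
  mat
}
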