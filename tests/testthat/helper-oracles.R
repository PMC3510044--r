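# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration for the hypergeometric tail,
# an O(n^3) from-scratch agglomeration for average linkage, and direct
# simulation of the spot-noise chain for the null IAI tail.

# Exact upper-tail hypergeometric probability by exhaustive enumeration of
# all C(N, n) query subsets; the set is taken as elements 1..K.
enum_hyper_tail <- function(k, K, n, N) {
  subs <- utils::combn(N, n)
  ov <- if (n == 0) rep(0L, ncol(subs)) else colSums(subs <= K)
  sum(ov >= k) / ncol(subs)
}

# Naive average-linkage clustering: recompute every cluster-pair distance
# as the mean over all member pairs at every step. Ties broken by the
# smallest pair of active-cluster indices. Returns merge heights in order.
naive_average_linkage <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(dm[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Small array experiment shared by pipeline tests.
small_array_cfg <- function(...) {
  defaults <- list(seed = 11, n_genes = 120, n_intron_genes = 40,
                   frac_two_intron = 0.1, n_sets = 5,
                   set_size_range = c(3, 10))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
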