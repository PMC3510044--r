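#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` members of a `K`-gene set in an
#' `n`-gene query drawn without replacement from an `N`-gene universe:
#' `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Computed in log space (log binomial coefficients + log-sum-exp) for
#' numerical stability at genome scale.
#'
#' @param k Observed overlap (vectorized).
#' @param K Set size.
#' @param n Query size.
#' @param N Universe size.
#' @return p-value(s) in [0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (length(K) != 1L || length(n) != 1L || length(N) != 1L) {
    stop("K, n, N must be scalars", call. = FALSE)
  }
  if (K < 0 || K > N) stop("constraint violated: 0 <= K <= N", call. = FALSE)
  if (n < 0 || n > N) stop("constraint violated: 0 <= n <= N", call. = FALSE)
  if (any(k < 0) || any(k > pmin(K, n))) {
    stop("constraint violated: 0 <= k <= min(K, n)", call. = FALSE)
  }
  vapply(k, function(k1) {
    i <- seq.int(k1, min(K, n))
    if (!length(i)) return(0)
    logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(logterms)
    min(1, exp(m + log(sum(exp(logterms - m)))))
  }, numeric(1))
}

#' Enrich a query gene set against every set of a catalog
#'
#' One raw upper-tail hypergeometric p-value per catalog set, with the
#' catalog universe as sampling frame. Results are sorted by `p_raw`
#' ascending with lexicographic `set_id` tie-break.
#'
#' @param query Character vector of query genes (must lie in the catalog
#'   universe).
#' @param catalog A [gene_catalog()].
#' @return Data.frame `set_id`, `k`, `K`, `n`, `N`, `p_raw`.
#' @export
enrich_catalog <- function(query, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  query <- unique(query)
  stray <- setdiff(query, catalog$universe)
  if (length(stray)) {
    stop("query gene(s) outside the catalog universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  N <- length(catalog$universe)
  n <- length(query)
  if (!length(catalog$sets)) {
    return(data.frame(set_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(names(catalog$sets), function(sid) {
    members <- catalog$sets[[sid]]
    k <- length(intersect(query, members))
    data.frame(set_id = sid, k = k, K = length(members), n = n, N = N,
               p_raw = hypergeom_pvalue(k, length(members), n, N),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$p_raw, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Parameters for multiple-testing adjustment
#'
#' @param B Number of resampled null queries (default 1000).
#' @param seed Seed for the resampling RNG.
#' @param m Number of tests for Bonferroni adjustment.
#' @param alpha Family-wise significance threshold (default 0.05).
#' @return List of class `"adjust_params"`.
#' @export
adjust_params <- function(B = 1000L, seed = 1L, m = NULL, alpha = 0.05) {
  if (B < 1L) stop("`B` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (!is.null(m) && m < 1L) stop("`m` must be >= 1", call. = FALSE)
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 m = if (is.null(m)) NULL else as.integer(m), alpha = alpha),
            class = "adjust_params")
}

#' Empirical min-p resampling family-wise correction
#'
#' Draws `B` uniform random query sets of the observed query size from the
#' catalog universe and records, for each, the minimum raw p-value across
#' all catalog sets. The adjusted p-value of a set is the add-one resampling
#' estimate `(1 + #{resamples with min-p <= p_raw}) / (B + 1)` — never
#' exactly zero — followed by a monotonicity pass so the adjusted ordering
#' matches the raw ordering.
#'
#' @param results Data.frame from [enrich_catalog()] over `catalog`.
#' @param catalog The same [gene_catalog()].
#' @param params An [adjust_params()] (uses `B` and `seed`).
#' @return `results` with columns `p_adjusted` and `method = "resampling"`.
#' @export
resampling_adjust <- function(results, catalog, params = adjust_params()) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (!nrow(results)) {
    results$p_adjusted <- numeric(0)
    results$method <- character(0)
    return(results)
  }
  N <- length(catalog$universe)
  n <- results$n[1]
  if (n > N) stop("query size exceeds universe size", call. = FALSE)
  set.seed(params$seed)
  sets <- catalog$sets[results$set_id]
  K <- lengths(sets)
  # per-set lookup of P(X >= k) over k = 0..min(K, n) so each resample is
  # a table lookup, not a fresh tail sum
  nr <- max(pmin(K, n)) + 1L
  pmat <- matrix(NA_real_, nr, length(sets))
  for (s in seq_along(sets)) {
    ks <- 0:min(K[s], n)
    pmat[ks + 1L, s] <- hypergeom_pvalue(ks, K[s], n, N)
  }
  member_idx <- lapply(sets, function(m) match(m, catalog$universe))
  in_set <- matrix(FALSE, N, length(sets))
  for (s in seq_along(sets)) in_set[member_idx[[s]], s] <- TRUE
  scol <- seq_along(sets)

  min_p <- vapply(seq_len(params$B), function(b) {
    draw <- sample.int(N, n)
    kk <- colSums(in_set[draw, , drop = FALSE])
    min(pmat[cbind(kk + 1L, scol)])
  }, numeric(1))

  min_p_sorted <- sort(min_p)
  counts <- findInterval(results$p_raw, min_p_sorted)
  p_adj <- (1 + counts) / (params$B + 1)
  # enforce monotonicity in p_raw (results are sorted by p_raw)
  o <- order(results$p_raw)
  p_adj[o] <- cummax(p_adj[o])
  results$p_adjusted <- pmin(1, p_adj)
  results$method <- "resampling"
  results
}

#' Bonferroni family-wise correction
#'
#' `p_adjusted = min(1, m * p_raw)`, with `m` the number of tests in the
#' family (e.g. 45 GO-slim process terms).
#'
#' @param results Data.frame with a `p_raw` column.
#' @param m Number of tests; must be at least `nrow(results)`.
#' @return `results` with `p_adjusted` and `method = "bonferroni"`.
#' @export
bonferroni_adjust <- function(results, m) {
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (m < nrow(results)) {
    stop("`m` must be at least the number of results", call. = FALSE)
  }
  results$p_adjusted <- pmin(1, m * results$p_raw)
  results$method <- "bonferroni"
  results
}
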