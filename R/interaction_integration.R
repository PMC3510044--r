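#' Call negative interactions from E-MAP scores
#'
#' Genes with a quantitative genetic-interaction score at or below the
#' threshold (default -2.5) are called synthetic sick/lethal. The boundary
#' value is included.
#'
#' @param scores Named numeric vector gene -> score.
#' @param threshold Calling threshold (default -2.5).
#' @return Sorted character vector of negative-interaction genes.
#' @export
call_emap_negatives <- function(scores, threshold = -2.5) {
  if (!length(scores)) return(character(0))
  if (any(!is.finite(scores))) {
    stop("E-MAP scores must be finite", call. = FALSE)
  }
  sort(names(scores)[scores <= threshold])
}

#' Integrate negative-interaction evidence into one gene set
#'
#' Union of the 30C SGA hits, the directed-genetics synthetic sick/lethal
#' calls, and the E-MAP negative calls, with per-gene provenance. Positive
#' (suppressor) calls are never merged here; they are analyzed as a separate
#' parallel set.
#'
#' @param sga30 Character vector of 30C SGA hit genes.
#' @param directed Character vector of directed-genetics SS/SL genes.
#' @param emap_negatives Character vector from [call_emap_negatives()].
#' @param universe Character vector of all screened genes; every source gene
#'   must belong to it.
#' @return List of class `"integrated_set"`: `genes` (sorted), `provenance`
#'   (named list gene -> character vector of sources), `universe_size`.
#' @export
integrate_negative_set <- function(sga30, directed, emap_negatives,
                                   universe) {
  sources <- list(sga30 = unique(sga30), directed = unique(directed),
                  emap = unique(emap_negatives))
  stray <- setdiff(unique(unlist(sources, use.names = FALSE)), universe)
  if (length(stray)) {
    stop("gene(s) outside the declared universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(unlist(sources, use.names = FALSE)))
  provenance <- lapply(genes, function(g) {
    names(sources)[vapply(sources, function(s) g %in% s, logical(1))]
  })
  names(provenance) <- genes
  structure(list(genes = genes, provenance = provenance,
                 universe_size = length(unique(universe))),
            class = "integrated_set")
}

#' @export
print.integrated_set <- function(x, ...) {
  cat(sprintf("integrated_set: %d negative-interaction genes over %d screened\n",
              length(x$genes), x$universe_size))
  src <- table(unlist(x$provenance, use.names = FALSE))
  for (s in names(src)) cat(sprintf("  %s: %d\n", s, src[[s]]))
  invisible(x)
}

#' Screen hit rate as a printed percentage
#'
#' `100 * n_hits / n_screened`, rounded half-up to one decimal — the form
#' screen summaries are reported in (e.g. 83 hits of 4800 genes -> 1.7).
#'
#' @param n_hits Number of hit genes.
#' @param n_screened Number of genes screened (> 0).
#' @return Percentage with one decimal.
#' @export
screen_summary <- function(n_hits, n_screened) {
  if (n_screened <= 0) stop("`n_screened` must be positive", call. = FALSE)
  if (n_hits < 0 || n_hits > n_screened) {
    stop("`n_hits` must lie in [0, n_screened]", call. = FALSE)
  }
  floor(1000 * n_hits / n_screened + 0.5) / 10
}
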