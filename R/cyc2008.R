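#' Synthetic CYC2008-format complex catalog
#'
#' Stand-in for the manually curated CYC2008 yeast protein-complex list
#' (408 complexes), which is an external resource not shipped here: builds a
#' synthetic catalog with the same shape — 408 complexes of 2-81 members
#' over a genome-scale universe — so that catalog-level bookkeeping (set
#' count, RAD6-trio augmentation) is testable. Members and sizes are random;
#' only the structure mimics the real list.
#'
#' @param seed Seed for reproducibility.
#' @param n_complexes Number of complexes (default 408).
#' @param universe Optional gene universe; defaults to a 4800-gene synthetic
#'   deletion universe.
#' @return A [gene_catalog()].
#' @export
synthetic_cyc2008_catalog <- function(seed = 1L, n_complexes = 408L,
                                      universe = NULL) {
  if (is.null(universe)) {
    universe <- sprintf("YSN%04dC", seq_len(4800L))
  }
  set.seed(as.integer(seed))
  # CYC2008-like size distribution: mostly dimers/trimers, a long tail
  sizes <- pmin(2L + stats::rpois(n_complexes, 1.8) +
                  stats::rgeom(n_complexes, 0.55) * 3L, length(universe))
  sets <- lapply(sizes, function(sz) sample(universe, sz))
  names(sets) <- sprintf("CPX%03d", seq_len(n_complexes))
  gene_catalog(sets, universe,
               descriptions = sprintf("synthetic complex %d",
                                      seq_len(n_complexes)))
}

#' Append the RAD6 complex to a complex catalog
#'
#' Adds the RAD6/BRE1/LGE1 H2B-ubiquitination trio as one additional
#' catalog entry (it was not annotated when the curated complex list was
#' created). Members absent from the universe are added to it.
#'
#' @param catalog A [gene_catalog()].
#' @param members Trio gene ids (default systematic names of RAD6, BRE1,
#'   LGE1).
#' @param set_id Id for the new set.
#' @return The augmented [gene_catalog()].
#' @export
append_rad6_complex <- function(catalog,
                                members = c("YGL058W", "YDL074C", "YPL055C"),
                                set_id = "RAD6_complex") {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (set_id %in% names(catalog$sets)) {
    stop("catalog already contains a set named ", set_id, call. = FALSE)
  }
  sets <- c(catalog$sets, stats::setNames(list(members), set_id))
  desc <- c(catalog$descriptions,
            stats::setNames("RAD6 complex (RAD6/BRE1/LGE1)", set_id))
  gene_catalog(sets, union(catalog$universe, members), descriptions = desc)
}
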