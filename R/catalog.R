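#' Gene-set catalog
#'
#' A catalog is a named collection of gene sets (protein complexes, GO-slim
#' biological processes) together with the gene universe they are drawn from.
#' The universe is the sampling frame for enrichment tests: all deletion
#' strains screened, not merely the union of catalog members.
#'
#' @param sets Named list of character vectors; names are set ids, elements
#'   are member gene ids. Members are deduplicated; empty or single-member
#'   sets are rejected.
#' @param universe Character vector of gene ids; every member of every set
#'   must belong to it.
#' @param descriptions Optional character vector of set descriptions,
#'   parallel to `sets` (recycled from set ids when missing).
#'
#' @return An object of class \code{"gene_catalog"}: a list with elements
#'   `sets`, `descriptions`, `universe`.
#' @export
gene_catalog <- function(sets, universe, descriptions = NULL) {
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets)))) {
    stop("catalog sets must have unique names (set ids)", call. = FALSE)
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  sizes <- lengths(sets)
  if (any(sizes < 2L)) {
    stop("every catalog set must have >= 2 members; offending set(s): ",
         paste(names(sets)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  universe <- unique(as.character(universe))
  stray <- setdiff(unique(unlist(sets, use.names = FALSE)), universe)
  if (length(stray)) {
    stop("catalog members outside the declared universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- as.character(names(sets))
  } else {
    stopifnot(length(descriptions) == length(sets))
  }
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d sets over a %d-gene universe\n",
              length(x$sets), length(x$universe)))
  sz <- lengths(x$sets)
  if (length(sz)) {
    cat(sprintf("  set sizes: %d-%d (median %g)\n",
                min(sz), max(sz), stats::median(sz)))
  }
  invisible(x)
}

#' @export
length.gene_catalog <- function(x) length(x$sets)
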