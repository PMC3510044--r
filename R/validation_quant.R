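#' qPCR unspliced fold change
#'
#' The Intron/Exon starting-quantity ratio of a mutant normalized to its
#' isogenic wild-type:
#' `(intron_sq/exon_sq)_mutant / (intron_sq/exon_sq)_wildtype`.
#' Invariant to any common positive rescaling of the starting quantities,
#' since those are arbitrary standard-curve units.
#'
#' @param mutant,wildtype Lists (or one-row data.frames) with fields
#'   `gene_id`, `intron_sq`, `exon_sq`; quantities must be positive.
#' @param log2_out If `TRUE`, return log2 of the fold change.
#' @return Fold change (linear by default).
#' @export
unspliced_fold_change <- function(mutant, wildtype, log2_out = FALSE) {
  if (!identical(as.character(mutant$gene_id),
                 as.character(wildtype$gene_id))) {
    stop("mutant and wild-type measurements are for different genes",
         call. = FALSE)
  }
  q <- c(mutant$intron_sq, mutant$exon_sq,
         wildtype$intron_sq, wildtype$exon_sq)
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("starting quantities must be positive", call. = FALSE)
  }
  fc <- (mutant$intron_sq / mutant$exon_sq) /
    (wildtype$intron_sq / wildtype$exon_sq)
  if (log2_out) log2(fc) else fc
}

#' Percent ubiquitinated H2B from band intensities
#'
#' `100 * ub / (ub + unmod)` from the ubiquitinated and unmodified H2B band
#' intensities of one lane; invariant to common positive scaling.
#'
#' @param ub_intensity,unmod_intensity Non-negative band intensities, not
#'   both zero.
#' @return Percentage in [0, 100].
#' @export
percent_ub_h2b <- function(ub_intensity, unmod_intensity) {
  if (any(ub_intensity < 0) || any(unmod_intensity < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  if (any(ub_intensity + unmod_intensity == 0)) {
    stop("both band intensities are zero: percentage undefined",
         call. = FALSE)
  }
  100 * ub_intensity / (ub_intensity + unmod_intensity)
}
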