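#' Simulation configuration for the synthetic screens and arrays
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' object. The defaults describe the study conditions the generator emulates:
#' a ~4,800-gene non-essential deletion universe, splicing arrays with exon,
#' intron and exon-exon junction probes spotted as 6 technical replicates,
#' dye-flipped replicate arrays, and 2-5 biological replicates.
#'
#' @param seed Integer root seed. All generator randomness derives from it;
#'   the same config yields byte-identical outputs.
#' @param n_genes Size of the gene universe (deletion collection).
#' @param n_intron_genes Number of intron-containing genes printed on the
#'   splicing array.
#' @param frac_two_intron Fraction of intron genes carrying a second intron;
#'   their second-intron probes are reported under the gene id suffixed
#'   \code{"_2"}.
#' @param defect_genes Named numeric vector mapping gene id (optionally
#'   \code{"_2"}-suffixed to target a second intron) to a planted Intron
#'   Accumulation Index effect, in log2 units.
#' @param exon_effect_genes Named numeric vector mapping gene id to a planted
#'   transcription-level (total mRNA) log2 effect, a confounder the IAI must
#'   cancel.
#' @param noise_sd Log2-scale spot noise standard deviation, applied
#'   independently to each channel of each spot. Must be >= 0.
#' @param dye_bias Log2 intensity offset added to channel 1 (the ~635 nm
#'   scan) of every spot, emulating global dye bias; cancelled by dye flips
#'   and by per-array median centering.
#' @param n_tech_reps Technical replicate spots per probe (default 6).
#' @param n_bio_reps Biological replicates (2-5; each contributes a forward
#'   and a dye-flipped array).
#' @param flag_rate Fraction of spots marked with a negative flag
#'   (manually-excluded bad spots).
#' @param planted_complexes Named numeric vector mapping a catalog set id to
#'   a (negative) E-MAP score shift applied to its members.
#' @param n_sets Number of random gene sets in the generated catalog, in
#'   addition to the fixed 3-member RAD6-like trio.
#' @param set_size_range Integer length-2 vector, inclusive range of random
#'   set sizes.
#' @param emap_sd Standard deviation of the background E-MAP score
#'   distribution (mean 0 normal).
#' @param sga30_fp,sga37_fp Per-gene false-positive rates of the 30C and 37C
#'   SGA screens among genes with no planted negative interaction. Free
#'   parameters of the emulation; defaults put the expected hit counts near
#'   the reported screen rates (1.7% and 6.9% of ~4,800 genes).
#' @param sga_fn Per-gene false-negative rate of the 30C SGA among planted
#'   negatives (the 37C screen uses half this rate).
#' @param n_directed Number of planted negatives confirmed by directed
#'   genetics (tetrad dissection / serial dilution).
#' @param baseline_intensity Median spot intensity scale (arbitrary scanner
#'   units).
#' @param genotype,reference,temperature Sample annotation carried onto the
#'   generated arrays.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 4800L,
                       n_intron_genes = 300L,
                       frac_two_intron = 0.1,
                       defect_genes = numeric(0),
                       exon_effect_genes = numeric(0),
                       noise_sd = 0.15,
                       dye_bias = 0.1,
                       n_tech_reps = 6L,
                       n_bio_reps = 3L,
                       flag_rate = 0.02,
                       planted_complexes = numeric(0),
                       n_sets = 20L,
                       set_size_range = c(3L, 30L),
                       emap_sd = 1,
                       sga30_fp = 0.015,
                       sga37_fp = 0.065,
                       sga_fn = 0.2,
                       n_directed = 10L,
                       baseline_intensity = 1000,
                       genotype = "mutant",
                       reference = "WT",
                       temperature = "30C") {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_intron_genes = as.integer(n_intron_genes),
    frac_two_intron = frac_two_intron,
    defect_genes = defect_genes,
    exon_effect_genes = exon_effect_genes,
    noise_sd = noise_sd,
    dye_bias = dye_bias,
    n_tech_reps = as.integer(n_tech_reps),
    n_bio_reps = as.integer(n_bio_reps),
    flag_rate = flag_rate,
    planted_complexes = planted_complexes,
    n_sets = as.integer(n_sets),
    set_size_range = as.integer(set_size_range),
    emap_sd = emap_sd,
    sga30_fp = sga30_fp,
    sga37_fp = sga37_fp,
    sga_fn = sga_fn,
    n_directed = as.integer(n_directed),
    baseline_intensity = baseline_intensity,
    genotype = genotype,
    reference = reference,
    temperature = temperature
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (cfg$n_genes < 1L) stop("`n_genes` must be positive", call. = FALSE)
  for (fr in c("frac_two_intron", "flag_rate", "sga30_fp", "sga37_fp", "sga_fn")) {
    v <- cfg[[fr]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a fraction in [0, 1]", fr), call. = FALSE)
    }
  }
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cfg$n_tech_reps < 1L) stop("`n_tech_reps` must be >= 1", call. = FALSE)
  if (cfg$n_bio_reps < 1L) stop("`n_bio_reps` must be >= 1", call. = FALSE)
  if (length(cfg$set_size_range) != 2L ||
      cfg$set_size_range[1] > cfg$set_size_range[2] ||
      cfg$set_size_range[1] < 2L) {
    stop("`set_size_range` must be an increasing pair with minimum >= 2",
         call. = FALSE)
  }
  if (length(cfg$defect_genes) && is.null(names(cfg$defect_genes))) {
    stop("`defect_genes` must be a named numeric vector", call. = FALSE)
  }
  if (length(cfg$exon_effect_genes) && is.null(names(cfg$exon_effect_genes))) {
    stop("`exon_effect_genes` must be a named numeric vector", call. = FALSE)
  }
  if (length(cfg$planted_complexes) && is.null(names(cfg$planted_complexes))) {
    stop("`planted_complexes` must be a named numeric vector", call. = FALSE)
  }
  invisible(cfg)
}

#' Gene universe implied by a simulation configuration
#'
#' Synthetic systematic-style gene names, deterministic in `n_genes`.
#'
#' @param cfg A [sim_config()].
#' @return Character vector of `n_genes` unique gene ids.
#' @export
sim_universe <- function(cfg) {
  validate_sim_config(cfg)
  sprintf("YSN%04dC", seq_len(cfg$n_genes))
}

# Stable per-array substream seed: mixing the root seed with the replicate
# and orientation so adding replicates never perturbs earlier arrays.
# Kept strictly below 2^31.
derive_seed <- function(seed, bio_rep, orientation, stream = 0L) {
  orient_code <- match(orientation, c("forward", "flipped"))
  if (is.na(orient_code)) orient_code <- 3L
  mix <- (as.double(seed) * 2654435761 +
            bio_rep * 97561 + orient_code * 7919 + stream * 524287)
  as.integer(mix %% 2147483629)
}
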