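#' Generate a synthetic protein-complex catalog
#'
#' Builds a CYC2008-style catalog of random gene sets over the configured
#' universe. One designated 3-member set, `RAD6_complex`, is always present,
#' mirroring the RAD6/BRE1/LGE1 ubiquitination module that real complex
#' catalogs of the era lacked; its members are the last three genes of the
#' universe, fixed so planting and recovery tests can target it by id.
#'
#' @param cfg A [sim_config()]; `n_sets` random sets with sizes drawn
#'   uniformly from `set_size_range` are generated (sets may overlap).
#' @return A [gene_catalog()] with `n_sets + 1` sets.
#' @export
generate_catalog <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_genes < 20L) {
    stop("universe too small to host a catalog: need n_genes >= 20",
         call. = FALSE)
  }
  if (cfg$set_size_range[2] > cfg$n_genes) {
    stop(sprintf(
      "requested set size %d exceeds the %d-gene universe",
      cfg$set_size_range[2], cfg$n_genes), call. = FALSE)
  }
  universe <- sim_universe(cfg)
  set.seed(derive_seed(cfg$seed, 0L, "catalog", stream = 1L))
  sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                  cfg$n_sets, replace = TRUE)
  sets <- lapply(sizes, function(sz) sample(universe, sz))
  names(sets) <- sprintf("C%03d", seq_len(cfg$n_sets))
  trio <- universe[(cfg$n_genes - 2L):cfg$n_genes]
  sets[["RAD6_complex"]] <- trio
  desc <- c(sprintf("synthetic complex %d", seq_len(cfg$n_sets)),
            "H2B ubiquitination module (E2/E3/adaptor trio)")
  gene_catalog(sets, universe, descriptions = desc)
}

#' Generate synthetic genetic-interaction screens with planted negatives
#'
#' Emulates the three evidence sources the integration step consumes:
#' binary SGA hit lists at 30C and 37C, a continuous E-MAP score table,
#' and a small set of directed-genetics confirmations. E-MAP scores are
#' background-normal (mean 0, sd `emap_sd`); members of each planted complex
#' are shifted by the planted (negative) amount so most fall at or below the
#' -2.5 calling threshold. SGA lists are noisy views of the planted
#' negatives: each planted gene is detected with probability `1 - sga_fn`
#' (half that miss rate at 37C), and non-planted genes enter as false
#' positives at the per-screen rates.
#'
#' @param cfg A [sim_config()]; `planted_complexes` maps catalog set ids to
#'   score shifts.
#' @param catalog A [gene_catalog()] over the same universe.
#' @return List with elements `sga30`, `sga37` (character vectors of hit
#'   gene ids), `emap` (data.frame `gene`, `score`), `directed` (character
#'   vector), and `truth` (list: `true_negative_genes`, `enriched_sets`).
#' @export
generate_interaction_data <- function(cfg, catalog) {
  validate_sim_config(cfg)
  stopifnot(inherits(catalog, "gene_catalog"))
  universe <- sim_universe(cfg)
  if (!setequal(catalog$universe, universe)) {
    stop("catalog universe does not match the configured universe",
         call. = FALSE)
  }
  missing_sets <- setdiff(names(cfg$planted_complexes), names(catalog$sets))
  if (length(missing_sets)) {
    stop("planted complex id(s) not in catalog: ",
         paste(missing_sets, collapse = ", "), call. = FALSE)
  }

  set.seed(derive_seed(cfg$seed, 0L, "interactions", stream = 2L))
  scores <- stats::rnorm(cfg$n_genes, mean = 0, sd = cfg$emap_sd)
  names(scores) <- universe
  planted_members <- character(0)
  for (sid in names(cfg$planted_complexes)) {
    members <- catalog$sets[[sid]]
    scores[members] <- scores[members] + cfg$planted_complexes[[sid]]
    planted_members <- union(planted_members, members)
  }

  is_planted <- universe %in% planted_members
  detect30 <- stats::runif(cfg$n_genes) <
    ifelse(is_planted, 1 - cfg$sga_fn, cfg$sga30_fp)
  detect37 <- stats::runif(cfg$n_genes) <
    ifelse(is_planted, 1 - cfg$sga_fn / 2, cfg$sga37_fp)
  sga30 <- universe[detect30]
  sga37 <- universe[detect37]
  directed <- if (length(planted_members)) {
    sort(sample(planted_members,
                min(cfg$n_directed, length(planted_members))))
  } else {
    character(0)
  }

  list(
    sga30 = sga30,
    sga37 = sga37,
    emap = data.frame(gene = universe, score = unname(scores),
                      stringsAsFactors = FALSE),
    directed = directed,
    truth = list(
      true_negative_genes = sort(planted_members),
      enriched_sets = names(cfg$planted_complexes)
    )
  )
}

# Probe layout for one experiment: exon / intron / junction rows per intron,
# second introns carried under "<gene>_2".
array_probe_layout <- function(cfg) {
  universe <- sim_universe(cfg)
  if (cfg$n_intron_genes < 1L) {
    stop("need at least one intron-containing gene", call. = FALSE)
  }
  if (cfg$n_intron_genes > cfg$n_genes) {
    stop("more intron genes requested than genes in the universe",
         call. = FALSE)
  }
  intron_genes <- universe[seq_len(cfg$n_intron_genes)]
  set.seed(derive_seed(cfg$seed, 0L, "layout", stream = 3L))
  n_two <- round(cfg$frac_two_intron * cfg$n_intron_genes)
  two_intron <- if (n_two > 0) sort(sample(intron_genes, n_two)) else character(0)

  rows <- rbind(
    data.frame(gene_id = intron_genes, feature = "exon",
               stringsAsFactors = FALSE),
    data.frame(gene_id = intron_genes, feature = "intron",
               stringsAsFactors = FALSE),
    data.frame(gene_id = intron_genes, feature = "junction",
               stringsAsFactors = FALSE)
  )
  if (length(two_intron)) {
    rows <- rbind(rows,
      data.frame(gene_id = paste0(two_intron, "_2"), feature = "intron",
                 stringsAsFactors = FALSE),
      data.frame(gene_id = paste0(two_intron, "_2"), feature = "junction",
                 stringsAsFactors = FALSE))
  }
  list(rows = rows, intron_genes = intron_genes, two_intron = two_intron)
}

#' Generate a synthetic two-color splicing-array experiment
#'
#' For each biological replicate, emits a forward array (mutant in channel 1)
#' and a dye-flipped array (mutant in channel 2). Each intron of each gene
#' contributes exon, intron and junction probes, each spotted `n_tech_reps`
#' times. The expected spot-level log2(mutant/WT) is `exon_effect` for exon
#' and junction probes and `exon_effect + planted IAI` for intron probes, so
#' the Intron Accumulation Index isolates the planted splicing effect from
#' the transcription confounder. Channel intensities follow
#' `baseline * 2^(effect + dye_bias + N(0, noise_sd))` with the dye bias on
#' channel 1; a `flag_rate` fraction of spots carries a negative flag.
#'
#' @param cfg A [sim_config()]. Names of `defect_genes` (after stripping an
#'   optional `"_2"` suffix) must be intron genes.
#' @return List with `arrays` (one element per array: `sample` metadata list
#'   and `spots` data.frame of spot records) and `truth` (list with
#'   `true_iai`, named per probe row, and `true_negative_genes` — intron
#'   genes with no planted effect).
#' @export
generate_array_experiment <- function(cfg) {
  validate_sim_config(cfg)
  layout <- array_probe_layout(cfg)
  rows <- layout$rows

  defect <- cfg$defect_genes
  if (length(defect)) {
    base_ids <- sub("_2$", "", names(defect))
    bad <- setdiff(base_ids, layout$intron_genes)
    if (length(bad)) {
      stop("defect gene(s) not on the intron-gene list: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    bad2 <- setdiff(grep("_2$", names(defect), value = TRUE),
                    paste0(layout$two_intron, "_2"))
    if (length(bad2)) {
      stop("defect planted on a second intron that does not exist: ",
           paste(bad2, collapse = ", "), call. = FALSE)
    }
  }

  exon_eff <- cfg$exon_effect_genes
  base_gene <- sub("_2$", "", rows$gene_id)
  row_exon_effect <- ifelse(base_gene %in% names(exon_eff),
                            exon_eff[base_gene], 0)
  iai_effect <- ifelse(rows$gene_id %in% names(defect),
                       defect[rows$gene_id], 0)
  # intron probes carry the splicing effect on top of the transcription one
  row_effect <- row_exon_effect + ifelse(rows$feature == "intron", iai_effect, 0)

  intron_rows <- rows$feature == "intron"
  true_iai <- iai_effect[intron_rows]
  names(true_iai) <- rows$gene_id[intron_rows]
  planted <- names(true_iai)[true_iai != 0]
  truth <- list(
    true_iai = true_iai,
    true_negative_genes = sort(setdiff(
      unique(sub("_2$", "", names(true_iai))),
      unique(sub("_2$", "", planted))))
  )

  n_spots <- nrow(rows) * cfg$n_tech_reps
  spot_gene <- rep(rows$gene_id, each = cfg$n_tech_reps)
  spot_feature <- rep(rows$feature, each = cfg$n_tech_reps)
  spot_block <- rep(seq_len(cfg$n_tech_reps), times = nrow(rows))
  spot_effect <- rep(row_effect, each = cfg$n_tech_reps)

  arrays <- list()
  for (b in seq_len(cfg$n_bio_reps)) {
    for (orient in c("forward", "flipped")) {
      set.seed(derive_seed(cfg$seed, b, orient))
      probe_baseline <- cfg$baseline_intensity *
        2^stats::rnorm(n_spots, 0, 1)
      noise_mut <- stats::rnorm(n_spots, 0, cfg$noise_sd)
      noise_ref <- stats::rnorm(n_spots, 0, cfg$noise_sd)
      i_mut <- probe_baseline * 2^(spot_effect + noise_mut)
      i_ref <- probe_baseline * 2^(noise_ref)
      if (orient == "forward") {
        i_ch1 <- i_mut * 2^cfg$dye_bias
        i_ch2 <- i_ref
      } else {
        i_ch1 <- i_ref * 2^cfg$dye_bias
        i_ch2 <- i_mut
      }
      flag <- ifelse(stats::runif(n_spots) < cfg$flag_rate, -100L, 0L)
      sample_meta <- list(
        sample_id = sprintf("%s_b%d_%s", cfg$genotype, b, orient),
        genotype = cfg$genotype,
        reference = cfg$reference,
        temperature = cfg$temperature,
        bio_rep = b,
        orientation = orient
      )
      spots <- data.frame(
        gene_id = spot_gene,
        feature = spot_feature,
        block = spot_block,
        i_ch1 = i_ch1,
        i_ch2 = i_ch2,
        flag = flag,
        stringsAsFactors = FALSE
      )
      arrays[[sample_meta$sample_id]] <- list(sample = sample_meta,
                                              spots = spots)
    }
  }
  list(arrays = arrays, truth = truth)
}
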