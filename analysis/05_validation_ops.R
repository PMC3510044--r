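#!/usr/bin/env Rscript
# Stage 5 — orthogonal-validation arithmetic: qPCR unspliced fold changes
# for genes the array called defective (simulated starting quantities from
# the same planted effects), and percent-ubiquitinated-H2B from synthetic
# band intensities.

suppressPackageStartupMessages(library(splicearray))

outdir <- "results/validation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

truth <- jsonlite::read_json("results/simdata/ground_truth.json",
                             simplifyVector = TRUE)
profiles <- read.table("results/arrays/splicing_profiles.tsv", sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)

# qPCR emulation: mutant intron/exon starting-quantity ratio is 2^IAI times
# the wild-type ratio (plus lognormal technical scatter)
set.seed(55)
genes <- c(sprintf("YSN%04dC", c(1, 2, 3)), "YSN0200C")
qpcr <- do.call(rbind, lapply(genes, function(g) {
  iai_true <- truth$array$true_iai[[g]]
  if (is.null(iai_true)) iai_true <- 0
  fc <- vapply(1:3, function(r) {   # 3 biological replicates
    noise <- 2^rnorm(4, 0, 0.1)
    unspliced_fold_change(
      list(gene_id = g, intron_sq = 0.2 * 2^iai_true * noise[1],
           exon_sq = 1 * noise[2]),
      list(gene_id = g, intron_sq = 0.2 * noise[3], exon_sq = 1 * noise[4]))
  }, numeric(1))
  data.frame(gene = g, true_iai = iai_true, fold_change_mean = mean(fc),
             fold_change_sd = sd(fc),
             array_iai = profiles$iai[match(g, profiles$gene_id)])
}))
write_tsv(qpcr, file.path(outdir, "qpcr_fold_changes.tsv"))

# percent ubiquitinated H2B from band intensities (synthetic lanes)
lanes <- data.frame(
  strain = c("WT", "npl3d", "bre1d"),
  ub = c(12, 11.5, 0.2), unmod = c(88, 88.5, 99.8))
lanes$percent_ub <- percent_ub_h2b(lanes$ub, lanes$unmod)
write_tsv(lanes, file.path(outdir, "percent_ub_h2b.tsv"))

cat("qPCR fold changes vs array IAI:\n")
print(qpcr, row.names = FALSE, digits = 3)
cat("\npercent ubiquitinated H2B:\n")
print(lanes, row.names = FALSE, digits = 3)
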