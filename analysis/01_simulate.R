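#!/usr/bin/env Rscript
# Stage 1 — simulate the study's raw inputs with known ground truth:
# a complex catalog (GMT), genetic-interaction screens at two temperatures
# plus E-MAP scores and directed-genetics calls (TSV), and a two-color
# splicing-array experiment (GPR-dialect spot tables + sample manifest).

suppressPackageStartupMessages(library(splicearray))

outdir <- "results/simdata"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

planted_iai <- setNames(rep(1.0, 60), sprintf("YSN%04dC", 1:60))
exon_conf <- setNames(rep(0.8, 30), sprintf("YSN%04dC", 101:130))
cfg <- sim_config(seed = 20120101, n_genes = 4800, n_intron_genes = 300,
                  defect_genes = planted_iai, exon_effect_genes = exon_conf,
                  planted_complexes = c(RAD6_complex = -4),
                  genotype = "npl3d_bre1d")

catalog <- generate_catalog(cfg)
write_gmt(catalog, file.path(outdir, "complex_catalog.gmt"))
writeLines(catalog$universe, file.path(outdir, "universe.txt"))

ia <- generate_interaction_data(cfg, catalog)
write_tsv(data.frame(gene = ia$sga30), file.path(outdir, "sga30_hits.tsv"))
write_tsv(data.frame(gene = ia$sga37), file.path(outdir, "sga37_hits.tsv"))
write_tsv(data.frame(gene = ia$directed), file.path(outdir, "directed_hits.tsv"))
write_tsv(ia$emap, file.path(outdir, "emap_scores.tsv"))

exp1 <- generate_array_experiment(cfg)
manifest <- do.call(rbind, lapply(exp1$arrays, function(a)
  as.data.frame(a$sample, stringsAsFactors = FALSE)))
manifest$file <- paste0(manifest$sample_id, ".tsv")
write_tsv(manifest, file.path(outdir, "array_manifest.tsv"))
for (a in exp1$arrays) {
  write_spot_table(a$spots, file.path(outdir, paste0(a$sample$sample_id, ".tsv")))
}

write_ground_truth(list(array = exp1$truth, screens = ia$truth),
                   file.path(outdir, "ground_truth.json"))

cat(sprintf(
  "simulated %d-gene universe: %d catalog sets, %d/%d SGA hits (30C/37C),\n%d arrays x %d spots; %d planted splicing defects, 1 planted complex\n",
  cfg$n_genes, length(catalog), length(ia$sga30), length(ia$sga37),
  length(exp1$arrays), nrow(exp1$arrays[[1]]$spots),
  sum(exp1$truth$true_iai != 0)))
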