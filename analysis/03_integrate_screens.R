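#!/usr/bin/env Rscript
# Stage 3 — integrate the 30C SGA hits, directed-genetics calls and E-MAP
# negatives (score <= -2.5) into one negative-interaction gene set with
# provenance, and summarize per-screen hit rates.

suppressPackageStartupMessages(library(splicearray))

indir <- "results/simdata"
outdir <- "results/integration"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

universe <- readLines(file.path(indir, "universe.txt"))
read_hits <- function(f) read.table(file.path(indir, f), sep = "\t",
                                    header = TRUE,
                                    stringsAsFactors = FALSE)$gene
sga30 <- read_hits("sga30_hits.tsv")
sga37 <- read_hits("sga37_hits.tsv")
directed <- read_hits("directed_hits.tsv")
emap <- read_scores_table(file.path(indir, "emap_scores.tsv"))

negatives <- call_emap_negatives(emap, threshold = -2.5)
integrated <- integrate_negative_set(sga30, directed, negatives, universe)

write_tsv(data.frame(
  gene = integrated$genes,
  sources = vapply(integrated$provenance, paste, character(1), collapse = ";")),
  file.path(outdir, "integrated_negative_set.tsv"))

rates <- data.frame(
  screen = c("sga30", "sga37", "emap<=-2.5", "integrated"),
  n_hits = c(length(sga30), length(sga37), length(negatives),
             length(integrated$genes)),
  n_screened = length(universe))
rates$percent <- mapply(screen_summary, rates$n_hits, rates$n_screened)
write_tsv(rates, file.path(outdir, "screen_summary.tsv"))

print(integrated)
cat(paste(sprintf("%-12s %4d hits  %4.1f%% of %d", rates$screen, rates$n_hits,
                  rates$percent, rates$n_screened), collapse = "\n"), "\n")
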