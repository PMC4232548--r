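#!/usr/bin/env Rscript

## Stage 6: viral integration sites.
##
## Classifies assembly scaffolds from exact-match alignment hits against
## the viral and host genomes, locates junctions on mixed scaffolds,
## corroborates them with chimeric read pairs, and calls junction zygosity
## (an insertion carried by all alleles leaves no reads spanning the
## host-only junction).

suppressMessages(library(genomescan))

cfg <- list(
  out_dir = "results/viral",
  reference = "results/sim/ref.fa",
  scaffolds = "results/sim/scaffolds.fa",
  viral = "results/sim/viral.fa",
  pairs = "results/sim/pairs.fa",
  samples = list(TEST = list(vcf = "results/sim/TEST.vcf")),
  stages = c("filter", "integrations"))
res <- run_pipeline(cfg)

cat("Scaffold classification:\n")
print(res$integrations$scaffold_classes)
cat("\nDetected integration sites:\n")
print(res$integrations$sites)
truth <- read_truth_tsv("results/sim/truth_viral_sites.tsv")
cat("\nPlanted truth:\n")
print(truth[, c("chrom", "pos", "orientation", "all_alleles")])
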