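#!/usr/bin/env Rscript

## Stage 5: coding-sequence impact.
##
## Projects filtered variants onto the CDS gene models, classifies effects
## (synonymous / nonsynonymous with Grantham severity / stop-gain /
## frameshift / in-frame indel) and aggregates candidate inactivated genes:
## genes with a sample-unique homozygous damaging hit, and genes with >= 2
## damaging hits in possibly heteroallelic combination.

suppressMessages(library(genomescan))

cfg <- list(
  out_dir = "results/coding",
  reference = "results/sim/ref.fa",
  genes = "results/sim/genes.gff3",
  samples = list(TEST = list(vcf = "results/sim/TEST.vcf"),
                 CTRL1 = list(vcf = "results/sim/CTRL1.vcf"),
                 CTRL2 = list(vcf = "results/sim/CTRL2.vcf")),
  stages = c("filter", "unique", "coding"))
res <- run_pipeline(cfg)

eff <- res$coding$TEST$effects
cat("TEST coding effects by category:\n")
print(table(eff$category))
cat("\nGenes with unique homozygous damaging hits:\n")
print(res$coding$TEST$genes$unique_hom_genes)
cat("\nGenes with >= 2 damaging hits (heteroallelic candidates):\n")
print(res$coding$TEST$genes$heteroallelic_genes)
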