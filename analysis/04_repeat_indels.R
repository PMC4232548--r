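#!/usr/bin/env Rscript

## Stage 4: indels at tandem repeats.
##
## Left-normalizes the sample-unique indels, classifies deletions that
## precisely remove one repeat unit and insertions that create a tandem
## duplication, and contrasts the per-length fractions of the TEST sample
## against the mean of the controls (the planted excess in TEST shows up as
## enrichment > 1).

suppressMessages(library(genomescan))

cfg <- list(
  out_dir = "results/repeat_indels",
  reference = "results/sim/ref.fa",
  samples = list(TEST = list(vcf = "results/sim/TEST.vcf"),
                 CTRL1 = list(vcf = "results/sim/CTRL1.vcf"),
                 CTRL2 = list(vcf = "results/sim/CTRL2.vcf")),
  params = list(test_sample = "TEST"),
  stages = c("filter", "unique", "repeat_indels"))
res <- suppressWarnings(run_pipeline(cfg))

cat("TEST deletions at repeats, by length:\n")
print(res$repeat_curves$TEST$deletion)
cat("\nEnrichment of TEST repeat deletions vs control mean:\n")
print(res$repeat_enrichment)
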