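#!/usr/bin/env Rscript

## Stage 1: build the synthetic study inputs.
##
## Generates the reference genome (tandem-repeat catalog, gene models), a
## three-sample cohort sharing an ancestral variant pool (the TEST sample
## carries a higher fraction of indels at tandem repeats), a coverage track
## over the configured ploidy map (disomic chr1, trisomic chr2, tetrasomic
## chr3, monosomic chrW), and viral-integration evidence (mixed scaffolds,
## decoys, chimeric read pairs). Everything downstream reads only the files
## written here.

suppressMessages(library(genomescan))

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
genome <- generate_reference(cfg)
print(genome)

write_genome_fasta(genome, "results/sim/ref.fa")
write_gene_models_gff(genome, "results/sim/genes.gff3")
write_repeat_catalog(genome, "results/sim/repeats.tsv")

cohort <- simulate_cohort(
  genome, samples = c("TEST", "CTRL1", "CTRL2"), shared_fraction = 0.6,
  overrides = list(TEST = list(repeat_indel_fraction = 0.45)), seed = 2)
for (s in names(cohort$samples)) {
  truth <- cohort$samples[[s]]
  write_variant_vcf(truth, sprintf("results/sim/%s.vcf", s), genome)
  write_truth_tsv(truth, sprintf("results/sim/truth_%s.tsv", s))
  cat(sprintf("%s: %d variants (%d private)\n", s, nrow(truth),
              sum(truth$origin == "private")))
}

coverage <- simulate_coverage(genome, het_variants = cohort$samples$TEST,
                              seed = 3)
write_coverage_track(coverage$track, "results/sim/coverage.tsv")
write_allele_depth_tsv(coverage$allele_depth, "results/sim/allele_depth.tsv")

viral <- sim_viral_genome(seed = 4)
planted <- plant_viral_insertions(genome, viral, seed = 5)
write_genome_fasta(setNames(viral$seq, viral$name), "results/sim/viral.fa")
write_scaffolds_fasta(planted$scaffolds, "results/sim/scaffolds.fa")
write_read_pairs_fasta(planted$pairs, "results/sim/pairs.fa")
write_truth_tsv(planted$sites, "results/sim/truth_viral_sites.tsv")
cat(sprintf("planted %d viral sites, %d scaffolds, %d read pairs\n",
            nrow(planted$sites), length(planted$scaffolds),
            nrow(planted$pairs)))
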