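## Shared fixtures, built once per test run and cached.

.fx <- new.env()

## small two-chromosome genome exercising every signal class
tiny_config <- function(seed = 11) {
  sim_config(
    chromosome_lengths = c(chrA = 120000, chrB = 80000, chrC = 60000),
    snv_rate = 5.8,
    het_fraction = 0.469,
    loh_tracts = data.frame(chrom = "chrA", start = 20000L, end = 60000L),
    indel_rate = 0.8,
    repeat_indel_fraction = 0.3,
    ploidy_map = c(chrA = 2, chrB = 3, chrC = 1),
    mean_coverage = 52,
    viral_sites = data.frame(chrom = "chrA", pos = 90000L,
                             orientation = "+", all_alleles = FALSE),
    seed = seed)
}

tiny_genome <- function() {
  if (is.null(.fx$genome)) .fx$genome <- generate_reference(tiny_config())
  .fx$genome
}

tiny_truth <- function() {
  if (is.null(.fx$truth)) {
    .fx$truth <- plant_variants(tiny_genome(), sample = "S1")
  }
  .fx$truth
}

## truth -> variant records (as read_vcf would produce, skipping the file)
truth_as_records <- function(truth) {
  data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
             alt = truth$alt, qual = truth$qual, depth = truth$depth,
             genotype = ifelse(truth$zygosity == "hom", "hom_alt", "het"),
             stringsAsFactors = FALSE)
}

## three-sample cohort with a repeat-deletion excess in the test sample,
## plus every pipeline input written to a directory
cohort_fixture <- function() {
  if (is.null(.fx$cohort)) {
    g <- tiny_genome()
    .fx$cohort <- simulate_cohort(
      g, samples = c("TEST", "CTRL1", "CTRL2"), shared_fraction = 0.6,
      overrides = list(TEST = list(repeat_indel_fraction = 0.45)),
      seed = 101)
  }
  .fx$cohort
}

pipeline_dir <- function() {
  if (is.null(.fx$pipedir)) {
    dir <- file.path(tempdir(), "gsfix")
    dir.create(dir, showWarnings = FALSE)
    g <- tiny_genome()
    co <- cohort_fixture()
    write_genome_fasta(g, file.path(dir, "ref.fa"))
    write_gene_models_gff(g, file.path(dir, "genes.gff3"))
    for (s in names(co$samples)) {
      write_variant_vcf(co$samples[[s]], file.path(dir, paste0(s, ".vcf")), g)
    }
    cov <- simulate_coverage(g, het_variants = co$samples$TEST, seed = 55)
    write_coverage_track(cov$track, file.path(dir, "coverage.tsv"))
    write_allele_depth_tsv(cov$allele_depth, file.path(dir, "ad.tsv"))
    vir <- sim_viral_genome(seed = 77)
    vp <- plant_viral_insertions(g, vir, seed = 78)
    write_scaffolds_fasta(vp$scaffolds, file.path(dir, "scaffolds.fa"))
    write_genome_fasta(setNames(vir$seq, vir$name), file.path(dir, "viral.fa"))
    write_read_pairs_fasta(vp$pairs, file.path(dir, "pairs.fa"))
    .fx$viral_truth <- vp
    .fx$pipedir <- dir
  }
  .fx$pipedir
}

viral_truth <- function() {
  pipeline_dir()
  .fx$viral_truth
}

pipeline_config <- function(out_dir) {
  dir <- pipeline_dir()
  list(out_dir = out_dir,
       reference = file.path(dir, "ref.fa"),
       genes = file.path(dir, "genes.gff3"),
       coverage = file.path(dir, "coverage.tsv"),
       allele_depth = file.path(dir, "ad.tsv"),
       scaffolds = file.path(dir, "scaffolds.fa"),
       viral = file.path(dir, "viral.fa"),
       pairs = file.path(dir, "pairs.fa"),
       samples = list(TEST = list(vcf = file.path(dir, "TEST.vcf")),
                      CTRL1 = list(vcf = file.path(dir, "CTRL1.vcf")),
                      CTRL2 = list(vcf = file.path(dir, "CTRL2.vcf"))),
       params = list(test_sample = "TEST",
                     baseline_chroms = "chrA",
                     block_size = 10000, min_hom = 25))
}

## independent splice-and-translate oracle used by the coding tests:
## edit the chromosome, re-extract the spliced CDS, translate
splice_cds <- function(gene, sequences) {
  seq <- sequences[[gene$chrom[1]]]
  parts <- vapply(seq_len(nrow(gene)), function(i)
    substr(seq, gene$start[i] + 1, gene$end[i]), character(1))
  cds <- paste(parts, collapse = "")
  if (gene$strand[1] == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

## brute-force tandem-repeat scanner oracles (independent of the flank-based
## classifier): enumerate all tandem pairs in the reference and test whether
## the edit removes / creates exactly one copy
oracle_repeat_deletion <- function(ref, pos, L) {
  n <- nchar(ref)
  a <- pos + 1            # deleted interval [a, b]
  b <- pos + L
  if (b > n || n < 2 * L) return(FALSE)
  for (i in seq_len(n - 2 * L + 1)) {
    if (substr(ref, i, i + L - 1) == substr(ref, i + L, i + 2 * L - 1)) {
      if ((a == i && b == i + L - 1) || (a == i + L && b == i + 2 * L - 1)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

oracle_tandem_insertion <- function(ref, pos, ins) {
  L <- nchar(ins)
  edited <- paste0(substr(ref, 1, pos), ins,
                   substr(ref, pos + 1, nchar(ref)))
  a <- pos + 1            # inserted interval [a, b] in the edited sequence
  b <- pos + L
  n <- nchar(edited)
  for (i in seq_len(max(0, n - 2 * L + 1))) {
    if (substr(edited, i, i + L - 1) == substr(edited, i + L, i + 2 * L - 1)) {
      if ((a == i && b == i + L - 1) || (a == i + L && b == i + 2 * L - 1)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

## all strings of length n over an alphabet
all_strings <- function(n, alphabet) {
  if (n == 0) return("")
  g <- do.call(expand.grid, rep(list(alphabet), n))
  do.call(paste0, g)
}
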