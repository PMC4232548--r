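test_that("config validation rejects bad fields by name", {
  expect_error(sim_config(chromosome_lengths = c(100000)), "chromosome_lengths")
  expect_error(sim_config(chromosome_lengths = c(chr1 = -5)),
               "chromosome_lengths")
  expect_error(sim_config(spectrum_weights = rep(0, 6)), "spectrum_weights")
  expect_error(sim_config(het_fraction = 1.4), "het_fraction")
  expect_error(sim_config(loh_tracts = data.frame(chrom = "chr1",
                                                  start = 0, end = 2e6)),
               "loh_tracts")
  expect_error(sim_config(ploidy_map = c(chr1 = 2)), "ploidy_map")
  expect_error(sim_config(ploidy_map = c(chr1 = 0, chr2 = 2, chr3 = 2,
                                         chrW = 1)), "ploidy_map")
  expect_error(sim_config(viral_sites = data.frame(chrom = "chr1", pos = 100,
                                                   orientation = "x")),
               "viral_sites")
})

test_that("reference generation is deterministic under seed, differs across seeds", {
  cfg <- sim_config(chromosome_lengths = c(chr1 = 100000),
                    ploidy_map = c(chr1 = 2),
                    loh_tracts = data.frame(chrom = character(0),
                                            start = integer(0),
                                            end = integer(0)),
                    viral_sites = data.frame(chrom = character(0),
                                             pos = integer(0),
                                             orientation = character(0)),
                    seed = 42)
  g1 <- generate_reference(cfg)
  g2 <- generate_reference(cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$repeats, g2$repeats)
  expect_equal(nchar(g1$sequences[["chr1"]]), 100000)
  cfg2 <- cfg
  cfg2$seed <- 43L
  g3 <- generate_reference(cfg2)
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("every repeat catalog entry matches the reference substring", {
  g <- tiny_genome()
  r <- g$repeats
  expect_gt(nrow(r), 20)
  expect_true(all(nchar(r$unit) >= 1 & nchar(r$unit) <= 15))
  expect_true(all(r$copies >= 2))
  run <- vapply(seq_len(nrow(r)), function(i)
    substr(g$sequences[[r$chrom[i]]], r$start[i] + 1, r$end[i]), character(1))
  expected <- vapply(seq_len(nrow(r)), function(i)
    paste(rep(r$unit[i], r$copies[i]), collapse = ""), character(1))
  expect_identical(run, expected)
})

test_that("gene models are valid multi-exon CDS on both strands", {
  g <- tiny_genome()
  genes <- g$genes
  for (chrom in names(g$sequences)) {
    sub <- genes[genes$chrom == chrom, ]
    expect_gte(length(unique(sub$gene_id)), 2)
    expect_setequal(unique(sub$strand), c("+", "-"))
  }
  for (gid in unique(genes$gene_id)) {
    gene <- genes[genes$gene_id == gid, ]
    expect_gte(nrow(gene), 2)   # multi-exon
    cds <- splice_cds(gene, g$sequences)
    expect_equal(nchar(cds) %% 3, 0)
    prot <- translate_cds(cds)
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    ## no internal stop
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("gene models survive a GFF3 round trip", {
  g <- tiny_genome()
  path <- tempfile(fileext = ".gff3")
  write_gene_models_gff(g, path)
  back <- read_gene_models_gff(path)
  orig <- g$genes[order(g$genes$gene_id, g$genes$start),
                  c("gene_id", "chrom", "strand", "start", "end")]
  rownames(orig) <- NULL
  expect_equal(back[, c("gene_id", "chrom", "strand", "start", "end")], orig)
})

test_that("planted variants honor LOH tracts, ploidy-1 and repeat flags", {
  g <- tiny_genome()
  tv <- tiny_truth()
  ## all-homozygous inside the planted LOH tract
  in_tract <- tv$chrom == "chrA" & tv$pos > 20000 & tv$pos <= 60000
  expect_gt(sum(in_tract), 100)
  expect_true(all(tv$zygosity[in_tract] == "hom"))
  ## ploidy-1 chromosome carries no heterozygous variants
  expect_true(all(tv$zygosity[tv$chrom == "chrC"] == "hom"))
  ## repeat-flagged deletions pass the repeat-unit test; others fail it
  del <- tv[tv$type == "del", ]
  verdict <- vapply(seq_len(nrow(del)), function(i) {
    seq <- g$sequences[[del$chrom[i]]]
    nv <- normalize_indel(seq, del$pos[i], del$ref[i], del$alt[i])
    is_repeat_unit_deletion(seq, nv$pos, nv$seq)$at_repeat
  }, logical(1))
  expect_identical(verdict, del$at_repeat)
  ins <- tv[tv$type == "ins", ]
  verdict_i <- vapply(seq_len(nrow(ins)), function(i) {
    seq <- g$sequences[[ins$chrom[i]]]
    nv <- normalize_indel(seq, ins$pos[i], ins$ref[i], ins$alt[i])
    is_tandem_duplication_insertion(seq, nv$pos, nv$seq)$at_repeat
  }, logical(1))
  expect_identical(verdict_i, ins$at_repeat)
  ## with repeat_indel_fraction = 0 no deletion passes the repeat test
  cfg0 <- tiny_config()
  cfg0$repeat_indel_fraction <- 0
  tv0 <- plant_variants(g, cfg0, seed = 9)
  del0 <- tv0[tv0$type == "del", ]
  verdict0 <- vapply(seq_len(nrow(del0)), function(i) {
    seq <- g$sequences[[del0$chrom[i]]]
    nv <- normalize_indel(seq, del0$pos[i], del0$ref[i], del0$alt[i])
    is_repeat_unit_deletion(seq, nv$pos, nv$seq)$at_repeat
  }, logical(1))
  expect_false(any(verdict0))
})

test_that("planting is deterministic under seed", {
  g <- tiny_genome()
  t1 <- plant_variants(g, seed = 77)
  t2 <- plant_variants(g, seed = 77)
  expect_identical(t1, t2)
})

test_that("VCF round trip preserves all truth-relevant fields", {
  g <- tiny_genome()
  tv <- tiny_truth()
  path <- tempfile(fileext = ".vcf")
  write_variant_vcf(tv, path, g)
  rec <- read_vcf(path)
  expect_equal(nrow(rec), nrow(tv))
  expect_identical(rec$chrom, tv$chrom)
  expect_identical(rec$pos, tv$pos)
  expect_identical(rec$ref, tv$ref)
  expect_identical(rec$alt, tv$alt)
  expect_identical(rec$depth, tv$depth)
  expect_identical(rec$genotype,
                   ifelse(tv$zygosity == "hom", "hom_alt", "het"))
  expect_equal(rec$qual, tv$qual, tolerance = 1e-9)
})

test_that("coverage track has the right Poisson means and BAF structure", {
  g <- tiny_genome()
  tv <- tiny_truth()
  cov <- simulate_coverage(g, het_variants = tv, seed = 5)
  tr <- cov$track
  ## per-chromosome mean ~ 52 * ploidy / 2, SE from the Poisson window model
  check_mean <- function(chrom, ploidy) {
    d <- tr$depth[tr$chrom == chrom]
    expected <- 52 * ploidy / 2
    se <- sqrt(expected / length(d))
    expect_lt(abs(mean(d) - expected), 3 * se)
  }
  check_mean("chrA", 2)
  check_mean("chrB", 3)
  check_mean("chrC", 1)
  ## trisomic chromosome: BAFs concentrate near 1/3 and 2/3
  ad <- cov$allele_depth
  b <- ad[ad$chrom == "chrB", ]
  baf <- b$alt_count / (b$ref_count + b$alt_count)
  expect_gt(nrow(b), 100)
  expect_true(all(abs(b$baf_true - 1/3) < 1e-9 | abs(b$baf_true - 2/3) < 1e-9))
  expect_gt(mean(abs(baf - 0.5) > 0.05), 0.5)
})

test_that("viral planting emits junction-exact scaffolds and honors flags", {
  g <- tiny_genome()
  vir <- sim_viral_genome(seed = 3)
  vp <- plant_viral_insertions(g, vir, seed = 4)
  site <- vp$sites[1, ]
  scf <- vp$scaffolds[[site$scaffold]]
  host_part <- substr(scf, 1, 500)
  ## host flank ends exactly at the junction coordinate
  expect_identical(host_part,
                   substr(g$sequences[[site$chrom]], site$pos - 499, site$pos))
  ## remainder is viral LTR prefix (forward site)
  expect_identical(substr(scf, 501, nchar(scf)),
                   substr(vir$seq, 1, nchar(scf) - 500))
  ## non-all-allele site has spanning pairs
  expect_gt(sum(vp$pairs$category == "spanning"), 0)

  ## all-allele flag: no spanning pairs for that site
  sites_aa <- data.frame(chrom = "chrA", pos = 50000L, orientation = "+",
                         all_alleles = TRUE)
  vp_aa <- plant_viral_insertions(g, vir, sites = sites_aa, seed = 6)
  expect_equal(sum(vp_aa$pairs$category == "spanning"), 0)

  ## zero sites: no mixed scaffolds (all decoys classify clean)
  vp0 <- plant_viral_insertions(g, vir,
                                sites = data.frame(chrom = character(0),
                                                   pos = integer(0),
                                                   orientation = character(0)),
                                seed = 7)
  expect_equal(nrow(vp0$sites), 0)
  ## site too close to the end is rejected
  expect_error(plant_viral_insertions(
    g, vir, sites = data.frame(chrom = "chrA", pos = 300L, orientation = "+"),
    seed = 8), "too close")
})
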