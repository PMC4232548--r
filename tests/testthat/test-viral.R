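hit_row <- function(qseqid, sseqid, len, qstart, qend, sstart, send,
                    pident = 100) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = len, mismatch = 0L, gapopen = 0L, qstart = qstart,
             qend = qend, sstart = sstart, send = send, evalue = 0,
             bitscore = 2 * len, stringsAsFactors = FALSE)
}

test_that("scaffold classification follows the hit-threshold rules", {
  v <- hit_row("s", "virus", 500, 1, 500, 1, 500)
  h <- hit_row("s", "chr1", 400, 501, 900, 1000, 1399)
  expect_equal(classify_scaffold(v, h, 900)$category, "mixed")
  expect_equal(classify_scaffold(v, NULL, 500)$category, "viral_only")
  expect_equal(classify_scaffold(NULL, h, 400)$category, "host_only")
  ## a 60-bp viral hit on a 30-kb scaffold with host hits: host_only with
  ## the short viral evidence annotated as excluded
  short_v <- hit_row("s", "phage", 60, 1, 60, 1, 60)
  cl <- classify_scaffold(short_v, h, 30000)
  expect_equal(cl$category, "host_only")
  expect_true(cl$excluded_short)
  ## no hits at all: host_only with zero-evidence flag
  cl0 <- classify_scaffold(NULL, NULL, 1000)
  expect_equal(cl0$category, "host_only")
  expect_true(cl0$zero_evidence)
  ## identity below threshold is discarded
  lowid <- hit_row("s", "virus", 500, 1, 500, 1, 500, pident = 80)
  expect_equal(classify_scaffold(lowid, h, 900)$category, "host_only")
})

test_that("junction location and orientation come from hit adjacency", {
  ## scaffold: host chr1:59501-60000 then viral LTR
  h <- hit_row("s", "chr1", 500, 1, 500, 59501, 60000)
  v <- hit_row("s", "virus", 250, 501, 750, 1, 250)
  site <- locate_integration(h, v)
  expect_equal(site$pos, 60000)
  expect_equal(site$orientation, "+")
  expect_false(site$unresolved)
  ## reverse-complemented viral segment: reverse orientation
  vr <- hit_row("s", "virus", 250, 501, 750, 250, 1)
  expect_equal(locate_integration(h, vr)$orientation, "-")
  ## viral before host on the scaffold: junction at the host hit start
  h2 <- hit_row("s", "chr1", 500, 251, 750, 60001, 60500)
  v2 <- hit_row("s", "virus", 250, 1, 250, 1, 250)
  expect_equal(locate_integration(h2, v2)$pos, 60001)
  ## a 200-bp unexplained spacer flags the candidate unresolved
  vgap <- hit_row("s", "virus", 250, 701, 950, 1, 250)
  expect_true(locate_integration(h, vgap)$unresolved)
})

test_that("read-pair clustering needs minimum support and finds the junction side", {
  g <- tiny_genome()
  vir <- sim_viral_genome(seed = 13)
  vp <- plant_viral_insertions(g, vir, seed = 14)
  sites <- readpair_integration(vp$pairs, vir$seq, g$sequences)
  expect_equal(nrow(sites), 1)
  truth <- vp$sites[1, ]
  expect_equal(sites$chrom, truth$chrom)
  expect_lte(abs(sites$pos - truth$pos), 350)
  expect_gte(sites$support, 3)
  ## spanning + background pairs alone produce no sites
  quiet <- vp$pairs[vp$pairs$category != "junction", ]
  expect_equal(nrow(readpair_integration(quiet, vir$seq, g$sequences)), 0)
  ## fewer pairs than the support threshold: not reported
  two <- vp$pairs[vp$pairs$category == "junction", ][1:2, ]
  expect_equal(nrow(readpair_integration(two, vir$seq, g$sequences)), 0)
})

test_that("junction zygosity follows the spanning/support rule", {
  expect_equal(junction_zygosity(0, 20), "all_alleles")
  expect_equal(junction_zygosity(10, 10), "partial")
  expect_equal(junction_zygosity(1, 2), "no_call")
  expect_equal(junction_zygosity(2, 10), "no_call")
  expect_error(junction_zygosity(-1, 2))
})

test_that("end-to-end detection recovers planted sites with evidence and zygosity", {
  g <- tiny_genome()
  vir <- sim_viral_genome(seed = 13)
  vp <- plant_viral_insertions(g, vir, seed = 14)
  det <- detect_integrations(vp$scaffolds, vir, g$sequences, vp$pairs)
  ## every scaffold got exactly one category, matching its construction
  expect_equal(nrow(det$scaffold_classes), length(vp$scaffolds))
  truth <- vp$scaffold_truth
  mixed_ids <- truth$scaffold[!is.na(truth$site_id)]
  expect_setequal(
    det$scaffold_classes$scaffold[det$scaffold_classes$category == "mixed"],
    mixed_ids)
  ## the planted junction is recovered exactly by the scaffold path
  expect_equal(nrow(det$sites), 1)
  expect_equal(det$sites$pos, vp$sites$pos[1])
  expect_equal(det$sites$orientation, vp$sites$orientation[1])
  expect_equal(det$sites$evidence, "both")
  ## tiny fixture site is not all-allele, and spanning pairs exist
  expect_equal(det$sites$zygosity, "partial")
})

test_that("endogenous-virus exclusion list removes those sequences from evidence", {
  g <- tiny_genome()
  vir <- sim_viral_genome(seed = 13)
  vp <- plant_viral_insertions(g, vir, seed = 14)
  det <- detect_integrations(vp$scaffolds,
                             setNames(vir$seq, "erv1"), g$sequences,
                             pairs = NULL, exclude_viral_ids = "erv1")
  expect_equal(nrow(det$sites), 0)
  expect_false(any(det$scaffold_classes$category %in%
                     c("mixed", "viral_only")))
})

test_that("insertion-free genomes yield zero integration sites", {
  vir <- sim_viral_genome(seed = 50)
  for (s in 1:3) {
    cfg <- sim_config(chromosome_lengths = c(c1 = 30000, c2 = 20000),
                      ploidy_map = c(c1 = 2, c2 = 2),
                      loh_tracts = data.frame(chrom = character(0),
                                              start = integer(0),
                                              end = integer(0)),
                      viral_sites = data.frame(chrom = character(0),
                                               pos = integer(0),
                                               orientation = character(0)),
                      seed = 400 + s)
    g <- generate_reference(cfg)
    vp <- plant_viral_insertions(g, vir, seed = 500 + s)
    det <- detect_integrations(vp$scaffolds, vir, g$sequences, vp$pairs)
    expect_equal(nrow(det$sites), 0)
    expect_false(any(det$scaffold_classes$category == "mixed"))
  }
})
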