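## hand-built two-exon gene on a tiny chromosome for arithmetic checks:
## CDS = ATG GAT TGC AAA TAA split as exon1 = 7 bp, exon2 = 8 bp
tiny_gene <- function(strand = "+") {
  cds <- "ATGGATTGCAAATAA"
  intron <- "GGGGG"
  if (strand == "+") {
    seq <- paste0("TTTT", substr(cds, 1, 7), intron, substr(cds, 8, 15),
                  "TTTT")
    exons <- data.frame(start = c(4L, 16L), end = c(11L, 24L))
  } else {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    seq <- paste0("TTTT", substr(rc, 1, 8), intron, substr(rc, 9, 15),
                  "TTTT")
    exons <- data.frame(start = c(4L, 17L), end = c(12L, 24L))
  }
  gene <- data.frame(gene_id = "g1", chrom = "t", strand = strand,
                     exon = 1:2, start = exons$start, end = exons$end,
                     stringsAsFactors = FALSE)
  list(gene = gene, reference = c(t = seq))
}

test_that("forward-strand SNVs project onto the right codon", {
  fx <- tiny_gene("+")
  ## CDS position 4 (the G of GAT) = codon 2, offset 0; genomic pos 8
  pr <- project_variant(fx$gene, 8, "G", "C", fx$reference)
  expect_equal(pr$cds_pos, 4)
  expect_equal(pr$codon_index, 2)
  expect_equal(pr$codon_offset, 0)
  expect_equal(pr$ref_codon, "GAT")
  expect_equal(pr$alt_codon, "CAT")
  ## position in the second exon: CDS pos 9 (C of TGC) = genomic 17
  pr2 <- project_variant(fx$gene, 18, "C", "G", fx$reference)
  expect_equal(pr2$cds_pos, 9)
  expect_equal(pr2$ref_codon, "TGC")
  expect_equal(pr2$alt_codon, "TGG")
  ## intronic position returns NULL
  expect_null(project_variant(fx$gene, 13, "G", "A", fx$reference))
  ## mismatching ref allele is rejected
  expect_error(project_variant(fx$gene, 8, "A", "C", fx$reference),
               "does not match")
})

test_that("reverse-strand SNVs are complemented in codon space", {
  fx <- tiny_gene("-")
  cds <- splice_cds(fx$gene, fx$reference)
  expect_equal(cds, "ATGGATTGCAAATAA")
  ## genomic base pairing with CDS position 4 (G): on the minus strand the
  ## genomic base is C; changing it to T gives codon GAT -> AAT
  ## locate via projection: find the genomic position whose cds_pos is 4
  hit <- NULL
  for (p in (fx$gene$start[1] + 1):fx$gene$end[2]) {
    base <- substr(fx$reference[["t"]], p, p)
    pr <- tryCatch(project_variant(fx$gene, p, base,
                                   setdiff(c("A", "C", "G", "T"), base)[1],
                                   fx$reference),
                   error = function(e) NULL)
    if (!is.null(pr) && pr$cds_pos == 4) {
      hit <- list(pos = p, base = base)
      break
    }
  }
  expect_false(is.null(hit))
  expect_equal(hit$base, "C")   # complement of CDS G
  pr <- project_variant(fx$gene, hit$pos, "C", "T", fx$reference)
  expect_equal(pr$ref_codon, "GAT")
  expect_equal(pr$alt_codon, "AAT")
})

test_that("codon-change classification follows the genetic code", {
  expect_equal(classify_snv_effect("AAA", "AAG"), "synonymous")
  expect_equal(classify_snv_effect("TGC", "TGA"), "stop_gain")
  expect_equal(classify_snv_effect("TGC", "TGG"), "nonsynonymous")
  expect_equal(classify_snv_effect("TAA", "CAA"), "stop_loss")
  expect_error(classify_snv_effect("AXA", "AAA"), "invalid codon")
})

test_that("Grantham lookups match the published distances and bands", {
  g <- grantham_matrix()
  expect_equal(dim(g), c(20, 20))
  expect_true(all(g == t(g)))          # symmetric
  expect_true(all(diag(g) == 0))
  li <- grantham_severity("Leu", "Ile")
  expect_equal(li$score, 5)
  expect_equal(li$severity, "conservative")
  cw <- grantham_severity("Cys", "Trp")
  expect_equal(cw$score, 215)
  expect_equal(cw$severity, "radical")
  expect_equal(grantham_severity("R", "K")$score, 26)
  expect_equal(grantham_severity("D", "E")$score, 45)
  ## identity
  expect_equal(grantham_severity("A", "A")$score, 0)
  expect_equal(grantham_severity("A", "A")$severity, "conservative")
  ## one example per severity band
  expect_equal(grantham_severity("S", "P")$severity,
               "moderately_conservative")                                   # 74
  expect_equal(grantham_severity("L", "R")$severity, "moderately_radical")  # 102
  expect_equal(grantham_severity("G", "W")$severity, "radical")             # 184
  expect_error(grantham_severity("X", "A"), "nonstandard")
})

test_that("indel coding effects follow the frame and boundary rules", {
  fx <- tiny_gene("+")
  gene <- fx$gene
  ## 3-bp deletion fully inside exon 2 (anchor 17, deletes 18-20)
  e1 <- classify_indel_effect(gene, 17, substr(fx$reference[["t"]], 17, 20),
                              substr(fx$reference[["t"]], 17, 17))
  expect_equal(e1$category, "inframe_indel")
  expect_false(e1$boundary)
  ## 2-bp deletion inside exon 1 -> frameshift
  e2 <- classify_indel_effect(gene, 5, substr(fx$reference[["t"]], 5, 7),
                              substr(fx$reference[["t"]], 5, 5))
  expect_equal(e2$category, "frameshift_indel")
  expect_false(e2$boundary)
  ## 3-bp deletion straddling the exon-1 end (deletes 10-12, exon ends 11)
  e3 <- classify_indel_effect(gene, 9, substr(fx$reference[["t"]], 9, 12),
                              substr(fx$reference[["t"]], 9, 9))
  expect_equal(e3$category, "frameshift_indel")
  expect_true(e3$boundary)
  ## intronic deletion is noncoding
  e4 <- classify_indel_effect(gene, 12, substr(fx$reference[["t"]], 12, 14),
                              substr(fx$reference[["t"]], 12, 12))
  expect_equal(e4$category, "noncoding")
  ## in-frame insertion inside exon 1
  e5 <- classify_indel_effect(gene, 6, substr(fx$reference[["t"]], 6, 6),
                              paste0(substr(fx$reference[["t"]], 6, 6), "GGG"))
  expect_equal(e5$category, "inframe_indel")
  e6 <- classify_indel_effect(gene, 6, substr(fx$reference[["t"]], 6, 6),
                              paste0(substr(fx$reference[["t"]], 6, 6), "GG"))
  expect_equal(e6$category, "frameshift_indel")
})

test_that("gene aggregation separates unique-homozygous and heteroallelic lists", {
  eff <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3", "g4", "g4"),
    chrom = "c", pos = c(1, 10, 20, 30, 40, 50),
    ref = "A", alt = "G",
    kind = "snv",
    category = c("stop_gain", "nonsynonymous", "nonsynonymous",
                 "synonymous", "frameshift_indel", "stop_gain"),
    grantham_score = c(NA, 180, 190, NA, NA, NA),
    severity = c("n/a", "radical", "radical", "n/a", "n/a", "n/a"),
    boundary = FALSE,
    genotype = c("hom_alt", "het", "het", "hom_alt", "het", "het"),
    stringsAsFactors = FALSE)
  agg <- aggregate_gene_hits(eff)
  ## g1: unique homozygous stop-gain -> list A
  expect_equal(agg$unique_hom_genes$gene_id, "g1")
  ## g2 (two het radical SNVs) and g4 (het frameshift + het stop-gain):
  ## heteroallelic candidates
  expect_equal(agg$heteroallelic_genes$gene_id, c("g2", "g4"))
  ## g3 synonymous never counts
  expect_false("g3" %in% c(agg$unique_hom_genes$gene_id,
                           agg$heteroallelic_genes$gene_id))
  ## restricting uniqueness empties list A
  agg2 <- aggregate_gene_hits(eff, unique_keys = character(0))
  expect_equal(nrow(agg2$unique_hom_genes), 0)
})

test_that("SNV effect classification matches the edit-and-translate oracle", {
  g <- tiny_genome()
  genes <- g$genes
  set.seed(31)
  n_checked <- 0
  for (gid in unique(genes$gene_id)) {
    gene <- genes[genes$gene_id == gid, ]
    cds_ref <- splice_cds(gene, g$sequences)
    prot_ref <- translate_cds(cds_ref)
    ## fuzz SNVs at random CDS positions
    cds_positions <- unlist(lapply(seq_len(nrow(gene)), function(i)
      (gene$start[i] + 1):gene$end[i]))
    for (p in sample(cds_positions, 25)) {
      base <- substr(g$sequences[[gene$chrom[1]]], p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      pr <- project_variant(gene, p, base, alt, g$sequences)
      got <- classify_snv_effect(pr$ref_codon, pr$alt_codon)
      ## oracle: edit the chromosome, re-splice, re-translate, diff
      seqs2 <- g$sequences
      s <- seqs2[[gene$chrom[1]]]
      substr(s, p, p) <- alt
      seqs2[[gene$chrom[1]]] <- s
      prot_alt <- translate_cds(splice_cds(gene, seqs2))
      want <- if (prot_alt == prot_ref) "synonymous"
      else {
        d <- which(strsplit(prot_alt, "")[[1]] != strsplit(prot_ref, "")[[1]])
        aa_new <- substr(prot_alt, d[1], d[1])
        aa_old <- substr(prot_ref, d[1], d[1])
        if (aa_new == "*") "stop_gain"
        else if (aa_old == "*") "stop_loss"
        else "nonsynonymous"
      }
      expect_identical(got, want,
                       label = sprintf("%s pos %d %s>%s", gid, p, base, alt))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 150)
})
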