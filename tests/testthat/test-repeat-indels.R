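test_that("deletions left-align to the canonical representation", {
  ## deleting the last A of CAAAT is the same edit as deleting the first
  ref <- "CAAAT"
  ## anchor 3, ref "AA", alt "A": deletes the last A of the run
  nv <- normalize_indel(ref, 3, "AA", "A")
  expect_equal(nv$pos, 1)
  expect_equal(nv$ref, "CA")
  expect_equal(nv$alt, "C")
  expect_equal(nv$seq, "A")
  ## already-normalized edits are fixed points
  nv2 <- normalize_indel(ref, nv$pos, nv$ref, nv$alt)
  expect_equal(nv2[c("pos", "ref", "alt")], nv[c("pos", "ref", "alt")])
  ## insertion with no repeat context stays put
  ins <- normalize_indel("GATTC", 3, "T", "TCG")
  expect_equal(ins$pos, 3)
  expect_equal(ins$seq, "CG")
  ## ref-allele mismatch is rejected
  expect_error(normalize_indel("GATTC", 2, "TT", "T"), "mismatch")
})

test_that("equivalent indel representations normalize to identical keys", {
  ## oracle: two representations are equivalent iff applying them to the
  ## reference yields the same edited sequence
  apply_edit <- function(ref, pos, r, a) {
    paste0(substr(ref, 1, pos - 1), a,
           substr(ref, pos + nchar(r), nchar(ref)))
  }
  set.seed(21)
  for (i in 1:200) {
    ref <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    L <- sample(1:4, 1)
    p <- sample(2:(40 - L - 1), 1)
    del_ref <- substr(ref, p, p + L)
    rep1 <- list(pos = p, ref = del_ref, alt = substr(ref, p, p))
    ## shift right while sequence-equivalent
    p2 <- p
    while (p2 + L + 1 <= 40 &&
           apply_edit(ref, p2 + 1, substr(ref, p2 + 1, p2 + 1 + L),
                      substr(ref, p2 + 1, p2 + 1)) ==
           apply_edit(ref, p, rep1$ref, rep1$alt)) {
      p2 <- p2 + 1
    }
    rep2 <- list(pos = p2, ref = substr(ref, p2, p2 + L),
                 alt = substr(ref, p2, p2))
    n1 <- normalize_indel(ref, rep1$pos, rep1$ref, rep1$alt)
    n2 <- normalize_indel(ref, rep2$pos, rep2$ref, rep2$alt)
    expect_identical(n1[c("pos", "seq")], n2[c("pos", "seq")])
    ## normalization preserves the edit itself
    if (n1$pos >= 1) {
      expect_identical(apply_edit(ref, n1$pos, n1$ref, n1$alt),
                       apply_edit(ref, rep1$pos, rep1$ref, rep1$alt))
    }
  }
})

test_that("repeat-unit deletion and tandem-duplication calls match the spec cases", {
  ## GACACT: deleting AC leaves one AC copy adjacent -> repeat-unit deletion
  r1 <- is_repeat_unit_deletion("GACACT", 1, "AC")
  expect_true(r1$at_repeat)
  expect_equal(r1$unit, "AC")
  ## GACGT: deleting CG has no adjacent CG copy
  expect_false(is_repeat_unit_deletion("GACGT", 1, "CG")$at_repeat)
  ## homopolymer: deleting one A of AAA
  expect_true(is_repeat_unit_deletion("CAAAT", 1, "A")$at_repeat)
  ## insertion duplicating the preceding AC
  expect_true(is_tandem_duplication_insertion("GACT", 3, "AC")$at_repeat)
  ## inserting TT after GAC is no duplication
  expect_false(is_tandem_duplication_insertion("GACT", 3, "TT")$at_repeat)
})

test_that("classifier matches the tandem-repeat scanner oracle exhaustively", {
  ## all two-letter references up to length 9, every contiguous deletion
  for (n in 2:9) {
    refs <- all_strings(n, c("A", "C"))
    for (ref in refs) {
      for (a in 1:n) {
        for (b in a:min(n, a + 4)) {
          L <- b - a + 1
          verdict <- is_repeat_unit_deletion(ref, a - 1,
                                             substr(ref, a, b))$at_repeat
          expect_identical(verdict, oracle_repeat_deletion(ref, a - 1, L),
                           label = sprintf("del %s [%d,%d]", ref, a, b))
        }
      }
    }
  }
})

test_that("insertion classifier matches the edit-and-scan oracle", {
  set.seed(8)
  for (i in 1:400) {
    n <- sample(4:12, 1)
    ref <- paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
    L <- sample(1:3, 1)
    ins <- paste(sample(c("A", "C"), L, replace = TRUE), collapse = "")
    pos <- sample(1:(n - 1), 1)
    verdict <- is_tandem_duplication_insertion(ref, pos, ins)$at_repeat
    expect_identical(verdict, oracle_tandem_insertion(ref, pos, ins),
                     label = sprintf("ins %s at %d in %s", ins, pos, ref))
  }
})

test_that("fraction curve applies the sqrt(k)/N error model exactly", {
  calls <- data.frame(kind = "deletion",
                      length = c(rep(10, 100), rep(5, 4)),
                      at_repeat = c(rep(TRUE, 16), rep(FALSE, 84),
                                    rep(FALSE, 4)))
  cu <- repeat_fraction_curve(calls, "s")
  r10 <- cu[cu$length == 10, ]
  expect_equal(r10$fraction, 0.16)
  expect_equal(r10$error, 0.04)
  expect_equal(r10$n_at_repeat, 16)
  r5 <- cu[cu$length == 5, ]
  expect_equal(r5$fraction, 0)
  expect_equal(r5$error, 0)
  ## integer conservation
  expect_equal(cu$fraction * cu$n_total, cu$n_at_repeat)
})

test_that("enrichment is the test fraction over the control mean", {
  tc <- data.frame(sample = "t", length = c(1, 10), n_total = c(100, 100),
                   n_at_repeat = c(80, 28), fraction = c(0.80, 0.28),
                   error = c(0.089, 0.053))
  c1 <- data.frame(sample = "c1", length = c(1, 10), n_total = c(100, 100),
                   n_at_repeat = c(79, 16), fraction = c(0.79, 0.16),
                   error = c(0.089, 0.04))
  c2 <- data.frame(sample = "c2", length = c(1, 10), n_total = c(100, 100),
                   n_at_repeat = c(82, 17), fraction = c(0.82, 0.17),
                   error = c(0.09, 0.041))
  e <- enrichment_curve(tc, list(c1, c2))
  expect_equal(e$enrichment[e$length == 10], 0.28 / 0.165)
  ## identical test and controls give enrichment 1
  e1 <- enrichment_curve(tc, list(tc, tc))
  expect_equal(e1$enrichment, c(1, 1))
  ## zero control fraction is flagged undefined
  c0 <- c1
  c0$fraction <- c(0, 0)
  c20 <- c2
  c20$fraction <- c(0, 0)
  e0 <- enrichment_curve(tc, list(c0, c20))
  expect_true(all(is.na(e0$enrichment)))
  expect_false(any(e0$defined))
  ## missing control length omitted with warning
  expect_warning(enrichment_curve(tc, list(c1[c1$length == 10, ])), "omitted")
})

test_that("signed length histogram counts insertions and deletions apart", {
  rec <- classify_variant(data.frame(
    chrom = "c", pos = 1,
    ref = c("A", "A", "A", "ACT", "AGT"),
    alt = c("AT", "AC", "AG", "A", "A"),
    qual = 1, depth = 1, genotype = "het"))
  h <- indel_length_histogram(rec)
  expect_equal(h$count[h$length == 1], 3)
  expect_equal(h$count[h$length == -2], 2)
  empty <- indel_length_histogram(rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("planted repeat-indel fraction is recovered from the truth set", {
  g <- tiny_genome()
  tv <- tiny_truth()
  rec <- classify_variant(truth_as_records(tv))
  calls <- annotate_repeat_indels(rec, g$sequences)
  frac <- mean(calls$at_repeat)
  ## planted fraction 0.3; repeat indels are planted per catalog locus so
  ## allow binomial slack around the planted rate
  n <- nrow(calls)
  expect_gt(n, 100)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n) + 0.02)
  ## classification agrees with the planted truth flags
  key <- paste(tv$chrom, tv$pos)
  m <- match(paste(calls$chrom, calls$pos), key)
  expect_identical(calls$at_repeat, tv$at_repeat[m])
})
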