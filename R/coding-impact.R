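## Project variants onto CDS gene models and classify coding effects:
## synonymous / nonsynonymous (with Grantham severity) / stop-gain /
## stop-loss / frameshift / in-frame indel; aggregate candidate inactivated
## genes.

.pkg_cache <- new.env(parent = emptyenv())

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' The Grantham amino-acid distance matrix
#'
#' The published 20x20 physicochemical distance matrix (composition, polarity
#' and molecular volume), loaded from the plain-text copy shipped with the
#' package. Symmetric, zero diagonal.
#'
#' @return numeric matrix with one-letter amino-acid dimnames.
#' @export
grantham_matrix <- function() {
  if (is.null(.pkg_cache$grantham)) {
    path <- system.file("extdata", "grantham.tsv", package = "genomescan")
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "integer"
    .pkg_cache$grantham <- m
  }
  .pkg_cache$grantham
}

#' Grantham score and severity band of an amino-acid substitution
#'
#' Severity uses the conventional banding: score <= 50 conservative, 51-100
#' moderately conservative, 101-150 moderately radical, > 150 radical (the
#' chemically most dissimilar category). Identity scores 0.
#'
#' @param aa_from,aa_to amino acids, one-letter or three-letter code.
#' @return list(score, severity).
#' @export
grantham_severity <- function(aa_from, aa_to) {
  to1 <- function(a) {
    if (nchar(a) == 3) a <- .aa3to1[[paste0(toupper(substr(a, 1, 1)),
                                            tolower(substr(a, 2, 3)))]]
    a
  }
  a <- to1(aa_from)
  b <- to1(aa_to)
  m <- grantham_matrix()
  if (is.null(a) || is.null(b) || !a %in% rownames(m) || !b %in% rownames(m)) {
    stop("nonstandard amino acid: ", aa_from, "/", aa_to, call. = FALSE)
  }
  score <- m[a, b]
  severity <- if (score <= 50) "conservative"
  else if (score <= 100) "moderately_conservative"
  else if (score <= 150) "moderately_radical"
  else "radical"
  list(score = score, severity = severity)
}

.translate_codon <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (is.na(aa)) stop("invalid codon: ", codon, call. = FALSE)
  aa
}

## spliced CDS sequence of one gene (exon table rows, genomic order)
.gene_cds <- function(gene, reference) {
  seq <- reference[[gene$chrom[1]]]
  chunks <- substring(seq, gene$start + 1L, gene$end)
  cds <- paste(chunks, collapse = "")
  if (gene$strand[1] == "-") cds <- revcomp(cds)
  cds
}

## 1-based CDS coordinate of genomic position pos1, or NA if not in CDS
.cds_pos <- function(gene, pos1) {
  p0 <- pos1 - 1L
  inside <- gene$start <= p0 & p0 < gene$end
  if (!any(inside)) return(NA_integer_)
  i <- which(inside)
  plus_index <- sum(pmax(0L, pmin(gene$end, p0) - gene$start)[seq_len(i - 1)]) +
    (p0 - gene$start[i]) + 1L
  total <- sum(gene$end - gene$start)
  if (gene$strand[1] == "+") plus_index else total - plus_index + 1L
}

#' Project an SNV onto a gene's CDS
#'
#' Returns the affected codon in transcription orientation; reverse-strand
#' variants have their alleles complemented in codon space.
#'
#' @param gene exon table rows of one gene (gene_id, chrom, strand, start,
#'   end; 0-based half-open, genomic order).
#' @param pos,ref,alt the SNV (1-based genomic, single bases).
#' @param reference named character vector of chromosome sequences.
#' @return list(cds_pos, codon_index, codon_offset, ref_codon, alt_codon), or
#'   NULL when the position is outside the CDS.
#' @export
project_variant <- function(gene, pos, ref, alt, reference) {
  stopifnot(nchar(ref) == 1, nchar(alt) == 1)
  if (substr(reference[[gene$chrom[1]]], pos, pos) != ref) {
    stop("ref allele does not match the reference sequence", call. = FALSE)
  }
  cp <- .cds_pos(gene, pos)
  if (is.na(cp)) return(NULL)
  cds <- .gene_cds(gene, reference)
  minus <- gene$strand[1] == "-"
  ref_tx <- if (minus) comp_base(ref) else ref
  alt_tx <- if (minus) comp_base(alt) else alt
  stopifnot(substr(cds, cp, cp) == ref_tx)
  ci <- (cp - 1L) %/% 3L + 1L
  off <- (cp - 1L) %% 3L
  ref_codon <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
  alt_codon <- ref_codon
  substr(alt_codon, off + 1L, off + 1L) <- alt_tx
  list(cds_pos = cp, codon_index = ci, codon_offset = off,
       ref_codon = ref_codon, alt_codon = alt_codon)
}

#' Classify the effect of a codon change
#' @param ref_codon,alt_codon valid DNA triplets.
#' @return one of "synonymous", "nonsynonymous", "stop_gain", "stop_loss".
#' @export
classify_snv_effect <- function(ref_codon, alt_codon) {
  aa_ref <- .translate_codon(ref_codon)
  aa_alt <- .translate_codon(alt_codon)
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_alt == "*") return("stop_gain")
  if (aa_ref == "*") return("stop_loss")
  "nonsynonymous"
}

#' Classify the coding effect of an indel
#'
#' Length not divisible by three: frameshift. Divisible by three and fully
#' inside one CDS exon: in-frame indel. An indel that crosses a CDS boundary
#' is called frameshift with `boundary = TRUE`, since the true effect would
#' need transcript evidence. Indels not touching the CDS return "noncoding".
#'
#' @param gene exon table rows of one gene.
#' @param pos,ref,alt the indel in VCF representation (1-based anchor).
#' @return list(category, boundary).
#' @export
classify_indel_effect <- function(gene, pos, ref, alt) {
  rl <- nchar(ref)
  al <- nchar(alt)
  if (rl > 1 && al == 1) {          # deletion of [pos, pos+L) 0-based
    L <- rl - 1L
    d0 <- pos
    d1 <- pos + L
    ov <- pmax(0L, pmin(gene$end, d1) - pmax(gene$start, d0))
    if (sum(ov) == 0L) return(list(category = "noncoding", boundary = FALSE))
    within_one <- any(gene$start <= d0 & d1 <= gene$end)
    if (!within_one) return(list(category = "frameshift_indel", boundary = TRUE))
  } else if (al > 1 && rl == 1) {   # insertion at junction j = pos (0-based)
    L <- al - 1L
    j <- pos
    if (!any(gene$start < j & j < gene$end)) {
      return(list(category = "noncoding", boundary = FALSE))
    }
  } else {
    stop("not a simple indel", call. = FALSE)
  }
  if (L %% 3L == 0L) list(category = "inframe_indel", boundary = FALSE)
  else list(category = "frameshift_indel", boundary = FALSE)
}

#' Coding effects of a variant set over a gene-model table
#'
#' Runs every SNV and in-range indel against every overlapping gene's CDS.
#' Only variants touching a CDS are returned.
#'
#' @param records classified variant records (see [classify_variant()]).
#' @param genes gene-model exon table ([read_gene_models_gff()] format).
#' @param reference named character vector of chromosome sequences.
#' @return data.frame(gene_id, chrom, pos, ref, alt, kind, category,
#'   grantham_score, severity, boundary, genotype).
#' @export
variant_effects <- function(records, genes, reference) {
  rows <- list()
  for (gid in unique(genes$gene_id)) {
    gene <- genes[genes$gene_id == gid, ]
    gene <- gene[order(gene$start), ]
    span0 <- min(gene$start) - 60L
    span1 <- max(gene$end) + 60L
    rc <- records[records$chrom == gene$chrom[1] & records$pos > span0 &
                    records$pos <= span1, , drop = FALSE]
    if (!nrow(rc)) next
    for (i in seq_len(nrow(rc))) {
      kind <- rc$kind[i]
      if (kind == "snv") {
        pr <- project_variant(gene, rc$pos[i], rc$ref[i], rc$alt[i], reference)
        if (is.null(pr)) next
        cat_ <- classify_snv_effect(pr$ref_codon, pr$alt_codon)
        score <- NA_integer_
        sev <- "n/a"
        if (cat_ == "nonsynonymous") {
          gs <- grantham_severity(.translate_codon(pr$ref_codon),
                                  .translate_codon(pr$alt_codon))
          score <- gs$score
          sev <- gs$severity
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, chrom = rc$chrom[i], pos = rc$pos[i],
          ref = rc$ref[i], alt = rc$alt[i], kind = kind, category = cat_,
          grantham_score = score, severity = sev, boundary = FALSE,
          genotype = rc$genotype[i], stringsAsFactors = FALSE)
      } else if (kind %in% c("insertion", "deletion") && rc$in_range[i]) {
        eff <- classify_indel_effect(gene, rc$pos[i], rc$ref[i], rc$alt[i])
        if (eff$category == "noncoding") next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, chrom = rc$chrom[i], pos = rc$pos[i],
          ref = rc$ref[i], alt = rc$alt[i], kind = kind,
          category = eff$category, grantham_score = NA_integer_,
          severity = "n/a", boundary = eff$boundary,
          genotype = rc$genotype[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), kind = character(0),
                      category = character(0), grantham_score = integer(0),
                      severity = character(0), boundary = logical(0),
                      genotype = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Aggregate candidate inactivated genes from coding effects
#'
#' Damaging categories default to radical nonsynonymous SNVs, frameshift and
#' in-frame indels, and stop-gains. List A: genes with at least one
#' sample-unique homozygous damaging hit. List B: genes with at least two
#' distinct damaging hits (heteroallelic combinations may inactivate both
#' alleles without any single homozygous hit).
#'
#' @param effects data.frame from [variant_effects()].
#' @param unique_keys optional character vector of "chrom:pos:ref:alt" keys
#'   that are unique to this sample (from [partition_unique_shared()]); when
#'   NULL, every hit counts as unique.
#' @param damaging damaging category set; "radical_nonsynonymous" means
#'   category nonsynonymous with severity radical.
#' @return list(unique_hom_genes, heteroallelic_genes): data.frames
#'   (gene_id, n_hits) sorted by gene, plus `hits` with per-variant detail.
#' @export
aggregate_gene_hits <- function(effects, unique_keys = NULL,
                                damaging = c("radical_nonsynonymous",
                                             "frameshift_indel",
                                             "inframe_indel", "stop_gain")) {
  is_dmg <- (effects$category %in% damaging) |
    ("radical_nonsynonymous" %in% damaging &
       effects$category == "nonsynonymous" & effects$severity == "radical")
  key <- paste(effects$chrom, effects$pos, effects$ref, effects$alt, sep = ":")
  is_unique <- if (is.null(unique_keys)) rep(TRUE, nrow(effects)) else
    key %in% unique_keys
  hits <- effects[is_dmg, , drop = FALSE]
  hits$unique <- is_unique[is_dmg]
  a <- hits[hits$unique & hits$genotype == "hom_alt", , drop = FALSE]
  list_a <- if (nrow(a)) {
    tab <- table(a$gene_id)
    data.frame(gene_id = sort(names(tab)),
               n_hits = as.integer(tab[sort(names(tab))]),
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(0), n_hits = integer(0))
  kcount <- tapply(paste(hits$chrom, hits$pos, hits$ref, hits$alt),
                   hits$gene_id, function(k) length(unique(k)))
  bgenes <- sort(names(kcount)[kcount >= 2])
  list_b <- data.frame(gene_id = bgenes,
                       n_hits = as.integer(kcount[bgenes]),
                       stringsAsFactors = FALSE)
  rownames(list_a) <- rownames(list_b) <- NULL
  list(unique_hom_genes = list_a, heteroallelic_genes = list_b, hits = hits)
}
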