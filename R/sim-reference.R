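## Synthetic reference genome: random chromosomes with planted tandem-repeat
## loci and multi-exon CDS gene models on both strands.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.all_codons <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

## TRUE if unit is a repetition of a shorter string (e.g. "ACAC")
.has_period <- function(unit) {
  n <- nchar(unit)
  if (n == 1) return(FALSE)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0) {
      if (unit == paste(rep(substr(unit, 1, d), n / d), collapse = ""))
        return(TRUE)
    }
  }
  FALSE
}

.overlaps_any <- function(start, end, ivs) {
  ## all 0-based half-open
  if (!nrow(ivs)) return(FALSE)
  any(start < ivs$end & end > ivs$start)
}

## One synthetic gene: multi-exon CDS with valid start and stop codon.
## Returns list(exons = data.frame(start, end (0-based half-open), chunk),
##              genomic span, genomic sequences to write per exon)
.make_gene <- function(anchor, strand, len_chrom) {
  n_exons <- sample(2:4, 1)
  n_codons <- sample(60:140, 1)
  coding <- c("ATG",
              sample(setdiff(.all_codons(), STOP_CODONS), n_codons - 2,
                     replace = TRUE),
              sample(STOP_CODONS, 1))
  cds <- paste(coding, collapse = "")
  L <- nchar(cds)
  ## split CDS into n_exons chunks, each >= 20 bp, cuts not codon-aligned
  repeat {
    cuts <- sort(sample(seq_len(L - 1), n_exons - 1))
    sizes <- diff(c(0, cuts, L))
    if (all(sizes >= 20)) break
  }
  introns <- sample(100:400, n_exons - 1, replace = TRUE)
  ## genomic-order chunk sequence: for minus-strand genes the genomic DNA of
  ## the gene region is the reverse complement of the spliced CDS
  genomic_cds <- if (strand == "+") cds else revcomp(cds)
  gsizes <- if (strand == "+") sizes else rev(sizes)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- anchor
  seqs <- character(n_exons)
  off <- 0L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + gsizes[i]
    seqs[i] <- substr(genomic_cds, off + 1L, off + gsizes[i])
    off <- off + gsizes[i]
    pos <- ends[i] + if (i < n_exons) introns[i] else 0L
  }
  if (pos > len_chrom) return(NULL)
  list(exons = data.frame(start = starts, end = ends, stringsAsFactors = FALSE),
       exon_seqs = seqs, span_end = pos, cds_len = L)
}

#' Generate a synthetic reference genome
#'
#' Builds random chromosomes over A/C/G/T, plants a catalog of tandem-repeat
#' loci (primitive units of 1-15 bp, 2-6 copies, roughly one per 1.5 kb)
#' and at least two multi-exon protein-coding genes per chromosome, one on
#' each strand, each with a valid start and stop codon and a CDS length
#' divisible by three. Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_genome`: list with `sequences` (named
#'   character vector), `repeats` (chrom, start, end, unit, copies; 0-based
#'   half-open), `genes` (gene_id, chrom, strand, exon, start, end; exons in
#'   genomic order, 0-based half-open) and the `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seqs <- character(0)
  repeat_rows <- list()
  gene_rows <- list()
  for (chrom in names(config$chromosome_lengths)) {
    len <- config$chromosome_lengths[[chrom]]
    chars <- sample(BASES, len, replace = TRUE)
    seq <- paste(chars, collapse = "")
    blocked <- data.frame(start = integer(0), end = integer(0))

    ## genes: one per strand, anchored near 1/3 and 2/3 of the chromosome
    strands <- c("+", "-")
    for (g in seq_along(strands)) {
      anchor <- as.integer(round(len * g / (length(strands) + 1))) +
        sample(-200:200, 1)
      gene <- .make_gene(anchor, strands[g], len)
      if (is.null(gene)) next
      gid <- sprintf("%s_g%d", chrom, g)
      for (i in seq_len(nrow(gene$exons))) {
        substr(seq, gene$exons$start[i] + 1L, gene$exons$end[i]) <-
          gene$exon_seqs[i]
      }
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strands[g],
        exon = seq_len(nrow(gene$exons)),
        start = gene$exons$start, end = gene$exons$end,
        stringsAsFactors = FALSE)
      blocked <- rbind(blocked,
                       data.frame(start = anchor - 1L, end = gene$span_end + 1L))
    }

    ## tandem-repeat loci: one per ~1.5 kb window that is clear of genes
    win <- 1500L
    for (w in seq(0L, len - win, by = win)) {
      u_len <- sample(1:15, 1, prob = 0.6^(1:15))
      copies <- sample(2:6, 1)
      run_len <- u_len * copies
      start <- w + sample(seq_len(win - run_len - 2L), 1)
      if (start < 1L) next
      if (.overlaps_any(start, start + run_len, blocked)) next
      unit <- paste(sample(BASES, u_len, replace = TRUE), collapse = "")
      tries <- 0L
      while (.has_period(unit) && tries < 20L) {
        unit <- paste(sample(BASES, u_len, replace = TRUE), collapse = "")
        tries <- tries + 1L
      }
      if (.has_period(unit)) next
      run <- paste(rep(unit, copies), collapse = "")
      substr(seq, start + 1L, start + run_len) <- run
      repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = start + run_len,
        unit = unit, copies = copies, stringsAsFactors = FALSE)
      blocked <- rbind(blocked,
                       data.frame(start = start - 1L, end = start + run_len + 1L))
    }
    seqs[[chrom]] <- seq
  }
  structure(list(
    sequences = seqs,
    repeats = do.call(rbind, repeat_rows),
    genes = do.call(rbind, gene_rows),
    config = config), class = "synthetic_genome")
}

#' @method print synthetic_genome
#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$sequences), "chromosomes,",
      sum(nchar(x$sequences)), "bp;",
      nrow(x$repeats), "tandem-repeat loci;",
      length(unique(x$genes$gene_id)), "genes\n")
  invisible(x)
}

#' Write genome FASTA
#' @param genome a `synthetic_genome` (or any named character vector of
#'   sequences in `genome$sequences`).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (is.list(genome)) genome$sequences else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/CDS rows (1-based inclusive coordinates) with CDS phase
#' computed in transcription order.
#'
#' @param genome a `synthetic_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff <- function(genome, path) {
  g <- genome$genes
  lines <- "##gff-version 3"
  for (gid in unique(g$gene_id)) {
    e <- g[g$gene_id == gid, ]
    strand <- e$strand[1]
    gstart <- min(e$start) + 1L
    gend <- max(e$end)
    lines <- c(lines,
      sprintf("%s\tgenomescan\tgene\t%d\t%d\t.\t%s\t.\tID=%s", e$chrom[1],
              gstart, gend, strand, gid),
      sprintf("%s\tgenomescan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              e$chrom[1], gstart, gend, strand, gid, gid))
    ## transcription order for phase
    tx <- if (strand == "+") order(e$start) else order(-e$start)
    before <- 0L
    phase <- integer(nrow(e))
    for (i in tx) {
      phase[i] <- (3L - before %% 3L) %% 3L
      before <- before + (e$end[i] - e$start[i])
    }
    lines <- c(lines, sprintf(
      "%s\tgenomescan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s.t1",
      e$chrom, e$start + 1L, e$end, strand, phase, gid, e$exon, gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read CDS gene models from a GFF3 file
#'
#' Parses CDS features (via rtracklayer) into the flat exon table used by the
#' coding-impact stage. Coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 path.
#' @return data.frame(gene_id, chrom, strand, exon, start, end).
#' @export
read_gene_models_gff <- function(path) {
  gr <- rtracklayer::import(path)
  cds <- gr[gr$type == "CDS"]
  parent <- vapply(cds$Parent, function(p) p[1], character(1))
  gene_id <- sub("\\.t[0-9]+$", "", parent)
  df <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds),
    stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$start), ]
  df$exon <- stats::ave(df$start, df$gene_id, FUN = seq_along)
  rownames(df) <- NULL
  df[, c("gene_id", "chrom", "strand", "exon", "start", "end")]
}

#' Write the tandem-repeat truth catalog as TSV
#' @param genome a `synthetic_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_catalog <- function(genome, path) {
  write_tsv_meta(genome$repeats, path, meta = list(coords = "0-based half-open"))
}
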