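## Plant retroviral insertions: mixed host/viral assembly scaffolds plus
## chimeric read pairs around each junction, with decoys and planted truth.

#' Generate a synthetic retroviral genome
#'
#' An LTR-internal-LTR layout (two identical long terminal repeats flanking
#' the internal genes), the structure of an alpharetrovirus provirus.
#'
#' @param seed RNG seed.
#' @param ltr_length LTR length in bp.
#' @param internal_length internal segment length in bp.
#' @return list(name, seq, ltr_length).
#' @export
sim_viral_genome <- function(seed = 99L, ltr_length = 300L,
                             internal_length = 2000L) {
  set.seed(seed)
  ltr <- paste(sample(BASES, ltr_length, replace = TRUE), collapse = "")
  internal <- paste(sample(BASES, internal_length, replace = TRUE),
                    collapse = "")
  list(name = "virus_synthetic", seq = paste0(ltr, internal, ltr),
       ltr_length = ltr_length)
}

#' Plant viral insertions: scaffolds, read pairs and truth
#'
#' For each site, emits one mixed scaffold (a host flank ending exactly at
#' the junction followed by part of the viral LTR, reverse-complemented for
#' reverse-orientation sites), viral-only and host-only decoy scaffolds, and
#' read pairs in which one mate is fully viral and the other maps to the
#' host within one fragment length of the junction. Host-host pairs spanning
#' the junction are emitted only for sites not flagged `all_alleles`
#' (an insertion carried by every allele leaves no reads spanning the
#' host-only junction sequence).
#'
#' @param genome a `synthetic_genome`.
#' @param viral a [sim_viral_genome()] result.
#' @param sites data.frame(chrom, pos, orientation, all_alleles); defaults to
#'   the config's viral sites.
#' @param read_length,fragment read and fragment lengths in bp.
#' @param flank host bases retained on each mixed scaffold.
#' @param n_junction_pairs chimeric pairs per site.
#' @param n_spanning_pairs junction-spanning host pairs per non-all-allele
#'   site.
#' @param n_background_pairs host-host decoy pairs.
#' @param seed RNG seed.
#' @return list(scaffolds (named character), scaffold_truth, pairs
#'   (data.frame pair_id, read1, read2, category, site_id), sites (truth)).
#' @export
plant_viral_insertions <- function(genome, viral,
                                   sites = genome$config$viral_sites,
                                   read_length = 100L, fragment = 350L,
                                   flank = 500L, n_junction_pairs = 10L,
                                   n_spanning_pairs = 5L,
                                   n_background_pairs = 20L,
                                   seed = genome$config$seed + 3L) {
  stopifnot(nchar(viral$seq) >= 2 * read_length)
  set.seed(seed)
  vlen <- nchar(viral$seq)
  margin <- flank + fragment
  scaffolds <- character(0)
  truth_rows <- list()
  pair_rows <- list()
  pair_n <- 0L
  add_pair <- function(r1, r2, category, site_id) {
    pair_n <<- pair_n + 1L
    pair_rows[[pair_n]] <<- data.frame(
      pair_id = sprintf("pr%04d", pair_n), read1 = r1, read2 = r2,
      category = category, site_id = site_id, stringsAsFactors = FALSE)
  }

  sites <- as.data.frame(sites)
  if (nrow(sites) && is.null(sites$all_alleles)) sites$all_alleles <- FALSE
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    pos <- sites$pos[i]
    len <- nchar(genome$sequences[[chrom]])
    if (pos <= margin || pos + margin > len) {
      stop(sprintf("viral site %s:%d too close to chromosome end", chrom, pos),
           call. = FALSE)
    }
    seq <- genome$sequences[[chrom]]
    host_part <- substr(seq, pos - flank + 1L, pos)
    vpart_len <- min(viral$ltr_length - 50L, 250L)
    vseg <- if (sites$orientation[i] == "+") {
      substr(viral$seq, 1L, vpart_len)
    } else {
      revcomp(substr(viral$seq, vlen - vpart_len + 1L, vlen))
    }
    sid <- sprintf("scf%03d", length(scaffolds) + 1L)
    scaffolds[[sid]] <- paste0(host_part, vseg)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      site_id = sprintf("site%d", i), chrom = chrom, pos = pos,
      orientation = sites$orientation[i],
      all_alleles = sites$all_alleles[i], scaffold = sid,
      stringsAsFactors = FALSE)

    ## chimeric junction pairs: viral side sequence adjacent to the junction
    vside <- if (sites$orientation[i] == "+") {
      substr(viral$seq, 1L, fragment)
    } else {
      revcomp(substr(viral$seq, vlen - fragment + 1L, vlen))
    }
    for (p in seq_len(n_junction_pairs)) {
      r <- sample.int(nchar(vside) - read_length, 1)
      viral_mate <- substr(vside, r, r + read_length - 1L)
      d <- sample.int(fragment - 2L * read_length, 1)
      host_mate <- substr(seq, pos - d - read_length + 1L, pos - d)
      add_pair(host_mate, viral_mate, "junction", sprintf("site%d", i))
    }
    if (!sites$all_alleles[i]) {
      for (p in seq_len(n_spanning_pairs)) {
        o <- sample(10:(read_length - 10L), 1)
        span_read <- substr(seq, pos - o + 1L, pos - o + read_length)
        up <- substr(seq, pos - o - fragment + 1L,
                     pos - o - fragment + read_length)
        add_pair(up, span_read, "spanning", sprintf("site%d", i))
      }
    }
  }

  ## decoy scaffolds: viral-only and host-only
  for (j in 1:2) {
    L <- sample(400:800, 1)
    s <- sample.int(vlen - L, 1)
    sid <- sprintf("scf%03d", length(scaffolds) + 1L)
    scaffolds[[sid]] <- substr(viral$seq, s, s + L - 1L)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      site_id = NA_character_, chrom = NA_character_, pos = NA_integer_,
      orientation = NA_character_, all_alleles = NA, scaffold = sid,
      stringsAsFactors = FALSE)
  }
  for (j in 1:3) {
    chrom <- sample(names(genome$sequences), 1)
    len <- nchar(genome$sequences[[chrom]])
    L <- sample(1000:2000, 1)
    s <- sample.int(len - L, 1)
    sid <- sprintf("scf%03d", length(scaffolds) + 1L)
    scaffolds[[sid]] <- substr(genome$sequences[[chrom]], s, s + L - 1L)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      site_id = NA_character_, chrom = NA_character_, pos = NA_integer_,
      orientation = NA_character_, all_alleles = NA, scaffold = sid,
      stringsAsFactors = FALSE)
  }

  ## background host-host pairs
  for (j in seq_len(n_background_pairs)) {
    chrom <- sample(names(genome$sequences), 1)
    len <- nchar(genome$sequences[[chrom]])
    s <- sample.int(len - fragment - read_length, 1)
    add_pair(substr(genome$sequences[[chrom]], s, s + read_length - 1L),
             substr(genome$sequences[[chrom]], s + fragment,
                    s + fragment + read_length - 1L),
             "background", NA_character_)
  }

  truth <- do.call(rbind, truth_rows)
  list(scaffolds = scaffolds,
       scaffold_truth = truth,
       sites = truth[!is.na(truth$site_id), , drop = FALSE],
       pairs = do.call(rbind, pair_rows))
}

#' Write scaffolds / read pairs as FASTA
#'
#' Read pairs are interleaved, named `<pair_id>/1` and `<pair_id>/2`.
#'
#' @param scaffolds named character vector of sequences.
#' @param pairs data.frame(pair_id, read1, read2).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scaffolds_fasta <- function(scaffolds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(scaffolds), path)
  invisible(path)
}

#' @rdname write_scaffolds_fasta
#' @export
write_read_pairs_fasta <- function(pairs, path) {
  seqs <- setNames(
    as.vector(rbind(pairs$read1, pairs$read2)),
    as.vector(rbind(paste0(pairs$pair_id, "/1"), paste0(pairs$pair_id, "/2"))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read interleaved read-pair FASTA back into a pair table
#' @param path FASTA path.
#' @return data.frame(pair_id, read1, read2).
#' @export
read_read_pairs_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("/[12]$", "", names(x))
  mate <- sub("^.*/", "", names(x))
  ids <- unique(nm)
  data.frame(pair_id = ids,
             read1 = as.character(x)[match(paste0(ids, "/1"),
                                           paste0(nm, "/", mate))],
             read2 = as.character(x)[match(paste0(ids, "/2"),
                                           paste0(nm, "/", mate))],
             stringsAsFactors = FALSE)
}
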