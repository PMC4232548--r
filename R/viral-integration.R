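## Detect viral integration sites from mixed host/viral assembly scaffolds
## and from chimeric read pairs; call junction zygosity.
##
## Alignment hits are consumed in 12-column tabular (BLAST outfmt-6-like)
## form; for synthetic data an exact k-mer seed-and-extend matcher produces
## equivalent hits so no external aligner is needed.

## maximal exact extension of an anchor match on one diagonal
.extend_match <- function(q, s, qpos, spos) {
  qlen <- nchar(q)
  slen <- nchar(s)
  a <- qpos
  b <- spos
  while (a > 1L && b > 1L &&
         substr(q, a - 1L, a - 1L) == substr(s, b - 1L, b - 1L)) {
    a <- a - 1L
    b <- b - 1L
  }
  len <- 0L
  while (qpos + len <= qlen && spos + len <= slen &&
         substr(q, qpos + len, qpos + len) ==
           substr(s, spos + len, spos + len)) {
    len <- len + 1L
  }
  c(qstart = a, qend = qpos + len - 1L, sstart = b, send = spos + len - 1L)
}

.hits_one_strand <- function(q, qname, s, sname, k) {
  qlen <- nchar(q)
  if (qlen < k) return(NULL)
  anchors <- seq(1L, qlen - k + 1L, by = k)
  seen <- character(0)
  rows <- list()
  for (a in anchors) {
    kmer <- substr(q, a, a + k - 1L)
    m <- gregexpr(kmer, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (spos in as.integer(m)) {
      key <- sprintf("%d", spos - a)       # diagonal
      ext <- .extend_match(q, s, a, spos)
      key <- sprintf("%s:%d", key, ext[["qstart"]])
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = qname, sseqid = sname, pident = 100,
        length = ext[["qend"]] - ext[["qstart"]] + 1L, mismatch = 0L,
        gapopen = 0L, qstart = ext[["qstart"]], qend = ext[["qend"]],
        sstart = ext[["sstart"]], send = ext[["send"]], evalue = 0,
        bitscore = 2 * (ext[["qend"]] - ext[["qstart"]] + 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Exact-match alignment hits in BLAST tabular form
#'
#' Seed-and-extend exact matcher: non-overlapping k-mer anchors of each query
#' are located in each subject and extended to maximal exact matches, on both
#' strands. Minus-strand hits follow the BLAST convention
#' (`sstart > send`). Suitable for synthetic data where hits are exact.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param k anchor length (default 25).
#' @param min_len drop hits shorter than this (default 50).
#' @return data.frame in BLAST outfmt-6 column order.
#' @export
kmer_hits <- function(queries, subjects, k = 25, min_len = 50) {
  out <- list()
  for (qn in names(queries)) {
    q <- queries[[qn]]
    qlen <- nchar(q)
    rcq <- revcomp(q)
    for (sn in names(subjects)) {
      h <- .hits_one_strand(q, qn, subjects[[sn]], sn, k)
      if (!is.null(h)) out[[length(out) + 1L]] <- h
      hr <- .hits_one_strand(rcq, qn, subjects[[sn]], sn, k)
      if (!is.null(hr)) {
        ## map back to forward-query coordinates; flip subject coords
        qs <- qlen - hr$qend + 1L
        qe <- qlen - hr$qstart + 1L
        tmp <- hr$sstart
        hr$sstart <- hr$send
        hr$send <- tmp
        hr$qstart <- qs
        hr$qend <- qe
        out[[length(out) + 1L]] <- hr
      }
    }
  }
  if (!length(out)) {
    return(data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[res$length >= min_len, , drop = FALSE]
  ## drop hits contained in a longer hit of the same query/subject pair
  res <- res[order(res$qseqid, res$sseqid, -res$length), ]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    j <- which(keep & res$qseqid == res$qseqid[i] &
                 res$sseqid == res$sseqid[i] &
                 res$qstart >= res$qstart[i] & res$qend <= res$qend[i])
    keep[setdiff(j, i)] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read/write BLAST outfmt-6 tabular hits
#' @param hits data.frame in outfmt-6 column order.
#' @param path file path.
#' @return `path` (write) or hits data.frame (read).
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")
  df
}

#' Classify one scaffold from its viral and host hits
#'
#' Hits below the length/identity thresholds are discarded; the category
#' follows from which evidence survives. A scaffold whose only viral
#' evidence was a discarded short match on a long scaffold keeps an
#' `excluded_short` annotation (such matches are typically spurious).
#'
#' @param viral_hits,host_hits outfmt-6 rows for this scaffold.
#' @param scaffold_length scaffold length in bp.
#' @param min_hit_len minimum surviving hit length (default 200).
#' @param min_identity minimum percent identity (default 90).
#' @return list(category in viral_only/host_only/mixed, excluded_short,
#'   zero_evidence).
#' @export
classify_scaffold <- function(viral_hits, host_hits, scaffold_length,
                              min_hit_len = 200, min_identity = 90) {
  ok <- function(h) {
    if (is.null(h) || !nrow(h)) {
      return(data.frame(length = numeric(0), pident = numeric(0)))
    }
    h[h$length >= min_hit_len & h$pident >= min_identity, , drop = FALSE]
  }
  v <- ok(viral_hits)
  h <- ok(host_hits)
  had_viral <- !is.null(viral_hits) && nrow(viral_hits) > 0
  excluded_short <- had_viral && nrow(v) == 0 &&
    scaffold_length >= 5 * min_hit_len
  zero_evidence <- !had_viral && (is.null(host_hits) || nrow(host_hits) == 0)
  category <- if (nrow(v) && nrow(h)) "mixed"
  else if (nrow(v)) "viral_only"
  else "host_only"
  list(category = category, excluded_short = excluded_short,
       zero_evidence = zero_evidence)
}

#' Locate the integration junction on a mixed scaffold
#'
#' Finds a host hit adjacent (gap <= `max_gap` on the scaffold) to a viral
#' hit; the junction is the host coordinate at the scaffold position where
#' the host alignment meets the viral sequence, and the orientation is the
#' relative strand of the viral and host hits.
#'
#' @param host_hits,viral_hits surviving outfmt-6 rows for one scaffold.
#' @param max_gap maximum unexplained scaffold bases between the host and
#'   viral segments (default 50).
#' @return data.frame(chrom, pos, orientation, evidence, support,
#'   unresolved) with a single row, or NULL if no adjacent host/viral pair
#'   exists at all.
#' @export
locate_integration <- function(host_hits, viral_hits, max_gap = 50) {
  if (!nrow(host_hits) || !nrow(viral_hits)) return(NULL)
  best <- NULL
  best_gap <- Inf
  for (i in seq_len(nrow(host_hits))) {
    for (j in seq_len(nrow(viral_hits))) {
      h <- host_hits[i, ]
      v <- viral_hits[j, ]
      hplus <- h$sstart <= h$send
      if ((h$qstart + h$qend) < (v$qstart + v$qend)) {
        ## host segment first; the host hit may extend a few bases into the
        ## viral segment (junction micro-homology) - trim it back
        ov <- max(0L, h$qend - (v$qstart - 1L))
        gap <- (v$qstart - 1L) - h$qend
        jpos <- if (hplus) h$send - ov else h$send + ov
      } else {
        ov <- max(0L, v$qend - (h$qstart - 1L))
        gap <- h$qstart - 1L - v$qend
        jpos <- if (hplus) h$sstart + ov else h$sstart - ov
      }
      if (ov > max_gap) next             # not a clean junction
      if (gap < best_gap) {
        best_gap <- gap
        vstrand <- if (v$sstart <= v$send) "+" else "-"
        best <- data.frame(
          chrom = h$sseqid, pos = jpos,
          orientation = if (hplus == (vstrand == "+")) "+" else "-",
          evidence = "mixed_scaffold", support = 1L,
          unresolved = gap > max_gap, stringsAsFactors = FALSE)
      }
    }
  }
  best
}

## exact placement of a read on the host genome (first hit; both strands)
.place_read <- function(read, reference) {
  for (chrom in names(reference)) {
    m <- regexpr(read, reference[[chrom]], fixed = TRUE)
    if (m != -1L) {
      return(data.frame(chrom = chrom, start = as.integer(m),
                        end = as.integer(m) + nchar(read) - 1L,
                        strand = "+", stringsAsFactors = FALSE))
    }
    m <- regexpr(revcomp(read), reference[[chrom]], fixed = TRUE)
    if (m != -1L) {
      return(data.frame(chrom = chrom, start = as.integer(m),
                        end = as.integer(m) + nchar(read) - 1L,
                        strand = "-", stringsAsFactors = FALSE))
    }
  }
  NULL
}

.viral_kmer_set <- function(viral_seq, k) {
  n <- nchar(viral_seq)
  rc <- revcomp(viral_seq)
  unique(c(substring(viral_seq, 1:(n - k + 1), k:n),
           substring(rc, 1:(n - k + 1), k:n)))
}

.is_viral_read <- function(read, kmer_set, k, frac = 0.8) {
  n <- nchar(read)
  if (n < k) return(FALSE)
  km <- substring(read, 1:(n - k + 1), k:n)
  mean(km %in% kmer_set) >= frac
}

#' Integration sites from chimeric read pairs
#'
#' Pairs with exactly one viral mate (k-mer membership against the viral
#' genome) contribute their host mate's exact-match placement; placements
#' are clustered within `cluster_window` and clusters with at least
#' `min_support` pairs become sites, positioned at the cluster boundary on
#' the viral-facing side (the junction side the host mates point toward).
#'
#' @param pairs data.frame(pair_id, read1, read2).
#' @param viral_seq viral genome sequence.
#' @param reference named character vector of host chromosome sequences.
#' @param k k-mer length for viral membership (default 25).
#' @param cluster_window clustering window in bp (default 1000).
#' @param min_support minimum supporting pairs per site (default 3).
#' @return data.frame(chrom, pos, orientation, evidence, support); zero rows
#'   when nothing is found.
#' @export
readpair_integration <- function(pairs, viral_seq, reference, k = 25,
                                 cluster_window = 1000, min_support = 3) {
  kset <- .viral_kmer_set(viral_seq, k)
  placements <- list()
  for (i in seq_len(nrow(pairs))) {
    v1 <- .is_viral_read(pairs$read1[i], kset, k)
    v2 <- .is_viral_read(pairs$read2[i], kset, k)
    if (v1 == v2) next                  # both or neither viral: ignore
    host_read <- if (v1) pairs$read2[i] else pairs$read1[i]
    p <- .place_read(host_read, reference)
    if (!is.null(p)) placements[[length(placements) + 1L]] <- p
  }
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      orientation = character(0), evidence = character(0),
                      support = integer(0))
  if (!length(placements)) return(empty)
  pl <- do.call(rbind, placements)
  sites <- list()
  for (chrom in unique(pl$chrom)) {
    p <- pl[pl$chrom == chrom, ]
    p <- p[order(p$start), ]
    grp <- cumsum(c(1L, as.integer(diff(p$start) > cluster_window)))
    for (g in unique(grp)) {
      pg <- p[grp == g, ]
      if (nrow(pg) < min_support) next
      plus <- sum(pg$strand == "+") >= nrow(pg) / 2
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = chrom, pos = if (plus) max(pg$end) else min(pg$start),
        orientation = NA_character_, evidence = "read_pairs",
        support = nrow(pg), stringsAsFactors = FALSE)
    }
  }
  if (!length(sites)) return(empty)
  res <- do.call(rbind, sites)
  rownames(res) <- NULL
  res
}

#' Count host reads spanning a junction
#'
#' A read spans when its exact host placement covers the junction coordinate
#' with at least `margin` bases on each side. Viral reads are excluded
#' first.
#'
#' @param pairs read-pair data.frame.
#' @param viral_seq viral genome sequence.
#' @param reference host chromosome sequences.
#' @param chrom,pos the junction.
#' @param k k-mer length for viral read detection.
#' @param margin minimum overhang on each side of the junction (default 10).
#' @return integer count of spanning reads.
#' @export
count_spanning_reads <- function(pairs, viral_seq, reference, chrom, pos,
                                 k = 25, margin = 10) {
  kset <- .viral_kmer_set(viral_seq, k)
  reads <- c(pairs$read1, pairs$read2)
  n <- 0L
  for (r in reads) {
    if (.is_viral_read(r, kset, k)) next
    p <- .place_read(r, reference)
    if (is.null(p)) next
    if (p$chrom == chrom && p$start <= pos - margin && p$end >= pos + margin) {
      n <- n + 1L
    }
  }
  n
}

#' Junction zygosity from spanning vs supporting read counts
#'
#' With solid junction support and zero reads spanning the host-only
#' junction sequence, the insertion is carried by all alleles; with solid
#' support on both sides it is partial; anything weaker is no-call.
#'
#' @param spanning_read_count reads spanning the unmodified host junction.
#' @param junction_support_count reads/pairs supporting the insertion.
#' @return "all_alleles", "partial" or "no_call".
#' @export
junction_zygosity <- function(spanning_read_count, junction_support_count) {
  stopifnot(spanning_read_count >= 0, junction_support_count >= 0)
  if (junction_support_count >= 3 && spanning_read_count == 0) "all_alleles"
  else if (junction_support_count >= 3 && spanning_read_count >= 3) "partial"
  else "no_call"
}

#' Detect integration sites end-to-end from scaffolds and read pairs
#'
#' Classifies every scaffold from its hits, locates junctions on mixed
#' scaffolds, runs the read-pair method, merges the two evidence paths
#' (sites within `merge_window` are combined, evidence "both") and calls
#' junction zygosity from the read pairs.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param viral named character vector (or [sim_viral_genome()] list) of
#'   viral sequence(s).
#' @param reference host chromosome sequences.
#' @param pairs read-pair data.frame (NULL to skip the read-pair path).
#' @param exclude_viral_ids viral sequence ids to ignore (endogenous
#'   retrovirus exclusion list).
#' @param min_hit_len,min_identity scaffold-hit thresholds.
#' @param merge_window bp window for merging the two evidence paths.
#' @param ... passed to [readpair_integration()].
#' @return list(scaffold_classes, sites) where sites has columns chrom, pos,
#'   orientation, evidence, support, zygosity.
#' @export
detect_integrations <- function(scaffolds, viral, reference, pairs = NULL,
                                exclude_viral_ids = character(0),
                                min_hit_len = 200, min_identity = 90,
                                merge_window = 500, ...) {
  if (is.list(viral) && !is.null(viral$seq)) {
    viral <- setNames(viral$seq, viral$name)
  }
  viral <- viral[setdiff(names(viral), exclude_viral_ids)]
  hits_v <- kmer_hits(scaffolds, viral)
  hits_h <- kmer_hits(scaffolds, reference)
  classes <- list()
  scaffold_sites <- list()
  for (sid in names(scaffolds)) {
    hv <- hits_v[hits_v$qseqid == sid, , drop = FALSE]
    hh <- hits_h[hits_h$qseqid == sid, , drop = FALSE]
    cl <- classify_scaffold(hv, hh, nchar(scaffolds[[sid]]),
                            min_hit_len, min_identity)
    classes[[length(classes) + 1L]] <- data.frame(
      scaffold = sid, category = cl$category,
      excluded_short = cl$excluded_short, zero_evidence = cl$zero_evidence,
      stringsAsFactors = FALSE)
    if (cl$category == "mixed") {
      keep <- function(h) h[h$length >= min_hit_len &
                              h$pident >= min_identity, , drop = FALSE]
      s <- locate_integration(keep(hh), keep(hv))
      if (!is.null(s) && !s$unresolved) {
        scaffold_sites[[length(scaffold_sites) + 1L]] <-
          s[, c("chrom", "pos", "orientation", "evidence", "support")]
      }
    }
  }
  classes <- do.call(rbind, classes)
  ssites <- if (length(scaffold_sites)) do.call(rbind, scaffold_sites) else
    NULL
  rsites <- if (!is.null(pairs)) {
    readpair_integration(pairs, paste(viral, collapse = ""), reference, ...)
  } else NULL

  sites <- ssites
  if (!is.null(rsites) && nrow(rsites)) {
    if (is.null(sites)) {
      sites <- rsites
    } else {
      matched_r <- logical(nrow(rsites))
      for (i in seq_len(nrow(sites))) {
        m <- which(!matched_r & rsites$chrom == sites$chrom[i] &
                     abs(rsites$pos - sites$pos[i]) <= merge_window)
        if (length(m)) {
          sites$evidence[i] <- "both"
          sites$support[i] <- sites$support[i] + rsites$support[m[1]]
          matched_r[m[1]] <- TRUE
        }
      }
      if (any(!matched_r)) sites <- rbind(sites, rsites[!matched_r, ])
    }
  }
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        orientation = character(0), evidence = character(0),
                        support = integer(0))
  }
  sites$zygosity <- rep("no_call", nrow(sites))
  if (!is.null(pairs) && nrow(sites)) {
    vseq <- paste(viral, collapse = "")
    for (i in seq_len(nrow(sites))) {
      spanning <- count_spanning_reads(pairs, vseq, reference,
                                       sites$chrom[i], sites$pos[i])
      sites$zygosity[i] <- junction_zygosity(spanning, sites$support[i])
    }
  }
  rownames(sites) <- NULL
  list(scaffold_classes = classes, sites = sites)
}
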