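## Indel normalization and tandem-repeat classification.
##
## Deletions that precisely remove one unit of a tandem repeat of >= 2 units
## and insertions that precisely duplicate an adjacent sequence are the
## signal; left-alignment first makes the verdict independent of which
## VCF-equivalent representation of the same edit is supplied.

#' Left-normalize an insertion or deletion
#'
#' Shifts the edit left while the resulting sequence stays identical
#' (standard VCF left-alignment by rotation), giving each edit a canonical,
#' unique representation. Idempotent.
#'
#' @param reference reference chromosome sequence (single string).
#' @param pos 1-based anchor position (the base before the inserted/deleted
#'   bases, VCF style).
#' @param ref,alt VCF ref/alt allele strings (one of them length 1).
#' @return list(pos, ref, alt, type ("ins"/"del"), seq (inserted or deleted
#'   bases), len). `pos` is the normalized 1-based anchor (0 if the edit
#'   reaches the chromosome start, in which case ref/alt are NA).
#' @export
normalize_indel <- function(reference, pos, ref, alt) {
  pos <- as.integer(pos)
  rl <- nchar(ref)
  al <- nchar(alt)
  if (substr(reference, pos, pos + rl - 1L) != ref) {
    stop(sprintf("ref allele mismatch at %d: VCF says '%s'", pos, ref),
         call. = FALSE)
  }
  if (rl > 1 && al == 1) {
    if (substr(ref, 1, 1) != alt)
      stop("not an anchored deletion", call. = FALSE)
    L <- rl - 1L
    a <- pos + 1L            # deleted interval [a, b], 1-based
    b <- pos + L
    while (a > 1L && substr(reference, a - 1L, a - 1L) ==
             substr(reference, b, b)) {
      a <- a - 1L
      b <- b - 1L
    }
    anchor <- a - 1L
    d <- substr(reference, a, b)
    list(pos = anchor,
         ref = if (anchor >= 1) paste0(substr(reference, anchor, anchor), d)
               else NA_character_,
         alt = if (anchor >= 1) substr(reference, anchor, anchor)
               else NA_character_,
         type = "del", seq = d, len = L)
  } else if (al > 1 && rl == 1) {
    if (substr(alt, 1, 1) != ref)
      stop("not an anchored insertion", call. = FALSE)
    L <- al - 1L
    ins <- substr(alt, 2, al)
    p <- pos                 # insertion sits between p and p+1
    while (p >= 1L && substr(reference, p, p) == substr(ins, L, L)) {
      ins <- paste0(substr(reference, p, p), substr(ins, 1, L - 1L))
      p <- p - 1L
    }
    list(pos = p,
         ref = if (p >= 1) substr(reference, p, p) else NA_character_,
         alt = if (p >= 1) paste0(substr(reference, p, p), ins)
               else NA_character_,
         type = "ins", seq = ins, len = L)
  } else {
    stop("not a simple insertion or deletion", call. = FALSE)
  }
}

#' Is a deletion the removal of one tandem-repeat unit?
#'
#' TRUE iff the deleted sequence has an identical copy immediately before or
#' immediately after it in the reference, i.e. the locus holds at least two
#' tandem copies of the unit and the deletion removes exactly one.
#' Homopolymer runs are length-1-unit repeats. Both flanks are examined, so
#' the verdict does not depend on which copy the caller deleted.
#'
#' @param reference chromosome sequence.
#' @param pos 1-based anchor of the (normalized) deletion; deleted bases are
#'   at `pos+1 .. pos+nchar(del_seq)`.
#' @param del_seq the deleted sequence.
#' @return list(at_repeat, unit) with `unit = del_seq` when TRUE, else "".
#' @export
is_repeat_unit_deletion <- function(reference, pos, del_seq) {
  L <- nchar(del_seq)
  n <- nchar(reference)
  before <- pos - L + 1L >= 1L &&
    substr(reference, pos - L + 1L, pos) == del_seq
  after <- pos + 2L * L <= n &&
    substr(reference, pos + L + 1L, pos + 2L * L) == del_seq
  if (before || after) list(at_repeat = TRUE, unit = del_seq)
  else list(at_repeat = FALSE, unit = "")
}

#' Is an insertion a tandem duplication?
#'
#' TRUE iff the inserted sequence equals the reference segment immediately
#' preceding or following the insertion point.
#'
#' @param reference chromosome sequence.
#' @param pos 1-based anchor of the (normalized) insertion; the insertion
#'   sits between `pos` and `pos + 1`.
#' @param ins_seq the inserted sequence.
#' @return list(at_repeat, unit).
#' @export
is_tandem_duplication_insertion <- function(reference, pos, ins_seq) {
  L <- nchar(ins_seq)
  n <- nchar(reference)
  before <- pos - L + 1L >= 1L &&
    substr(reference, pos - L + 1L, pos) == ins_seq
  after <- pos + L <= n &&
    substr(reference, pos + 1L, pos + L) == ins_seq
  if (before || after) list(at_repeat = TRUE, unit = ins_seq)
  else list(at_repeat = FALSE, unit = "")
}

#' Normalize and repeat-classify all indels in a record set
#'
#' Runs [normalize_indel()] and the tandem-repeat tests over every in-range
#' insertion/deletion record (see [classify_variant()]).
#'
#' @param records classified variant records.
#' @param reference named character vector of chromosome sequences.
#' @return data.frame of indel calls: chrom, pos, ref, alt, kind, length
#'   (unsigned), norm_pos, indel_seq, at_repeat, repeat_unit, genotype.
#' @export
annotate_repeat_indels <- function(records, reference) {
  idx <- which(records$kind %in% c("insertion", "deletion") & records$in_range)
  out <- records[idx, , drop = FALSE]
  n <- nrow(out)
  norm_pos <- integer(n)
  indel_seq <- character(n)
  at_repeat <- logical(n)
  unit <- character(n)
  for (i in seq_len(n)) {
    seq <- reference[[out$chrom[i]]]
    nv <- normalize_indel(seq, out$pos[i], out$ref[i], out$alt[i])
    cls <- if (nv$type == "del") {
      is_repeat_unit_deletion(seq, nv$pos, nv$seq)
    } else {
      is_tandem_duplication_insertion(seq, nv$pos, nv$seq)
    }
    norm_pos[i] <- nv$pos
    indel_seq[i] <- nv$seq
    at_repeat[i] <- cls$at_repeat
    unit[i] <- cls$unit
  }
  out$length <- abs(out$length)
  out$norm_pos <- norm_pos
  out$indel_seq <- indel_seq
  out$at_repeat <- at_repeat
  out$repeat_unit <- unit
  rownames(out) <- NULL
  out
}

#' Per-length fraction of indels at tandem repeats
#'
#' For each indel length L in 1..50 present in the calls: the fraction at
#' repeats and its Poisson error, `sqrt(n_at_repeat) / n_total` (the error of
#' the counted events divided by the number of events). Lengths with no
#' events are omitted.
#'
#' @param calls output of [annotate_repeat_indels()], optionally pre-filtered
#'   to deletions or insertions.
#' @param sample sample label carried into the output.
#' @return data.frame(sample, length, n_total, n_at_repeat, fraction, error).
#' @export
repeat_fraction_curve <- function(calls, sample = "sample") {
  stopifnot(all(calls$length >= 1), all(calls$length <= 50))
  lens <- sort(unique(calls$length))
  n_total <- vapply(lens, function(L) sum(calls$length == L), integer(1))
  n_rep <- vapply(lens, function(L) sum(calls$length == L & calls$at_repeat),
                  integer(1))
  data.frame(sample = sample, length = lens, n_total = n_total,
             n_at_repeat = n_rep, fraction = n_rep / n_total,
             error = sqrt(n_rep) / n_total, stringsAsFactors = FALSE)
}

#' Per-length enrichment of repeat-indel fractions vs control samples
#'
#' `enrichment(L) = test fraction(L) / mean(control fractions(L))`. Lengths
#' absent from any control are omitted with a warning; lengths where the
#' control mean is zero are flagged undefined (NA enrichment).
#'
#' @param test_curve a [repeat_fraction_curve()] for the test sample.
#' @param control_curves list of control curves.
#' @return data.frame(length, test_fraction, control_mean, enrichment,
#'   defined).
#' @export
enrichment_curve <- function(test_curve, control_curves) {
  stopifnot(length(control_curves) >= 1)
  lens <- test_curve$length
  keep <- rep(TRUE, length(lens))
  ctrl <- matrix(NA_real_, nrow = length(lens), ncol = length(control_curves))
  for (j in seq_along(control_curves)) {
    cc <- control_curves[[j]]
    m <- match(lens, cc$length)
    ctrl[, j] <- cc$fraction[m]
    keep <- keep & !is.na(m)
  }
  if (any(!keep)) {
    warning("lengths absent from controls omitted: ",
            paste(lens[!keep], collapse = ", "))
  }
  lens <- lens[keep]
  ctrl <- ctrl[keep, , drop = FALSE]
  cmean <- rowMeans(ctrl)
  enr <- ifelse(cmean > 0, test_curve$fraction[match(lens, test_curve$length)] /
                  cmean, NA_real_)
  data.frame(length = lens,
             test_fraction = test_curve$fraction[match(lens, test_curve$length)],
             control_mean = cmean, enrichment = enr, defined = cmean > 0)
}

#' Signed indel length histogram
#'
#' Counts insertions (positive lengths) and deletions (negative lengths) per
#' length from -50 to +50, excluding 0. Coding-only histograms are produced
#' by passing the coding subset of the calls.
#'
#' @param records classified variant records (insertions/deletions in range).
#' @param scope label recorded on the output ("genome_wide" or "coding_only").
#' @return data.frame(scope, length, count) for lengths with count > 0.
#' @export
indel_length_histogram <- function(records, scope = "genome_wide") {
  idx <- records$kind %in% c("insertion", "deletion") & records$in_range
  len <- records$length[idx]
  if (!length(len)) {
    return(data.frame(scope = character(0), length = integer(0),
                      count = integer(0)))
  }
  tab <- table(len)
  data.frame(scope = scope, length = as.integer(names(tab)),
             count = as.integer(tab), stringsAsFactors = FALSE)
}
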