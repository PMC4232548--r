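## Unique/shared variant partitioning across samples.

.variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Partition variant keys into per-sample unique sets and a shared set
#'
#' A variant (matched on chrom/pos/ref/alt; zygosity is ignored) is unique to
#' a sample iff it occurs in that sample and in no other; everything else is
#' shared by at least two samples. Duplicate keys within a sample are
#' deduplicated with a warning. The unique sets plus the shared set form a
#' partition of the union, and the result does not depend on sample order.
#'
#' @param sample_sets named list of variant-record data.frames (>= 2), each
#'   with chrom, pos, ref, alt columns. Indels should be left-normalized
#'   first (see [annotate_repeat_indels()]) so representation differences do
#'   not break matching.
#' @return list(unique = named list of data.frames, shared = data.frame of
#'   keys with an `n_samples` column).
#' @export
partition_unique_shared <- function(sample_sets) {
  stopifnot(length(sample_sets) >= 2, !is.null(names(sample_sets)))
  keys <- lapply(sample_sets, function(df) {
    k <- .variant_key(df)
    if (anyDuplicated(k)) {
      warning("duplicate variant keys within a sample; deduplicated")
      df <- df[!duplicated(k), , drop = FALSE]
    }
    df
  })
  all_keys <- unlist(lapply(keys, .variant_key), use.names = FALSE)
  occ <- table(all_keys)
  uniq <- lapply(keys, function(df) {
    k <- .variant_key(df)
    out <- df[occ[k] == 1, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  shared_keys <- names(occ)[occ >= 2]
  parts <- strsplit(shared_keys, ":", fixed = TRUE)
  shared <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    ref = vapply(parts, `[`, "", 3),
    alt = vapply(parts, `[`, "", 4),
    n_samples = as.integer(occ[shared_keys]),
    stringsAsFactors = FALSE)
  shared <- shared[order(shared$chrom, shared$pos, shared$ref, shared$alt), ]
  rownames(shared) <- NULL
  list(unique = uniq, shared = shared)
}

#' Ratio of unique indels to unique SNVs
#'
#' Reported to three significant figures, the precision at which such ratios
#' are conventionally quoted.
#'
#' @param unique_indel_count,unique_snv_count non-negative counts.
#' @return the ratio, rounded to 3 significant figures.
#' @export
unique_indel_snv_ratio <- function(unique_indel_count, unique_snv_count) {
  if (unique_snv_count <= 0) {
    stop("unique SNV count is zero; ratio undefined", call. = FALSE)
  }
  signif(unique_indel_count / unique_snv_count, 3)
}
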