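## Block-based scan for copy-neutral loss of heterozygosity.
##
## SNVs are tallied in fixed blocks (default 100 kb) anchored at position 0
## of each chromosome. A block with at least `min_hom` homozygous SNVs is
## classifiable; it is LOH iff het < ratio_threshold * hom (strictly).
## Blocks below the homozygous minimum stay unclassified.

#' Tally hom/het SNVs in fixed genomic blocks
#'
#' Every genomic position belongs to exactly one block; the last block of a
#' chromosome may be short. Only SNV records with genotype `hom_alt` or
#' `het` are counted.
#'
#' @param records variant records (classified or not; non-SNV alleles are
#'   ignored).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param block_size block width in bp (default 100000).
#' @return data.frame(chrom, start, end, hom_count, het_count), 0-based
#'   half-open, ordered by chromosome and start, covering every chromosome
#'   completely.
#' @export
block_counts <- function(records, chrom_lengths, block_size = 100000) {
  stopifnot(block_size > 0)
  is_snv <- nchar(records$ref) == 1 & nchar(records$alt) == 1 &
    records$genotype %in% c("hom_alt", "het")
  r <- records[is_snv, , drop = FALSE]
  if (any(!r$chrom %in% names(chrom_lengths))) {
    stop("record on unknown chromosome: ",
         paste(setdiff(unique(r$chrom), names(chrom_lengths)), collapse = ","),
         call. = FALSE)
  }
  if (any(r$pos > chrom_lengths[r$chrom])) {
    stop("record beyond chromosome length", call. = FALSE)
  }
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(0L, len - 1L, by = block_size)
    ends <- pmin(starts + block_size, len)
    rc <- r[r$chrom == chrom, ]
    blk <- (rc$pos - 1L) %/% block_size + 1L   # block index, 1-based
    hom <- tabulate(blk[rc$genotype == "hom_alt"], nbins = length(starts))
    het <- tabulate(blk[rc$genotype == "het"], nbins = length(starts))
    out[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                               hom_count = hom, het_count = het,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify blocks as LOH / non-LOH / unclassified
#'
#' A block with fewer than `min_hom` homozygous SNVs is `unclassified` (too
#' little information); otherwise it is `loh` iff
#' `het_count < ratio_threshold * hom_count` (strict), else `non_loh`.
#'
#' @param blocks data.frame from [block_counts()], or numeric vectors via
#'   `hom_count`/`het_count`.
#' @param min_hom minimum homozygous SNVs for classifiability (default 50).
#' @param ratio_threshold het/hom ratio below which a block is LOH
#'   (default 0.1).
#' @return `blocks` with added `status` and `het_hom_ratio` columns
#'   (ratio NA when hom_count is 0).
#' @export
classify_blocks <- function(blocks, min_hom = 50, ratio_threshold = 0.1) {
  hom <- blocks$hom_count
  het <- blocks$het_count
  if (any(hom < 0) || any(het < 0)) stop("negative counts", call. = FALSE)
  status <- ifelse(hom < min_hom, "unclassified",
                   ifelse(het < ratio_threshold * hom, "loh", "non_loh"))
  blocks$status <- status
  blocks$het_hom_ratio <- ifelse(hom > 0, het / hom, NA_real_)
  blocks
}

#' Classify a single block (scalar rule)
#' @param hom_count,het_count SNV counts in the block.
#' @inheritParams classify_blocks
#' @return one of "loh", "non_loh", "unclassified".
#' @export
classify_block <- function(hom_count, het_count, min_hom = 50,
                           ratio_threshold = 0.1) {
  classify_blocks(data.frame(hom_count = hom_count, het_count = het_count),
                  min_hom, ratio_threshold)$status
}

#' Merge consecutive LOH blocks into maximal regions
#'
#' @param blocks classified blocks, ordered by chromosome and start.
#' @return data.frame(chrom, start, end, n_blocks, size) of maximal runs of
#'   consecutive `loh` blocks (0-based half-open; size respects last-block
#'   truncation).
#' @export
merge_loh_regions <- function(blocks) {
  out <- list()
  for (chrom in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == chrom, ]
    b <- b[order(b$start), ]
    is_loh <- b$status == "loh"
    if (!any(is_loh)) next
    r <- rle(is_loh)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = b$start[idx_start[j]], end = b$end[idx_end[j]],
        n_blocks = r$lengths[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_blocks = integer(0),
                      size = integer(0)))
  }
  res <- do.call(rbind, out)
  res$size <- res$end - res$start
  rownames(res) <- NULL
  res
}

#' Genome-level LOH summary
#'
#' @param blocks classified blocks.
#' @param regions merged LOH regions from [merge_loh_regions()].
#' @param block_size block width for the histogram binning.
#' @return list(n_blocks, loh_fraction_pct, unclassified_fraction_pct,
#'   size_histogram (data.frame size, n), mean_hom, mean_het).
#' @export
loh_summary <- function(blocks, regions = merge_loh_regions(blocks),
                        block_size = 100000) {
  n <- nrow(blocks)
  if (n == 0) stop("no blocks to summarize", call. = FALSE)
  sizes <- regions$n_blocks * block_size
  hist <- if (length(sizes)) {
    tab <- table(sizes)
    data.frame(size = as.integer(names(tab)), n = as.integer(tab))
  } else data.frame(size = integer(0), n = integer(0))
  list(n_blocks = n,
       loh_fraction_pct = round_half_up(100 * sum(blocks$status == "loh") / n, 1),
       unclassified_fraction_pct =
         round_half_up(100 * sum(blocks$status == "unclassified") / n, 1),
       size_histogram = hist,
       mean_hom = mean(blocks$hom_count),
       mean_het = mean(blocks$het_count))
}

#' Write LOH regions as BED (0-based half-open)
#' @param regions data.frame from [merge_loh_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loh_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    name = sprintf("loh_%dkb", regions$size %/% 1000))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
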