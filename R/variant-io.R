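## Read, filter, classify and summarize variant records.
##
## A variant record is one row of a data.frame with columns: chrom, pos
## (1-based), ref, alt, qual, depth, genotype ("hom_alt"/"het"/"other").
## VCF stays 1-based at the I/O boundary; all internal interval math in the
## package is 0-based half-open.

#' Read a VCF into a variant-record data.frame
#'
#' Parses with vcfR, then flattens to one record per alt allele: multi-allelic
#' rows are split, sharing chrom/pos. Per alt allele, a genotype carrying
#' only that allele (1/1 or 1|1) maps to `hom_alt`; one carrying it together
#' with any other allele (0/1, 1/0, 1/2) maps to `het`; anything else,
#' including a missing GT, maps to `other`. Depth comes from the sample
#' FORMAT DP field, falling back to INFO DP.
#'
#' @param path VCF path.
#' @return data.frame with columns chrom, pos, ref, alt, qual, depth,
#'   genotype, in file order.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), depth = integer(0),
                      genotype = character(0), stringsAsFactors = FALSE))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]))
  if (length(bad)) {
    stop(sprintf("malformed VCF data row %d in %s", bad[1], path),
         call. = FALSE)
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  depth <- rep(NA_integer_, n)
  gt_raw <- rep(NA_character_, n)
  if (ncol(v@gt) >= 2) {
    gt_raw <- unname(vcfR::extract.gt(v, element = "GT")[, 1])
    dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
    depth <- dp
  }
  if (anyNA(depth)) {
    info_dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
    depth[is.na(depth)] <- info_dp[is.na(depth)]
  }
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(n), n_alt)
  alt_index <- sequence(n_alt)
  gt <- gt_raw[idx]
  alleles <- strsplit(gsub("\\|", "/", ifelse(is.na(gt), ".", gt)), "/")
  genotype <- mapply(function(al, ai) {
    al <- al[al != "."]
    if (!length(al)) return("other")
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al)) return("other")
    if (all(al == ai)) return("hom_alt")
    if (any(al == ai)) return("het")
    "other"
  }, alleles, alt_index)
  data.frame(chrom = fix[idx, "CHROM"], pos = pos[idx], ref = fix[idx, "REF"],
             alt = unlist(alt_list), qual = qual[idx], depth = depth[idx],
             genotype = unname(genotype), stringsAsFactors = FALSE)
}

#' Write variant records as minimal VCF
#' @param records variant-record data.frame (see [read_vcf()]).
#' @param path output path.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2", "##source=genomescan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name))
  gt <- c(hom_alt = "1/1", het = "0/1", other = "./.")[records$genotype]
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP\t%s:%d",
                  records$chrom, records$pos, records$ref, records$alt,
                  formatC(records$qual, format = "fg"), gt, records$depth)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Filter variant records on depth and quality
#'
#' Keeps records with `depth >= min_depth` and `qual >= min_quality` (both
#' boundaries inclusive); order is preserved and the kept/dropped counts are
#' attached as the `"filter_summary"` attribute.
#'
#' @param records variant-record data.frame.
#' @param min_depth minimum read depth (default 3).
#' @param min_quality minimum variant quality (default 30).
#' @return filtered data.frame with attribute `filter_summary` =
#'   c(kept, dropped).
#' @export
filter_variants <- function(records, min_depth = 3, min_quality = 30) {
  stopifnot(min_depth >= 0, min_quality >= 0)
  keep <- !is.na(records$depth) & !is.na(records$qual) &
    records$depth >= min_depth & records$qual >= min_quality
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_summary") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Classify variants by allele lengths
#'
#' Pure allele-length rules: equal length 1 is an SNV; a one-base ref with a
#' longer alt is an insertion (positive length); a one-base alt with a longer
#' ref is a deletion (negative length); anything else is `mnv_or_complex`.
#' Indels longer than 50 bp are flagged out of range (`in_range = FALSE`) and
#' are excluded from all downstream tallies.
#'
#' @param records variant-record data.frame.
#' @return `records` with added columns `kind`, `length` (signed), `in_range`.
#' @export
classify_variant <- function(records) {
  rl <- nchar(records$ref)
  al <- nchar(records$alt)
  kind <- rep("mnv_or_complex", nrow(records))
  len <- integer(nrow(records))
  kind[rl == 1 & al == 1] <- "snv"
  ins <- rl == 1 & al > 1
  kind[ins] <- "insertion"
  len[ins] <- al[ins] - 1L
  del <- al == 1 & rl > 1
  kind[del] <- "deletion"
  len[del] <- -(rl[del] - 1L)
  records$kind <- kind
  records$length <- len
  records$in_range <- abs(len) <= 50L
  records
}

#' Homozygous/heterozygous counts and homozygous fraction
#'
#' Counts records with genotype `hom_alt` or `het`; the homozygous fraction
#' is reported as a percentage rounded half-up to one decimal.
#'
#' @param records variant-record data.frame.
#' @return list(hom, het, hom_pct, defined); `hom_pct` is NA and `defined`
#'   FALSE when no record is classifiable.
#' @export
zygosity_counts <- function(records) {
  if (is.data.frame(records)) {
    hom <- sum(records$genotype == "hom_alt")
    het <- sum(records$genotype == "het")
  } else {
    stopifnot(length(records) == 2)
    hom <- records[[1]]
    het <- records[[2]]
  }
  n <- hom + het
  if (n == 0) {
    return(list(hom = 0L, het = 0L, hom_pct = NA_real_, defined = FALSE))
  }
  list(hom = hom, het = het, hom_pct = round_half_up(100 * hom / n, 1),
       defined = TRUE)
}
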