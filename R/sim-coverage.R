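## Simulate a read-depth track and per-site allele depths over a ploidy map.

#' Simulate a coverage track and heterozygous allele depths
#'
#' Window depths are Poisson around `mean_coverage * ploidy / 2` (the depth
#' model the coverage-based copy-number caller assumes). For each
#' heterozygous truth variant, total depth is Poisson and the alt-allele
#' depth binomial with success probability equal to the planted B-allele
#' fraction: 1/2 on disomic chromosomes, 1/3 or 2/3 (coin flip) on trisomic,
#' 1/2 on 2+2 tetrasomic.
#'
#' @param genome a `synthetic_genome`.
#' @param ploidy_map named integer vector, chromosome -> copy number.
#' @param mean_coverage disomic mean depth.
#' @param seed RNG seed.
#' @param window window width in bp for the track (default 10000).
#' @param het_variants optional truth data.frame; rows with zygosity "het"
#'   get allele-depth annotations.
#' @return list(track = data.frame(chrom, start, end, depth),
#'   allele_depth = data.frame(chrom, pos, ref_count, alt_count, baf_true)).
#' @export
simulate_coverage <- function(genome, ploidy_map = genome$config$ploidy_map,
                              mean_coverage = genome$config$mean_coverage,
                              seed = genome$config$seed + 2L,
                              window = 10000, het_variants = NULL) {
  if (!all(names(genome$sequences) %in% names(ploidy_map))) {
    stop("ploidy_map must cover all chromosomes", call. = FALSE)
  }
  set.seed(seed)
  track <- list()
  for (chrom in names(genome$sequences)) {
    len <- nchar(genome$sequences[[chrom]])
    starts <- seq(0L, len - 1L, by = window)
    ends <- pmin(starts + as.integer(window), len)
    lambda <- mean_coverage * ploidy_map[[chrom]] / 2
    track[[chrom]] <- data.frame(
      chrom = chrom, start = starts, end = ends,
      depth = rpois(length(starts), lambda), stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, track)
  rownames(track) <- NULL

  allele_depth <- NULL
  if (!is.null(het_variants)) {
    hv <- het_variants[het_variants$zygosity == "het", , drop = FALSE]
    if (nrow(hv)) {
      ploidy <- ploidy_map[hv$chrom]
      baf <- ifelse(ploidy == 3,
                    ifelse(runif(nrow(hv)) < 0.5, 1 / 3, 2 / 3), 0.5)
      tot <- pmax(1L, rpois(nrow(hv), mean_coverage * ploidy / 2))
      alt <- rbinom(nrow(hv), tot, baf)
      allele_depth <- data.frame(chrom = hv$chrom, pos = hv$pos,
                                 ref_count = tot - alt, alt_count = alt,
                                 baf_true = baf, stringsAsFactors = FALSE)
    }
  }
  list(track = track, allele_depth = allele_depth)
}

#' Write the heterozygous allele-depth table as TSV
#' @param allele_depth data.frame from [simulate_coverage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_depth_tsv <- function(allele_depth, path) {
  write_tsv_meta(allele_depth, path, meta = list(coords = "pos is 1-based"))
}

#' @rdname write_allele_depth_tsv
#' @export
read_allele_depth_tsv <- function(path) read_tsv_meta(path)
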