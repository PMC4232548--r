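## Whole-chromosome copy number from mean coverage relative to a disomic
## baseline, plus B-allele-frequency profiling of heterozygous sites.

RELIABLE_MIN_LENGTH <- 5e6   # coverage is not a reliable ploidy measure below

#' Length-weighted mean coverage per chromosome
#'
#' @param track data.frame(chrom, start, end, depth), 0-based half-open
#'   windows tiling each chromosome completely (gaps are rejected).
#' @return data.frame(chrom, length, mean_depth, reliable); `reliable` is
#'   FALSE for chromosomes shorter than 5 Mb.
#' @export
chromosome_mean_coverage <- function(track) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    t <- track[track$chrom == chrom, ]
    t <- t[order(t$start), ]
    if (t$start[1] != 0 || any(t$start[-1] != t$end[-nrow(t)])) {
      stop("coverage track has a gap on ", chrom, call. = FALSE)
    }
    w <- t$end - t$start
    len <- sum(w)
    out[[chrom]] <- data.frame(
      chrom = chrom, length = len,
      mean_depth = sum(t$depth * w) / len,
      reliable = len >= RELIABLE_MIN_LENGTH, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Disomic baseline depth
#'
#' Length-weighted mean depth over chromosomes assumed disomic (in a real
#' genome, the larger autosomes without copy-number evidence).
#'
#' @param coverages data.frame from [chromosome_mean_coverage()].
#' @param baseline_chroms chromosome names forming the baseline.
#' @return baseline depth (scalar).
#' @export
disomic_baseline <- function(coverages, baseline_chroms) {
  if (!length(baseline_chroms)) stop("empty baseline set", call. = FALSE)
  miss <- setdiff(baseline_chroms, coverages$chrom)
  if (length(miss)) {
    stop("baseline chromosome missing from track: ",
         paste(miss, collapse = ","), call. = FALSE)
  }
  b <- coverages[coverages$chrom %in% baseline_chroms, ]
  sum(b$mean_depth * b$length) / sum(b$length)
}

#' Integer copy number from mean depth vs disomic baseline
#'
#' `copy number = round(2 * mean_depth / baseline)`, minimum 1. Calls on
#' chromosomes shorter than 5 Mb carry `reliable = FALSE`.
#'
#' @param mean_depth chromosome mean depth (vectorized).
#' @param baseline disomic baseline depth.
#' @param chrom_length chromosome length in bp.
#' @return data.frame(copy_number, ratio, reliable).
#' @export
copy_number_estimate <- function(mean_depth, baseline, chrom_length = Inf) {
  stopifnot(baseline > 0)
  ratio <- mean_depth / baseline
  cn <- pmax(1L, as.integer(floor(2 * ratio + 0.5)))
  data.frame(copy_number = cn, ratio = ratio,
             reliable = chrom_length >= RELIABLE_MIN_LENGTH)
}

#' B-allele-frequency profile of one chromosome
#'
#' Histograms the alt-allele fraction of heterozygous sites in (0.1, 0.9)
#' at bin width 0.05, finds modes (peaks holding at least `min_mass` of the
#' sites, merged when closer than 0.08) and labels the allelic state:
#' a single mode near 0.5 is disomic-like (or tetrasomic 2+2 when the
#' coverage copy number is 4); modes near 1/3 and 2/3 are trisomic-like.
#'
#' @param allele_depths data.frame(chrom, pos, ref_count, alt_count) for
#'   heterozygous sites.
#' @param chrom chromosome to profile.
#' @param copy_number coverage-based copy number (used to separate the
#'   disomic and tetrasomic 2+2 interpretations of a 0.5 mode).
#' @param min_sites minimum heterozygous sites for a call (default 50).
#' @param min_mass minimum fraction of sites under a peak (default 0.1).
#' @return list(n_sites, modes, state); state is one of "disomic_like",
#'   "trisomic_like", "tetrasomic_2plus2_like", "ambiguous", "no_call".
#' @export
baf_profile <- function(allele_depths, chrom, copy_number = 2,
                        min_sites = 50, min_mass = 0.1) {
  d <- allele_depths[allele_depths$chrom == chrom, ]
  tot <- d$ref_count + d$alt_count
  baf <- d$alt_count[tot > 0] / tot[tot > 0]
  baf <- baf[baf > 0.1 & baf < 0.9]
  if (length(baf) < min_sites) {
    return(list(n_sites = length(baf), modes = numeric(0), state = "no_call"))
  }
  breaks <- seq(0.1, 0.9, by = 0.05)
  bin <- findInterval(baf, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  dens <- counts / length(baf)
  mids <- breaks[-length(breaks)] + 0.025
  ## local maxima with enough mass
  nb <- length(dens)
  peak <- which(dens >= min_mass &
                  dens >= c(-Inf, dens[-nb]) &
                  dens >= c(dens[-1], -Inf))
  modes <- mids[peak]
  if (length(modes) > 1) {        # merge close modes, weighted by mass
    merged <- numeric(0)
    grp_start <- 1
    for (i in seq_along(modes)[-1]) {
      if (modes[i] - modes[i - 1] >= 0.08) {
        idx <- peak[grp_start:(i - 1)]
        merged <- c(merged, sum(mids[idx] * dens[idx]) / sum(dens[idx]))
        grp_start <- i
      }
    }
    idx <- peak[grp_start:length(modes)]
    merged <- c(merged, sum(mids[idx] * dens[idx]) / sum(dens[idx]))
    modes <- merged
  }
  near <- function(x, target, tol = 0.09) abs(x - target) <= tol
  state <- if (length(modes) == 1 && near(modes, 0.5)) {
    if (copy_number >= 4) "tetrasomic_2plus2_like" else "disomic_like"
  } else if (length(modes) == 2 && near(modes[1], 1 / 3) &&
             near(modes[2], 2 / 3)) {
    "trisomic_like"
  } else "ambiguous"
  list(n_sites = length(baf), modes = modes, state = state)
}

#' Full per-chromosome copy-number and allelic-state table
#'
#' @param track coverage track (see [chromosome_mean_coverage()]).
#' @param allele_depths heterozygous allele-depth table (may be NULL).
#' @param baseline_chroms chromosomes forming the disomic baseline.
#' @return data.frame(chrom, length, mean_depth, ratio, copy_number,
#'   reliable, baf_state).
#' @export
copy_number_table <- function(track, allele_depths, baseline_chroms) {
  cov <- chromosome_mean_coverage(track)
  base <- disomic_baseline(cov, baseline_chroms)
  est <- copy_number_estimate(cov$mean_depth, base, cov$length)
  cov$ratio <- est$ratio
  cov$copy_number <- est$copy_number
  cov$baf_state <- vapply(seq_len(nrow(cov)), function(i) {
    if (is.null(allele_depths)) return("no_call")
    baf_profile(allele_depths, cov$chrom[i], cov$copy_number[i])$state
  }, character(1))
  cov
}

#' Write / read a bedGraph-like coverage track
#' @param track data.frame(chrom, start, end, depth).
#' @param path file path.
#' @return `path` (write) or the track data.frame (read).
#' @export
write_coverage_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_track
#' @export
read_coverage_track <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "depth")
  df
}
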