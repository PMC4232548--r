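#' Simulation configuration for the synthetic genome generator
#'
#' Bundles and validates every parameter of the synthetic diploid genome:
#' chromosome sizes, SNV/indel rates, the six-class substitution spectrum,
#' heterozygosity, planted LOH tracts, per-chromosome ploidy, coverage depth
#' and viral integration sites. Defaults mirror whole-genome resequencing of
#' a chicken-like genome at desk scale: 5.8 SNVs/kb with the DT40-like
#' spectrum, 46.9% heterozygous variants, 0.66 indels/kb, a trisomic and a
#' tetrasomic chromosome, a monosomic W, and ~52x mean coverage.
#'
#' @param chromosome_lengths named integer vector of chromosome sizes in bp.
#' @param snv_rate SNVs per kb.
#' @param spectrum_weights six non-negative weights in [SPECTRUM_CLASSES]
#'   order; normalized to sum to 1.
#' @param het_fraction fraction of planted variants that are heterozygous
#'   (outside LOH tracts and ploidy-1 chromosomes, where all are homozygous).
#' @param loh_tracts data.frame(chrom, start, end), 0-based half-open planted
#'   LOH intervals.
#' @param indel_rate indels per kb.
#' @param repeat_indel_fraction fraction of indels planted at catalog tandem
#'   repeats (deletions remove exactly one unit; insertions duplicate one).
#' @param indel_length_weights positive weights over non-repeat indel lengths
#'   1..length(indel_length_weights) (max 50).
#' @param ploidy_map named integer vector, chromosome -> copy number (>= 1).
#' @param mean_coverage haploid-pair mean sequencing depth (depth of a
#'   disomic chromosome).
#' @param viral_sites data.frame(chrom, pos, orientation, all_alleles):
#'   1-based junction coordinate, orientation "+"/"-", and whether the
#'   insertion is carried by all alleles (then no reads span the junction).
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(chromosome_lengths = c(chr1 = 1000000, chr2 = 600000,
                                              chr3 = 400000, chrW = 150000),
                       snv_rate = 5.8,
                       spectrum_weights = c(0.0735, 0.0713, 0.3531,
                                            0.0777, 0.3529, 0.0716),
                       het_fraction = 0.469,
                       loh_tracts = data.frame(
                         chrom = c("chr1", "chr2"),
                         start = c(100000L, 200000L),
                         end = c(500000L, 500000L)),
                       indel_rate = 0.66,
                       repeat_indel_fraction = 0.3,
                       indel_length_weights = 0.55^(0:14),
                       ploidy_map = c(chr1 = 2, chr2 = 3, chr3 = 4, chrW = 1),
                       mean_coverage = 52,
                       viral_sites = data.frame(
                         chrom = c("chr1", "chr3"),
                         pos = c(60000L, 200000L),
                         orientation = c("+", "-"),
                         all_alleles = c(TRUE, FALSE)),
                       seed = 1L) {
  if (is.null(names(chromosome_lengths)) || any(names(chromosome_lengths) == ""))
    stop_field("chromosome_lengths", "must be a named vector")
  if (any(chromosome_lengths <= 0))
    stop_field("chromosome_lengths", "all lengths must be > 0")
  if (length(spectrum_weights) != 6 || any(spectrum_weights < 0) ||
      sum(spectrum_weights) <= 0)
    stop_field("spectrum_weights", "need six non-negative weights with positive sum")
  spectrum_weights <- spectrum_weights / sum(spectrum_weights)
  names(spectrum_weights) <- SPECTRUM_CLASSES
  if (het_fraction < 0 || het_fraction > 1)
    stop_field("het_fraction", "must be in [0, 1]")
  loh_tracts <- as.data.frame(loh_tracts)
  if (nrow(loh_tracts)) {
    if (!all(c("chrom", "start", "end") %in% names(loh_tracts)))
      stop_field("loh_tracts", "needs columns chrom, start, end")
    if (!all(loh_tracts$chrom %in% names(chromosome_lengths)))
      stop_field("loh_tracts", "unknown chromosome")
    if (any(loh_tracts$start < 0) || any(loh_tracts$end <= loh_tracts$start) ||
        any(loh_tracts$end > chromosome_lengths[loh_tracts$chrom]))
      stop_field("loh_tracts", "tracts must lie within chromosome bounds")
  }
  if (snv_rate < 0) stop_field("snv_rate", "must be >= 0")
  if (indel_rate < 0) stop_field("indel_rate", "must be >= 0")
  if (repeat_indel_fraction < 0 || repeat_indel_fraction > 1)
    stop_field("repeat_indel_fraction", "must be in [0, 1]")
  if (length(indel_length_weights) < 1 || length(indel_length_weights) > 50 ||
      any(indel_length_weights < 0))
    stop_field("indel_length_weights", "non-negative weights over lengths 1..50")
  if (!all(names(chromosome_lengths) %in% names(ploidy_map)))
    stop_field("ploidy_map", "must cover every chromosome")
  if (any(ploidy_map < 1) || any(ploidy_map != round(ploidy_map)))
    stop_field("ploidy_map", "ploidy must be an integer >= 1")
  if (mean_coverage <= 0) stop_field("mean_coverage", "must be > 0")
  viral_sites <- as.data.frame(viral_sites)
  if (nrow(viral_sites)) {
    if (!all(c("chrom", "pos", "orientation") %in% names(viral_sites)))
      stop_field("viral_sites", "needs columns chrom, pos, orientation")
    if (is.null(viral_sites$all_alleles)) viral_sites$all_alleles <- FALSE
    if (!all(viral_sites$chrom %in% names(chromosome_lengths)))
      stop_field("viral_sites", "unknown chromosome")
    if (any(viral_sites$pos < 1) ||
        any(viral_sites$pos > chromosome_lengths[viral_sites$chrom]))
      stop_field("viral_sites", "position outside chromosome bounds")
    if (!all(viral_sites$orientation %in% c("+", "-")))
      stop_field("viral_sites", "orientation must be '+' or '-'")
  }
  if (length(seed) != 1 || is.na(seed) || seed != round(seed))
    stop_field("seed", "must be a single integer")
  structure(list(
    chromosome_lengths = setNames(as.integer(chromosome_lengths),
                                  names(chromosome_lengths)),
    snv_rate = snv_rate,
    spectrum_weights = spectrum_weights,
    het_fraction = het_fraction,
    loh_tracts = loh_tracts,
    indel_rate = indel_rate,
    repeat_indel_fraction = repeat_indel_fraction,
    indel_length_weights = indel_length_weights,
    ploidy_map = ploidy_map[names(chromosome_lengths)],
    mean_coverage = mean_coverage,
    viral_sites = viral_sites,
    seed = as.integer(seed)), class = "sim_config")
}
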