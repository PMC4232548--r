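#' Reported variant tallies for the DT40 cell line and two domestic breeds
#'
#' Whole-genome SNV and indel counts reported for the DT40 bursal-lymphoma
#' cell line and the L2 and Silkie chicken breeds, each called against the
#' same reference genome: the six-class spectrum of all and of
#' sample-unique SNVs, homozygous/heterozygous indel counts (all and
#' unique), and the fraction of 10-bp deletions at tandem repeats. These
#' serve as worked-example inputs: feeding the counts through
#' [compute_spectrum()], [zygosity_counts()], [unique_indel_snv_ratio()] and
#' [enrichment_curve()] reproduces the percentages and ratios quoted for
#' these genomes.
#'
#' @return list of data.frames/vectors: `snv_all`, `snv_unique` (six-class
#'   counts per sample), `indel_all`, `indel_unique` (hom/het counts per
#'   sample), `repeat_del_10bp` (fraction of 10-bp deletions at repeats per
#'   sample).
#' @export
dt40_reference_counts <- function() {
  snv_all <- data.frame(
    class = SPECTRUM_CLASSES,
    DT40 = c(459364L, 445483L, 2207538L, 485466L, 2206210L, 447492L),
    L2 = c(455653L, 446463L, 2249362L, 478766L, 2181601L, 443900L),
    Silkie = c(459896L, 451513L, 2276302L, 481672L, 2211668L, 448589L))
  snv_unique <- data.frame(
    class = SPECTRUM_CLASSES,
    DT40 = c(152918L, 132424L, 733718L, 148064L, 556837L, 122404L),
    L2 = c(125881L, 112578L, 631195L, 125262L, 467746L, 100442L),
    Silkie = c(153238L, 135442L, 758788L, 145251L, 572208L, 121206L))
  indel_all <- data.frame(
    zygosity = c("hom", "het"),
    DT40 = c(441245L, 267647L),
    L2 = c(389374L, 220838L),
    Silkie = c(370100L, 223594L))
  indel_unique <- data.frame(
    zygosity = c("hom", "het"),
    DT40 = c(125420L, 114504L),
    L2 = c(71472L, 72201L),
    Silkie = c(78273L, 84728L))
  repeat_del_10bp <- c(DT40 = 0.28, L2 = 0.16, Silkie = 0.17)
  list(snv_all = snv_all, snv_unique = snv_unique, indel_all = indel_all,
       indel_unique = indel_unique, repeat_del_10bp = repeat_del_10bp)
}
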