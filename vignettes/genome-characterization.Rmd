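---
title: "Characterizing a resequenced genome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a resequenced genome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This package implements the downstream characterization of a resequenced
genome against a reference — the kind of analysis applied to the DT40
bursal-lymphoma cell line compared with the L2 and Silkie chicken breed
genomes. This vignette records the models, the tunable parameters, the
numerical decisions, and what the synthetic-data tests do and do not
demonstrate. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## Variant records and filtering

A variant record is a (chrom, pos, ref, alt, qual, depth, genotype) tuple.
VCF input stays 1-based; every internal interval computation is 0-based
half-open, with conversions only at I/O boundaries. The call filter keeps
records with depth ≥ 3 and quality ≥ 30, both boundaries inclusive; these
defaults are the standard VCFtools-style thresholds for SAMtools calls, and
site-level depth is used (whether the original pipelines used site or
sample depth is generally unstated; with one sample per VCF the two
coincide). Multi-allelic rows split into one record per alt allele; a
genotype carrying only that allele is `hom_alt`, one carrying it with any
other allele (including 1/2) is `het`, and anything else — missing GT
included — is `other` and is excluded from zygosity tallies. Indels longer
than 50 bp are flagged out of range and excluded from all tallies, matching
the ≤ 50 bp call set the analysis is designed for.

## Mutation spectrum

Each substitution is merged with its reverse complement, giving six classes
in fixed order (CG>AT, CG>GC, CG>TA, TA>AT, TA>CG, TA>GC); the fixed order
and half-up rounding of percentages to two decimals make every table
byte-stable. Counts are never rounded. An empty spectrum is explicitly
flagged rather than reported as 0/0 percentages. Strand symmetry
(complementing all alleles leaves the spectrum unchanged) and count
conservation are enforced as property tests.

## Unique/shared partition

Samples are compared by exact variant key (chrom, pos, ref, alt) after
left-normalizing indels, so representation differences cannot break
matching; allele-aware point matching is at least as precise as the
interval-intersection approach it replaces and identical for SNVs.
Zygosity is deliberately ignored for uniqueness — a site homozygous in one
sample and heterozygous in another is shared. A key present in exactly one
sample is unique to it; the unique sets plus the shared-by-≥2 set partition
the union, independent of sample order. The unique-indel/unique-SNV ratio
is reported to three significant figures.

## LOH block scan

SNVs are tallied in non-overlapping blocks (default 100 kb) anchored at
position 0 of each chromosome — anchoring is a free choice, and position 0
is the simplest reproducible one. A block needs at least `min_hom = 50`
homozygous SNVs to be classifiable; below that it is `unclassified` and
never contributes to LOH regions. A classifiable block is LOH iff
`het < 0.1 × hom`, strictly. The two published phrasings of this rule
("at least 10-times greater" vs "ratio less than 0.1") disagree exactly at
the boundary `het = 0.1 × hom`; the ratio-less-than form is used because it
is the one stated as the classification rule, and the boundary case is a
measure-zero event at realistic densities. Consecutive LOH blocks merge
into maximal regions; region size is end − start, so a truncated final
block contributes its true width. Detection below one block width is out of
scope by construction — at ~300 SNVs per 100 kb the density cannot support
it.

## Indels at tandem repeats

Indels are first left-aligned by the standard rotation (shift the edit left
while the edited sequence is unchanged); normalization is idempotent and
representation-invariant, which the tests verify against a brute-force
sequence-equality oracle. A deletion is a repeat-unit removal iff the
deleted sequence has an identical copy immediately before *or* after it in
the reference — both flanks are examined so the verdict does not depend on
which copy was deleted; "at least two repeat units" is evaluated on the
reference (pre-deletion) state, and partial-unit matches do not count. A
homopolymer contraction is the unit-length-1 case. An insertion is a tandem
duplication iff it equals the reference segment immediately preceding or
following the insertion point. Per length L, the curve reports
fraction = k/N with error √k/N — read as the Poisson error of the
numerator over the denominator; the published error-bar phrasing is
ambiguous between this and √N/N, and the √k/N reading is recorded here and
in the output metadata because it is the Poisson error of the counted
events. Enrichment at L is the test fraction over the mean of the control
fractions, undefined (flagged) where the control mean is zero.

## Coding impact

Gene models are ordered CDS intervals with strand; projection maps a
genomic position to its spliced CDS coordinate, complementing alleles for
reverse-strand genes. SNV effects come from translating the reference and
alternate codons (synonymous / nonsynonymous / stop-gain / stop-loss);
nonsynonymous changes carry the Grantham distance, embedded as a
plain-text copy of the published 20×20 matrix, with the conventional
severity bands: ≤ 50 conservative, 51–100 moderately conservative, 101–150
moderately radical, > 150 radical. Indels in CDS are frameshift when the
length is not divisible by three, in-frame otherwise; an indel crossing a
CDS boundary is called frameshift with a boundary flag, because the true
effect would require transcript evidence the pipeline does not have.
Insertions exactly at a CDS edge are treated as noncoding (the inserted
copy can equally be assigned to the intron). "Damaging" for gene
aggregation means radical nonsynonymous, frameshift, in-frame indel, or
stop-gain — in-frame indels are included because whole-codon loss can
inactivate a protein; the category set is a configurable argument since
published gene-list definitions vary in exactly which categories they
admit. List A contains genes with ≥ 1 sample-unique homozygous damaging
hit; list B genes with ≥ 2 distinct damaging hits, the heteroallelic-
combination candidates (haplotype phase is not resolved). Splice-site and
UTR effects are out of scope.

## Coverage copy number and BAF states

Chromosome mean depth is the length-weighted mean of the coverage-track
windows; the disomic baseline is the length-weighted mean over a named set
of assumed-disomic chromosomes. Copy number is `round(2 × depth /
baseline)` with a floor of one copy — an explicit rounding rule where the
original analysis read the value off a plot. Chromosomes shorter than 5 Mb
keep their call but are flagged unreliable, the published caveat for
small-chromosome coverage bias. BAF modes are found on a fixed 0.05-wide
histogram of alt-allele fractions in (0.1, 0.9), peaks must hold ≥ 10% of
sites, and peaks closer than 0.08 merge (mass-weighted); a single mode
near 0.5 is disomic-like — or 2+2 tetrasomic-like when coverage says four
copies, the signature being a doubled depth ratio with only intermediate
allele frequency 0.5 — and modes near 1/3 and 2/3 are trisomic-like. At
least 50 heterozygous sites are required for any call; a monosomic
chromosome therefore yields `no_call`, which is itself the expected
signature.

## Viral integrations

Alignment hits are *consumed* in 12-column tabular (outfmt-6) form; the
package does not re-implement an aligner. For synthetic data an exact
k-mer seed-and-extend matcher (anchor stride = k = 25, maximal exact
extension, both strands, containment-deduplicated) produces equivalent
hits, so tests need no external program. Scaffold classification discards
hits under 200 bp or 90% identity — thresholds the source analyses left
unquantified, so they are explicit, configurable arguments — and a
scaffold whose only viral evidence was such a short match on a long
(≥ 5 × 200 bp) scaffold keeps an `excluded_short` annotation. On a mixed
scaffold the junction is the host coordinate where the host alignment
meets the viral segment; up to 50 bp of unexplained spacer is tolerated
and junction micro-homology (the host hit extending into the viral
segment) is trimmed back, which can leave a one-base ambiguity. The
read-pair path takes pairs with exactly one viral mate (≥ 80% of the
read's 25-mers in the viral genome), places the host mate by exact match,
clusters placements within 1 kb, and reports clusters with ≥ 3 pairs at
the cluster edge facing the junction. Zygosity: support ≥ 3 with zero
junction-spanning host reads means the insertion is on all alleles;
support ≥ 3 with ≥ 3 spanning reads is partial; anything weaker is
no-call. Endogenous retroviruses are handled as a user-supplied exclusion
list of viral sequence ids.

## The synthetic-data generator

The generator is first-class, tested code. It emulates: a multi-chromosome
diploid genome (default 3–5 chromosomes, 0.15–1 Mb) with a catalog of
primitive tandem-repeat units (1–15 bp, 2–6 copies, about one locus per
1.5 kb) and ≥ 2 multi-exon CDS genes per chromosome on both strands with
valid start/stop codons; SNVs at 5.8/kb drawn multinomially over the
DT40-like six-class spectrum with 46.9% heterozygotes; indels at 0.66/kb,
a configurable fraction planted at catalog repeats (deletions remove
exactly one unit, insertions duplicate one) and the remainder
rejection-sampled *away* from repeat context so the planted fraction is
the truth; planted LOH tracts and monosomic chromosomes force
homozygosity; a Poisson coverage track at `mean_coverage × ploidy/2`
(52× disomic) with binomial allele depths at the planted B-allele
fraction (1/2, 1/3 or 2/3, or 1/2 for 2+2 tetrasomy); and viral
insertions as mixed scaffolds (500 bp host flank + 250 bp LTR, reverse-
complemented for reverse orientation), viral-only/host-only decoys, and
chimeric read pairs at 100 bp reads / 350 bp fragments, with junction-
spanning host pairs emitted only for insertions not carried by all
alleles. Quality and depth are uniform over 10–60 and 1–60, deliberately
straddling the filter thresholds so the filter stage is non-trivially
exercised. The noise models are the simplest consistent with the observed
data shapes — Poisson depth, binomial allele depth; none is stated in the
source analyses.

What the generator does *not* emulate: read-level sequencing error and
quality recalibration, alignment artifacts, GC bias, real linkage
structure, SNP-array noise, and genuine microsatellite mutational
processes. Passing tests therefore demonstrate correctness of the
*computations* on inputs with known truth, not robustness to every
real-data artifact.

Spectrum weights passed to `sim_config()` are normalized to sum to one, so
published percentage columns (which carry rounding error of ~1e-4) can be
used verbatim as weights.

## Test design and problem sizes

Oracles are independent of the code paths they check: tandem-repeat
classification is compared against a scanner that enumerates all tandem
pairs in the reference (exhaustively over all two-letter references to
length 12 with every deletion up to 6 bp, all four-letter references to
length 7 with every deletion, and edit-and-rescan for insertions — the
two-letter alphabet concentrates the repeat-rich hard cases while keeping
exhaustive enumeration tractable); coding classification against
edit-the-chromosome, re-splice, re-translate on ≥ 1000 fuzzed variants
over multi-exon genes on both strands; normalization against brute-force
sequence equality of the edited genomes. Recovery tests run at desk scale:
a 5-Mb chromosome for LOH boundary recovery (≤ 1 block error on planted
tracts ≥ 300 kb), 20,000 SNVs for spectrum recovery within three
multinomial standard errors, 200-kb chromosomes per ploidy for
copy-number recovery, and twenty insertion-free genomes for the viral
false-positive check. These sizes were chosen so the whole suite runs on a
laptop in minutes while keeping every statistical check adequately
powered.

## Known limitations

Copy number is whole-chromosome only; there is no segmentation or joint
depth/BAF probability model. The LOH scan cannot see events below one
block width. Heteroallelic gene candidates are not phased. The read-pair
integration path assumes error-free exact placement, which is appropriate
for the synthetic data it is tested on but would need a real aligner on
real reads. The Grantham severity bands are a convention; only the
"radical" band is anchored in the source analyses.
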