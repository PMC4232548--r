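## Plant SNVs and indels into a synthetic genome, with truth tracking.

## alt allele implied by spectrum class and ref base
.class_alt <- list(
  "CG>AT" = c(C = "A", G = "T"),
  "CG>GC" = c(C = "G", G = "C"),
  "CG>TA" = c(C = "T", G = "A"),
  "TA>AT" = c(T = "A", A = "T"),
  "TA>CG" = c(T = "C", A = "G"),
  "TA>GC" = c(T = "G", A = "C"))

.class_ref_bases <- list(
  "CG>AT" = c("C", "G"), "CG>GC" = c("C", "G"), "CG>TA" = c("C", "G"),
  "TA>AT" = c("T", "A"), "TA>CG" = c("T", "A"), "TA>GC" = c("T", "A"))

## per-chromosome state shared across planting calls (position collision mask,
## base-position index, repeat-locus usage)
.plant_env <- function(genome) {
  env <- new.env(parent = emptyenv())
  env$used <- lapply(genome$sequences, function(s) logical(nchar(s)))
  env$pos_by_base <- lapply(genome$sequences, function(s) {
    split(seq_len(nchar(s)), strsplit(s, "", fixed = TRUE)[[1]])
  })
  env$repeat_used <- logical(if (is.null(genome$repeats)) 0 else
    nrow(genome$repeats))
  env
}

.in_tracts <- function(chrom, pos1, tracts) {
  ## pos1 is 1-based; tracts 0-based half-open
  if (!nrow(tracts)) return(rep(FALSE, length(pos1)))
  out <- rep(FALSE, length(pos1))
  for (i in seq_len(nrow(tracts))) {
    out <- out | (chrom == tracts$chrom[i] & pos1 > tracts$start[i] &
                    pos1 <= tracts$end[i])
  }
  out
}

.draw_zygosity <- function(chrom, pos1, config) {
  hom_forced <- .in_tracts(chrom, pos1, config$loh_tracts) |
    config$ploidy_map[chrom] == 1
  ifelse(hom_forced | runif(length(pos1)) >= config$het_fraction, "hom", "het")
}

## Plant one set of variants at `frac` of the configured rates.
## RNG state must already be set by the caller.
.plant_set <- function(genome, config, frac, env) {
  rows <- list()
  for (chrom in names(config$chromosome_lengths)) {
    seq <- genome$sequences[[chrom]]
    len <- nchar(seq)
    used <- env$used[[chrom]]

    ## --- SNVs ---
    n_snv <- round(config$snv_rate * len / 1000 * frac)
    if (n_snv > 0) {
      cls <- sample(SPECTRUM_CLASSES, n_snv, replace = TRUE,
                    prob = config$spectrum_weights)
      tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
      for (cl in SPECTRUM_CLASSES) {
        k <- tab[[cl]]
        if (k == 0) next
        cand <- unlist(env$pos_by_base[[chrom]][.class_ref_bases[[cl]]],
                       use.names = FALSE)
        cand <- cand[!used[cand]]
        if (length(cand) < k) {
          warning("not enough free positions for class ", cl, " on ", chrom)
          k <- length(cand)
        }
        pos <- resample(cand, k)
        used[pos] <- TRUE
        ref <- substring(seq, pos, pos)
        alt <- unname(.class_alt[[cl]][ref])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, ref = ref, alt = alt, type = "snv",
          class = cl, zygosity = .draw_zygosity(chrom, pos, config),
          at_repeat = FALSE, unit = "", stringsAsFactors = FALSE)
      }
    }

    ## --- indels ---
    n_ind <- round(config$indel_rate * len / 1000 * frac)
    n_rep <- round(n_ind * config$repeat_indel_fraction)
    n_free <- n_ind - n_rep

    if (n_rep > 0) {
      cand <- which(genome$repeats$chrom == chrom & !env$repeat_used &
                      genome$repeats$start >= 1)
      if (length(cand) < n_rep) {
        warning("repeat catalog exhausted on ", chrom, "; planting ",
                length(cand), " of ", n_rep, " repeat indels")
        n_rep <- length(cand)
      }
      pick <- if (n_rep > 0) resample(cand, n_rep) else integer(0)
      env$repeat_used[pick] <- TRUE
      for (j in pick) {
        s <- genome$repeats$start[j]          # 0-based run start
        u <- nchar(genome$repeats$unit[j])
        is_del <- runif(1) < 0.5
        if (is_del) {
          ref <- substr(seq, s, s + u)        # anchor + one unit
          alt <- substr(seq, s, s)
          type <- "del"
        } else {
          ref <- substr(seq, s, s)
          alt <- paste0(ref, genome$repeats$unit[j])
          type <- "ins"
        }
        span <- s:min(len, s + u)
        if (any(used[span])) next
        used[span] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = s, ref = ref, alt = alt, type = type,
          class = NA_character_,
          zygosity = .draw_zygosity(chrom, s, config),
          at_repeat = TRUE, unit = genome$repeats$unit[j],
          stringsAsFactors = FALSE)
      }
    }

    if (n_free > 0) {
      lens <- sample(seq_along(config$indel_length_weights), n_free,
                     replace = TRUE, prob = config$indel_length_weights)
      for (L in unique(lens)) {
        for (i in seq_len(sum(lens == L))) {
          is_del <- runif(1) < 0.5
          placed <- FALSE
          for (attempt in 1:50) {
            q <- sample.int(len - L - 2L, 1)   # 1-based anchor position
            if (any(used[q:(q + L)])) next
            if (is_del) {
              ref <- substr(seq, q, q + L)
              alt <- substr(seq, q, q)
              nv <- normalize_indel(seq, q, ref, alt)
              if (is_repeat_unit_deletion(seq, nv$pos, nv$seq)$at_repeat) next
            } else {
              ref <- substr(seq, q, q)
              ins <- paste(sample(BASES, L, replace = TRUE), collapse = "")
              alt <- paste0(ref, ins)
              nv <- normalize_indel(seq, q, ref, alt)
              if (is_tandem_duplication_insertion(seq, nv$pos, nv$seq)$at_repeat)
                next
            }
            used[q:(q + L)] <- TRUE
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = chrom, pos = q, ref = ref, alt = alt,
              type = if (is_del) "del" else "ins", class = NA_character_,
              zygosity = .draw_zygosity(chrom, q, config),
              at_repeat = FALSE, unit = "", stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!placed)
            warning("could not place a non-repeat indel of length ", L,
                    " on ", chrom, " after 50 tries; skipped")
        }
      }
    }
    env$used[[chrom]] <- used
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(match(out$chrom, names(config$chromosome_lengths)), out$pos), ,
      drop = FALSE]
}

.draw_qual_depth <- function(df) {
  ## quality and depth straddle the default filter thresholds (3x, Q30) so
  ## the filter stage is exercised non-trivially
  df$qual <- round(runif(nrow(df), 10, 60), 1)
  df$depth <- sample(1:60, nrow(df), replace = TRUE)
  df
}

#' Plant variants into a synthetic genome
#'
#' Draws SNVs multinomially over the configured six-class spectrum (the alt
#' allele follows from the class and the reference base), indels at planted
#' tandem repeats (a deletion removes exactly one unit, an insertion
#' duplicates one) and elsewhere (rejection-sampled so they do not fall in
#' repeat context), assigns het/hom genotypes (all-homozygous inside LOH
#' tracts and on ploidy-1 chromosomes) and per-record quality and depth.
#'
#' @param genome a [generate_reference()] result.
#' @param config simulation config; defaults to the one inside `genome`.
#' @param sample sample name recorded in the truth set.
#' @param seed RNG seed for this planting (defaults to `config$seed + 1`).
#' @return truth data.frame: sample, chrom, pos (1-based VCF), ref, alt, type
#'   (snv/ins/del), class, zygosity, at_repeat, unit, qual, depth.
#' @export
plant_variants <- function(genome, config = genome$config, sample = "S1",
                           seed = config$seed + 1L) {
  set.seed(seed)
  env <- .plant_env(genome)
  df <- .plant_set(genome, config, 1, env)
  if (is.null(df)) stop("no variants planted; raise the rates", call. = FALSE)
  df <- .draw_qual_depth(df)
  df$sample <- sample
  rownames(df) <- NULL
  df
}

#' Simulate a cohort of samples sharing one reference genome
#'
#' Plants a shared variant pool present in every sample plus disjoint
#' per-sample private sets, emulating a multi-sample resequencing comparison
#' (one cell-line-like sample and control breeds). Per-sample parameter
#' overrides (e.g. a higher `repeat_indel_fraction` in the test sample) apply
#' to the private set only. Quality and depth are drawn independently per
#' sample.
#'
#' @param genome a [generate_reference()] result.
#' @param samples character vector of sample names.
#' @param shared_fraction fraction of the configured rates planted as the
#'   pool shared by all samples.
#' @param overrides named list (by sample) of config fields to override for
#'   that sample's private variants.
#' @param seed RNG seed.
#' @return list with `samples` (named list of truth data.frames, each with an
#'   `origin` column "shared"/"private") and `private_keys` (data.frame of
#'   planted private variant keys with their sample).
#' @export
simulate_cohort <- function(genome, samples = c("DT40", "L2", "Silkie"),
                            shared_fraction = 0.6,
                            overrides = list(),
                            seed = genome$config$seed + 1L) {
  stopifnot(length(samples) >= 2)
  set.seed(seed)
  env <- .plant_env(genome)
  config <- genome$config
  shared <- .plant_set(genome, config, shared_fraction, env)
  if (!is.null(shared)) shared$origin <- "shared"
  priv <- list()
  for (s in samples) {
    cfg_s <- config
    if (!is.null(overrides[[s]])) {
      for (k in names(overrides[[s]])) cfg_s[[k]] <- overrides[[s]][[k]]
    }
    p <- .plant_set(genome, cfg_s, 1 - shared_fraction, env)
    if (!is.null(p)) p$origin <- "private"
    priv[[s]] <- p
  }
  out <- list()
  for (s in samples) {
    df <- rbind(shared, priv[[s]])
    df <- df[order(match(df$chrom, names(config$chromosome_lengths)), df$pos), ]
    df <- .draw_qual_depth(df)
    df$sample <- s
    rownames(df) <- NULL
    out[[s]] <- df
  }
  pk <- do.call(rbind, lapply(samples, function(s) {
    p <- priv[[s]]
    if (is.null(p)) return(NULL)
    data.frame(sample = s, chrom = p$chrom, pos = p$pos, ref = p$ref,
               alt = p$alt, stringsAsFactors = FALSE)
  }))
  list(samples = out, private_keys = pk)
}

#' Write a planted truth set as a VCF file
#'
#' Minimal VCF 4.2: QUAL column, GT and DP in the genotype field, contig
#' headers from the genome. Heterozygous variants are written as 0/1,
#' homozygous as 1/1.
#'
#' @param truth a truth data.frame from [plant_variants()] /
#'   [simulate_cohort()].
#' @param path output path.
#' @param genome optional `synthetic_genome`, for contig header lines.
#' @param sample_name VCF sample column name.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(truth, path, genome = NULL,
                              sample_name = truth$sample[1]) {
  hdr <- c("##fileformat=VCFv4.2", "##source=genomescan-synthetic")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$sequences), nchar(genome$sequences)))
  }
  hdr <- c(hdr,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name))
  gt <- ifelse(truth$zygosity == "hom", "1/1", "0/1")
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t.\tDP=%d\tGT:DP\t%s:%d",
                  truth$chrom, truth$pos, truth$ref, truth$alt, truth$qual,
                  truth$depth, gt, truth$depth)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a truth table as TSV
#' @param truth truth data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write_tsv_meta(truth, path, meta = list(coords = "pos is 1-based VCF"))
}

#' Read a truth table written by [write_truth_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_truth_tsv <- function(path) read_tsv_meta(path)
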