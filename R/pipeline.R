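## End-to-end orchestration: filter -> spectrum -> unique/shared -> LOH ->
## repeat indels -> coding -> CNV -> integrations, with per-stage TSV outputs
## whose headers record the exact parameters used.

.default_params <- function() {
  list(min_depth = 3, min_quality = 30,
       block_size = 100000, min_hom = 50, ratio_threshold = 0.1,
       baseline_chroms = NULL, test_sample = NULL,
       min_hit_len = 200, min_identity = 90,
       cluster_window = 1000, min_support = 3)
}

PIPELINE_STAGES <- c("filter", "spectrum", "unique", "loh", "repeat_indels",
                     "coding", "cnv", "integrations")

## variant keys with left-normalized indels, so representation differences
## cannot break cross-sample matching
.normalized_keyed <- function(records, reference) {
  records <- classify_variant(records)
  idx <- which(records$kind %in% c("insertion", "deletion") & records$in_range)
  for (i in idx) {
    nv <- normalize_indel(reference[[records$chrom[i]]], records$pos[i],
                          records$ref[i], records$alt[i])
    if (nv$pos >= 1) {
      records$pos[i] <- nv$pos
      records$ref[i] <- nv$ref
      records$alt[i] <- nv$alt
    }
  }
  records
}

#' Run the full characterization pipeline
#'
#' Executes the enabled stages in order over one or more samples and writes
#' every output table under `config$out_dir`, each with its stage parameters
#' in `#`-comment header lines. Outputs are byte-stable: two runs on the
#' same inputs and config produce identical files.
#'
#' @param config list with elements: `out_dir`; `samples` (named list, each
#'   with `$vcf`); `reference` (FASTA path); optional `genes` (GFF3),
#'   `coverage` (bedGraph-like TSV), `allele_depth` (TSV), `scaffolds`,
#'   `viral`, `pairs` (FASTA); `params` (see details; missing entries take
#'   defaults); `stages` (subset of filter, spectrum, unique, loh,
#'   repeat_indels, coding, cnv, integrations; default all).
#' @return invisible list with the per-stage in-memory results.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages
  if (is.null(stages)) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ","),
                        call. = FALSE)
  params <- utils::modifyList(.default_params(),
                              if (is.null(config$params)) list() else
                                config$params)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(field, stage) {
    if (is.null(config[[field]])) {
      stop(sprintf("stage '%s' needs config$%s", stage, field), call. = FALSE)
    }
    config[[field]]
  }
  if (is.null(config$samples) || !length(config$samples)) {
    stop("config$samples is required", call. = FALSE)
  }
  reference <- read_genome_fasta(need("reference", "all"))
  chrom_lengths <- setNames(nchar(reference), names(reference))
  res <- list()

  ## --- filter ---
  raw <- lapply(config$samples, function(s) read_vcf(s$vcf))
  if ("filter" %in% stages) {
    filt <- lapply(raw, filter_variants, min_depth = params$min_depth,
                   min_quality = params$min_quality)
    summ <- do.call(rbind, lapply(names(filt), function(s) {
      fs <- attr(filt[[s]], "filter_summary")
      data.frame(sample = s, kept = fs[["kept"]], dropped = fs[["dropped"]])
    }))
    write_tsv_meta(summ, file.path(out_dir, "filter_summary.tsv"),
                   meta = list(min_depth = params$min_depth,
                               min_quality = params$min_quality))
    res$filter <- filt
  } else {
    filt <- raw
  }
  recs <- lapply(filt, classify_variant)

  ## --- spectrum ---
  if ("spectrum" %in% stages) {
    spectra <- lapply(recs, function(r) {
      compute_spectrum(r[r$kind == "snv", c("ref", "alt")])
    })
    write_tsv_meta(spectrum_table(spectra),
                   file.path(out_dir, "spectrum_all.tsv"),
                   meta = list(stage = "spectrum"))
    zy <- do.call(rbind, lapply(names(recs), function(s) {
      z <- zygosity_counts(recs[[s]][recs[[s]]$kind != "snv" &
                                       recs[[s]]$in_range, ])
      data.frame(sample = s, hom = z$hom, het = z$het, hom_pct = z$hom_pct)
    }))
    write_tsv_meta(zy, file.path(out_dir, "indel_zygosity_all.tsv"),
                   meta = list(stage = "spectrum"))
    res$spectrum <- spectra
  }

  ## --- unique/shared partition ---
  if ("unique" %in% stages) {
    if (length(recs) < 2) stop("stage 'unique' needs >= 2 samples",
                               call. = FALSE)
    normed <- lapply(recs, .normalized_keyed, reference = reference)
    part <- partition_unique_shared(normed)
    res$unique <- part
    usumm <- do.call(rbind, lapply(names(part$unique), function(s) {
      u <- part$unique[[s]]
      n_snv <- sum(u$kind == "snv")
      n_ind <- sum(u$kind %in% c("insertion", "deletion") & u$in_range)
      z <- zygosity_counts(u[u$kind %in% c("insertion", "deletion") &
                               u$in_range, ])
      data.frame(sample = s, unique_snvs = n_snv, unique_indels = n_ind,
                 unique_indel_hom_pct = z$hom_pct,
                 indel_snv_ratio = if (n_snv > 0)
                   unique_indel_snv_ratio(n_ind, n_snv) else NA_real_)
    }))
    write_tsv_meta(usumm, file.path(out_dir, "unique_summary.tsv"),
                   meta = list(stage = "unique"))
    uspectra <- lapply(part$unique, function(u) {
      compute_spectrum(u[u$kind == "snv", c("ref", "alt")])
    })
    write_tsv_meta(spectrum_table(uspectra),
                   file.path(out_dir, "spectrum_unique.tsv"),
                   meta = list(stage = "unique"))
    res$unique_spectra <- uspectra
  }

  ## --- LOH scan ---
  if ("loh" %in% stages) {
    res$loh <- list()
    for (s in names(recs)) {
      blocks <- classify_blocks(
        block_counts(recs[[s]], chrom_lengths, params$block_size),
        min_hom = params$min_hom, ratio_threshold = params$ratio_threshold)
      regions <- merge_loh_regions(blocks)
      write_tsv_meta(blocks, file.path(out_dir, sprintf("loh_blocks_%s.tsv", s)),
                     meta = list(block_size = params$block_size,
                                 min_hom = params$min_hom,
                                 ratio_threshold = params$ratio_threshold))
      write_loh_bed(regions, file.path(out_dir,
                                       sprintf("loh_regions_%s.bed", s)))
      res$loh[[s]] <- list(blocks = blocks, regions = regions,
                           summary = loh_summary(blocks, regions,
                                                 params$block_size))
    }
  }

  ## --- repeat indels (on unique indels when available) ---
  if ("repeat_indels" %in% stages) {
    source_sets <- if (!is.null(res$unique)) res$unique$unique else recs
    curves <- list()
    for (s in names(source_sets)) {
      calls <- annotate_repeat_indels(source_sets[[s]], reference)
      del_curve <- repeat_fraction_curve(calls[calls$kind == "deletion", ], s)
      ins_curve <- repeat_fraction_curve(calls[calls$kind == "insertion", ], s)
      write_tsv_meta(rbind(cbind(del_curve, kind = "deletion"),
                           cbind(ins_curve, kind = "insertion")),
                     file.path(out_dir, sprintf("repeat_indels_%s.tsv", s)),
                     meta = list(error_model = "sqrt(k)/N"))
      curves[[s]] <- list(deletion = del_curve, insertion = ins_curve)
    }
    test_sample <- params$test_sample
    if (is.null(test_sample)) test_sample <- names(source_sets)[1]
    controls <- setdiff(names(source_sets), test_sample)
    if (length(controls)) {
      enr <- enrichment_curve(curves[[test_sample]]$deletion,
                              lapply(controls, function(s)
                                curves[[s]]$deletion))
      write_tsv_meta(enr, file.path(out_dir, "repeat_deletion_enrichment.tsv"),
                     meta = list(test = test_sample,
                                 controls = paste(controls, collapse = ",")))
      res$repeat_enrichment <- enr
    }
    res$repeat_curves <- curves
  }

  ## --- coding impact ---
  if ("coding" %in% stages) {
    genes <- read_gene_models_gff(need("genes", "coding"))
    res$coding <- list()
    for (s in names(recs)) {
      eff <- variant_effects(recs[[s]], genes, reference)
      write_tsv_meta(eff, file.path(out_dir, sprintf("coding_effects_%s.tsv", s)),
                     meta = list(stage = "coding"))
      ukeys <- if (!is.null(res$unique)) {
        u <- res$unique$unique[[s]]
        paste(u$chrom, u$pos, u$ref, u$alt, sep = ":")
      } else NULL
      agg <- aggregate_gene_hits(eff, unique_keys = ukeys)
      write_tsv_meta(agg$unique_hom_genes,
                     file.path(out_dir, sprintf("genes_unique_hom_%s.tsv", s)),
                     meta = list(stage = "coding"))
      write_tsv_meta(agg$heteroallelic_genes,
                     file.path(out_dir, sprintf("genes_heteroallelic_%s.tsv", s)),
                     meta = list(stage = "coding"))
      res$coding[[s]] <- list(effects = eff, genes = agg)
    }
  }

  ## --- coverage CNV ---
  if ("cnv" %in% stages) {
    track <- read_coverage_track(need("coverage", "cnv"))
    ad <- if (!is.null(config$allele_depth))
      read_allele_depth_tsv(config$allele_depth) else NULL
    baseline <- params$baseline_chroms
    if (is.null(baseline)) {
      cov0 <- chromosome_mean_coverage(track)
      baseline <- cov0$chrom[which.max(cov0$length)]
    }
    cn <- copy_number_table(track, ad, baseline)
    write_tsv_meta(cn, file.path(out_dir, "copy_number.tsv"),
                   meta = list(baseline = paste(baseline, collapse = ",")))
    res$cnv <- cn
  }

  ## --- viral integrations ---
  if ("integrations" %in% stages) {
    scaffolds <- read_genome_fasta(need("scaffolds", "integrations"))
    viral <- read_genome_fasta(need("viral", "integrations"))
    pairs <- if (!is.null(config$pairs)) read_read_pairs_fasta(config$pairs)
    else NULL
    det <- detect_integrations(scaffolds, viral, reference, pairs,
                               min_hit_len = params$min_hit_len,
                               min_identity = params$min_identity,
                               cluster_window = params$cluster_window,
                               min_support = params$min_support)
    write_tsv_meta(det$scaffold_classes,
                   file.path(out_dir, "scaffold_classes.tsv"),
                   meta = list(min_hit_len = params$min_hit_len,
                               min_identity = params$min_identity))
    write_tsv_meta(det$sites, file.path(out_dir, "integration_sites.tsv"),
                   meta = list(min_support = params$min_support,
                               cluster_window = params$cluster_window))
    res$integrations <- det
  }
  invisible(res)
}

#' Cross-sample comparison report
#'
#' Combines per-sample pipeline results into the comparison tables a
#' multi-sample study reports: six-class spectra side by side (all and
#' unique variants), indel zygosity, unique-indel/unique-SNV ratios and the
#' repeat-deletion enrichment of a designated test sample against the mean
#' of the controls.
#'
#' @param res result list from [run_pipeline()] (needs the spectrum, unique
#'   and repeat_indels stages).
#' @param test_sample name of the test sample.
#' @return list(spectrum_all, spectrum_unique, unique_summary, enrichment).
#' @export
compare_samples_report <- function(res, test_sample) {
  if (is.null(res$unique) || length(res$unique$unique) < 2) {
    stop("comparison needs >= 2 samples processed identically", call. = FALSE)
  }
  list(spectrum_all = spectrum_table(res$spectrum),
       spectrum_unique = spectrum_table(res$unique_spectra),
       enrichment = res$repeat_enrichment)
}
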