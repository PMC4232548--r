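#' Six strand-collapsed substitution classes, in fixed table order
#'
#' Each single-base substitution is merged with its reverse complement, giving
#' six classes. The fixed order makes all spectrum tables byte-stable.
#'
#' @export
SPECTRUM_CLASSES <- c("CG>AT", "CG>GC", "CG>TA", "TA>AT", "TA>CG", "TA>GC")

## substitution -> class lookup, built once
.subst_class_map <- local({
  m <- c(
    "C>A" = "CG>AT", "G>T" = "CG>AT",
    "C>G" = "CG>GC", "G>C" = "CG>GC",
    "C>T" = "CG>TA", "G>A" = "CG>TA",
    "T>A" = "TA>AT", "A>T" = "TA>AT",
    "T>C" = "TA>CG", "A>G" = "TA>CG",
    "T>G" = "TA>GC", "A>C" = "TA>GC")
  m
})

#' Collapse a substitution onto the six-class spectrum
#'
#' A substitution and its reverse complement map to the same class, e.g. both
#' C>T and G>A are `CG>TA`.
#'
#' @param ref_base,alt_base character vectors of single bases (A/C/G/T).
#' @return character vector of class labels (see [SPECTRUM_CLASSES]).
#' @export
collapse_substitution <- function(ref_base, alt_base) {
  ok <- ref_base %in% BASES & alt_base %in% BASES
  if (!all(ok)) {
    stop("non-ACGT base in substitution: ",
         paste(unique(paste0(ref_base[!ok], ">", alt_base[!ok])), collapse = ", "),
         call. = FALSE)
  }
  if (any(ref_base == alt_base)) {
    stop("ref and alt base identical; not a substitution", call. = FALSE)
  }
  unname(.subst_class_map[paste0(ref_base, ">", alt_base)])
}

#' Compute a six-class mutation spectrum
#'
#' Tallies SNV records into the six strand-collapsed substitution classes.
#' Percentages are rounded half-up to two decimals, matching conventional
#' table formatting; counts are never rounded.
#'
#' @param snv_records data.frame with columns `ref` and `alt` holding single
#'   bases, or a precomputed named count vector over [SPECTRUM_CLASSES].
#' @return object of class `mutation_spectrum`: list with `counts` (named
#'   integer), `total`, `percentages` (named numeric, two decimals) and
#'   `defined` (FALSE when total is zero, in which case percentages are NA).
#' @export
compute_spectrum <- function(snv_records) {
  if (is.numeric(snv_records) && !is.null(names(snv_records))) {
    if (!setequal(names(snv_records), SPECTRUM_CLASSES)) {
      stop("count vector must be named by the six spectrum classes", call. = FALSE)
    }
    counts <- snv_records[SPECTRUM_CLASSES]
  } else {
    stopifnot(is.data.frame(snv_records))
    if (nrow(snv_records)) {
      bad <- nchar(snv_records$ref) != 1L | nchar(snv_records$alt) != 1L
      if (any(bad)) stop("compute_spectrum expects SNV records only", call. = FALSE)
      cls <- collapse_substitution(snv_records$ref, snv_records$alt)
      counts <- table(factor(cls, levels = SPECTRUM_CLASSES))
      counts <- setNames(as.integer(counts), SPECTRUM_CLASSES)
    } else {
      counts <- setNames(integer(6), SPECTRUM_CLASSES)
    }
  }
  total <- sum(counts)
  defined <- total > 0
  pct <- if (defined) round_half_up(100 * counts / total, 2) else
    setNames(rep(NA_real_, 6), SPECTRUM_CLASSES)
  structure(list(counts = counts, total = total, percentages = pct,
                 defined = defined),
            class = "mutation_spectrum")
}

#' @method print mutation_spectrum
#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("Mutation spectrum (", x$total, " SNVs)\n", sep = "")
  df <- data.frame(class = SPECTRUM_CLASSES, count = as.integer(x$counts),
                   percent = x$percentages, row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cross-sample spectrum comparison table
#'
#' Lays out one or more spectra side by side: six class rows plus a total row,
#' with a count and a percentage column per sample.
#'
#' @param spectra named list of `mutation_spectrum` objects.
#' @return data.frame with columns `class`, then `<sample>_count`,
#'   `<sample>_pct` per sample.
#' @export
spectrum_table <- function(spectra) {
  stopifnot(length(spectra) >= 1, !is.null(names(spectra)))
  out <- data.frame(class = c(SPECTRUM_CLASSES, "Total"),
                    stringsAsFactors = FALSE)
  for (nm in names(spectra)) {
    sp <- spectra[[nm]]
    out[[paste0(nm, "_count")]] <- c(as.integer(sp$counts), sp$total)
    out[[paste0(nm, "_pct")]] <- c(sp$percentages,
                                   if (sp$defined) 100.00 else NA_real_)
  }
  out
}
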