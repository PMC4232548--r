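#' @import Biostrings
#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Decimal rounding where exact .5 cases go up, matching how percentages are
#' conventionally printed in variant-count tables (base `round()` rounds half
#' to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement without reversal, for single bases
comp_base <- function(x) chartr("ACGT", "TGCA", x)

## sample() without the scalar-x surprise
resample <- function(x, k) x[sample.int(length(x), k)]

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

## write a data.frame as TSV with "# key=value" provenance header lines;
## byte-stable (no timestamps)
write_tsv_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s=%s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
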