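DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' keeps plain character vectors as input and output.
#'
#' @param x character vector of DNA sequences over `A,C,G,T` (optionally `N`).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  n <- length(x)
  if (n == 0L) return(character(0))
  if (n <= 32L) {
    ## scalar/small case: complement via chartr, reverse via code points --
    ## much cheaper than an XStringSet round trip
    y <- chartr("ACGTN", "TGCAN", x)
    return(vapply(y, function(s) intToUtf8(base::rev(utf8ToInt(s))),
                  character(1), USE.NAMES = FALSE))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## all k-mers of a single string, as a character vector (1 per start position)
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(s, starts, starts + k - 1L)
}

## stopifnot with a nicer message
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_dna <- function(x) {
  all(grepl("^[ACGT]+$", x))
}

## split an allele name "02:01:01" into its colon fields
allele_fields <- function(name) strsplit(name, ":", fixed = TRUE)

## truncate an allele name to at most `n` colon-delimited fields
truncate_fields <- function(name, n) {
  vapply(allele_fields(name), function(f) {
    paste(f[seq_len(min(length(f), n))], collapse = ":")
  }, character(1))
}

## gene class from the symbol: class II genes start with "HLA-D" by HLA
## nomenclature convention; everything else is treated as class I.
gene_class <- function(gene) {
  ifelse(grepl("^HLA-D", gene), 2L, 1L)
}

#' Targeted exon indices for a gene
#'
#' Major (antigen-binding) exons are 2 and 3 for class I genes and 2 for
#' class II genes; the minor polymorphic exon is 4 (class I) or 3 (class II).
#'
#' @param gene gene symbol, e.g. `"HLA-A"` or `"HLA-DRB1"`.
#' @param which one of `"major"`, `"minor"`, `"all"`.
#' @return integer vector of exon indices.
#' @export
targeted_exons <- function(gene, which = c("all", "major", "minor")) {
  which <- match.arg(which)
  cls <- gene_class(gene)
  major <- if (cls == 1L) c(2L, 3L) else 2L
  minor <- if (cls == 1L) 4L else 3L
  switch(which, major = major, minor = minor, all = c(major, minor))
}
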