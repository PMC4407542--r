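## Block-swap phase fixtures shared by the typing and acceptance tests.

## mDB over one class II gene with a planted block-swap quartet:
## A = (b1, b2), B = (b1', b2'), C = (b1, b2'), D = (b1', b2), where the two
## polymorphic blocks are separated by an identical run of `gap` bases
block_swap_db <- function(gap, seed = 99) {
  set.seed(seed)
  left <- rand_dna(60)
  run <- rand_dna(gap)
  right <- rand_dna(60)
  b1 <- rand_dna(8); b1p <- sub_at(b1, c(2L, 5L))
  b2 <- rand_dna(8); b2p <- sub_at(b2, c(3L, 7L))
  ## identical exon 3 everywhere so only exon 2 separates the quartet
  ex3 <- rand_dna(250)
  mk <- function(name, x, y) {
    allele_record("HLA-DQB1", name,
      data.frame(kind = c("exon", "exon"), index = c(2L, 3L),
                 sequence = c(paste0(left, x, run, y, right), ex3)))
  }
  recs <- list(mk("01:01", b1, b2), mk("02:01", b1p, b2p),
               mk("03:01", b1, b2p), mk("04:01", b1p, b2))
  build_exact_dbs(recs)
}

## oracle: two allele pairs explain the same reads iff the multisets of all
## read-length substrings of their (major) exon sequences coincide
spectrum <- function(mdb, pair, L) {
  subs <- unlist(lapply(pair, function(lab) {
    unlist(lapply(mdb$entries[["HLA-DQB1"]][[lab]]$exons, function(e) {
      n <- nchar(e)
      if (n < L) e else substring(e, 1:(n - L + 1), L:n)
    }))
  }))
  sort(subs)
}

consistent_pairs_oracle <- function(mdb, designated, L) {
  labs <- names(mdb$entries[["HLA-DQB1"]])
  ref <- spectrum(mdb, designated, L)
  out <- list()
  for (i in seq_along(labs)) for (j in i:length(labs)) {
    p <- sort(c(labs[i], labs[j]))
    if (identical(spectrum(mdb, p, L), ref)) out[[length(out) + 1L]] <- p
  }
  unique(out)
}

phase_call <- function(mdb) {
  call <- hlatyper:::new_typing_call("HLA-DQB1")
  call$alleles <- c("HLA-DQB1*01:01", "HLA-DQB1*02:01")
  call$resolution <- stats::setNames(c("allele", "allele"), call$alleles)
  call
}

## four-digit-equivalent comparison of a reported call against a truth pair:
## returns the number of truth alleles (0..2) matched by the reported labels
four_digit_correct <- function(truth_pair, call) {
  two_fields <- function(x) {
    gene <- sub("\\*.*$", "", x)
    name <- sub("^.*\\*", "", x)
    paste0(gene, "*", vapply(strsplit(name, ":", fixed = TRUE), function(f)
      paste(f[seq_len(min(2L, length(f)))], collapse = ":"), character(1)))
  }
  if (call$no_call || length(call$alleles) == 0L) return(0L)
  got <- call$alleles
  if (length(got) == 1L) got <- rep(got, 2L)   # homozygous or lone designation
  got4 <- two_fields(got)
  n <- 0L
  for (t in two_fields(truth_pair)) {
    hit <- match(t, got4)
    if (!is.na(hit)) { n <- n + 1L; got4 <- got4[-hit] }
  }
  n
}
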