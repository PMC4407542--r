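## Shared fixture builders. Everything is generated in code; nothing is
## read from disk except files the tests themselves write to tempdirs.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## substitute specific positions of a DNA string with a different base
sub_at <- function(s, pos, base = NULL) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) {
    ch[p] <- if (is.null(base)) setdiff(c("A", "C", "G", "T"), ch[p])[1] else base
  }
  paste(ch, collapse = "")
}

## a minimal hand-built class I allele: introns around exons 2,3,4
toy_class1_record <- function(gene = "HLA-A", name = "01:01:01", seed = 1,
                              exon_len = 270, intron_len = 120) {
  set.seed(seed)
  segs <- data.frame(
    kind = c("intron", "exon", "intron", "exon", "intron", "exon", "intron"),
    index = c(1L, 2L, 2L, 3L, 3L, 4L, 4L),
    sequence = c(rand_dna(intron_len), rand_dna(exon_len), rand_dna(intron_len),
                 rand_dna(exon_len), rand_dna(intron_len), rand_dna(exon_len),
                 rand_dna(intron_len)),
    stringsAsFactors = FALSE)
  allele_record(gene, name, segs)
}

## derive a sibling allele from `rec` by substituting `n_subs` positions in
## each exon (deterministic given seed)
derive_allele <- function(rec, name, n_subs = 3, seed = 2, exons = NULL) {
  set.seed(seed)
  segs <- rec$segments
  for (i in which(segs$kind == "exon")) {
    if (!is.null(exons) && !(segs$index[i] %in% exons)) next
    pos <- sample.int(nchar(segs$sequence[i]), n_subs)
    segs$sequence[i] <- sub_at(segs$sequence[i], pos)
  }
  allele_record(rec$gene, name, segs)
}

## error-free reads tiling a region [from, to] of a sequence every `step` bp
tile_reads <- function(seqchr, from, to, read_len = 100, step = 20,
                       prefix = "r") {
  starts <- seq(from, to - read_len + 1, by = step)
  data.frame(id = sprintf("%s%03d", prefix, seq_along(starts)),
             sequence = substring(seqchr, starts, starts + read_len - 1),
             stringsAsFactors = FALSE)
}

## uniform random error-free reads over [from, to] to a target mean depth
depth_reads <- function(seqchr, from, to, depth, read_len = 100, seed = 1,
                        prefix = "d") {
  set.seed(seed)
  n <- round(depth * (to - from + 1) / read_len)
  starts <- sample(from:(to - read_len + 1), n, replace = TRUE)
  data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
             sequence = substring(seqchr, starts, starts + read_len - 1),
             stringsAsFactors = FALSE)
}

## full record sequence of an allele
record_seq <- function(rec) paste(rec$segments$sequence, collapse = "")

## a small two-gene mock reference shared by several test files (cheap to
## build; cached per session)
small_mock <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genes = c("HLA-A" = "I", "HLA-DQB1" = "II"),
                        competitors = c("HLA-E" = "HLA-A"),
                        alleles_per_gene = 10L, alleles_per_competitor = 4L,
                        seed = 42L)
      mock <- make_mock_alleles(cfg)
      ref <- build_reference(mock$records,
                             competitor_genes = names(cfg$competitors))
      cache <<- list(cfg = cfg, mock = mock, ref = ref)
    }
    cache
  }
})
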