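## Contig-to-allele matching, scoring, designation, G-resolution, phase.

## tiny hand-built mDB/aDB over one class I gene
toy_dbs <- function(seed = 90) {
  a1 <- toy_class1_record("HLA-A", "01:01:01", seed = seed)
  a2 <- a1; a2$name <- "01:01:02"      # same majors, distinct minor: G pair
  i4 <- which(a2$segments$index == 4L & a2$segments$kind == "exon")
  a2$segments$sequence[i4] <- sub_at(a2$segments$sequence[i4], c(30L, 60L))
  b <- derive_allele(a1, "03:01:01", n_subs = 5, seed = seed + 1)
  dbs <- build_exact_dbs(list(a1, a2, b))
  list(a1 = a1, a2 = a2, b = b, mdb = dbs$mdb, adb = dbs$adb)
}

as_contig <- function(seqchr, depth = 20, gene = "HLA-A") {
  list(gene = gene, sequence = seqchr, depth = rep(as.integer(depth), nchar(seqchr)),
       support = 10L, mean_depth = depth)
}
contig_set <- function(...) structure(list(...), class = "hla_contig_set")

exon_of <- function(rec, idx) {
  rec$segments$sequence[rec$segments$kind == "exon" & rec$segments$index == idx]
}

test_that("exact and flanked contigs match; one mismatch routes to unmatched", {
  d <- toy_dbs()
  ex2 <- exon_of(d$a1, 2L)
  flank <- function(n, s) rand_dna(n, seed = s)
  contigs <- contig_set(
    as_contig(ex2),                                            # exact
    as_contig(paste0(flank(30, 91), ex2, flank(30, 92))),      # 30 bp overhangs
    as_contig(sub_at(ex2, 100L)),                              # 1 mismatch
    as_contig(revcomp(ex2))                                    # minus strand
  )
  m <- match_contigs(contigs, d$mdb, "HLA-A")
  lab <- "HLA-A*01:01:01G"
  expect_equal(m$matches$exonic_fraction[m$matches$contig == 1L &
                                         m$matches$allele_label == lab &
                                         m$matches$exon == 2L], 1.0)
  expect_equal(m$matches$exonic_fraction[m$matches$contig == 2L &
                                         m$matches$allele_label == lab &
                                         m$matches$exon == 2L],
               nchar(ex2) / (nchar(ex2) + 60), tolerance = 1e-12)
  expect_true(3L %in% m$unmatched)                 # zero-tolerance rule
  expect_true(any(m$matches$contig == 4L & m$matches$strand == "-"))
})

test_that("contig overhang beyond the flank budget voids the match", {
  d <- toy_dbs()
  ex2 <- exon_of(d$a1, 2L)
  far <- contig_set(as_contig(paste0(rand_dna(80, seed = 93), ex2)))
  m <- match_contigs(far, d$mdb, "HLA-A", flank_len = 50L)
  expect_length(m$unmatched, 1L)
})

test_that("allele scores are contig length x depth x exonic fraction, summed", {
  d <- toy_dbs()
  ex2 <- exon_of(d$a1, 2L); ex3 <- exon_of(d$a1, 3L)
  c1 <- as_contig(substr(ex2, 1, 270), depth = 20)     # 270 x 20 x 1 = 5400
  c2 <- as_contig(ex3, depth = 10)
  contigs <- contig_set(c1, c2)
  m <- match_contigs(contigs, d$mdb, "HLA-A")
  sc <- score_alleles(m$matches, contigs)
  lab <- "HLA-A*01:01:01G"
  expect_equal(sc$total[sc$allele_label == lab], 5400 + nchar(ex3) * 10)
  ## brute-force oracle over the match table
  lens <- c(nchar(c1$sequence), nchar(c2$sequence))
  deps <- c(20, 10)
  oracle <- tapply(lens[m$matches$contig] * deps[m$matches$contig] *
                     m$matches$exonic_fraction,
                   m$matches$allele_label, sum)
  expect_equal(sc$total, unname(oracle[sc$allele_label]))
})

test_that("designation walks scores and needs an unassigned uniquely matched contig", {
  d <- toy_dbs()
  exA <- exon_of(d$a1, 2L); exA3 <- exon_of(d$a1, 3L)
  exB <- exon_of(d$b, 2L);  exB3 <- exon_of(d$b, 3L)
  contigs <- contig_set(as_contig(exA, 22), as_contig(exA3, 20),
                        as_contig(exB, 12), as_contig(exB3, 11))
  m <- match_contigs(contigs, d$mdb, "HLA-A")
  sc <- score_alleles(m$matches, contigs)
  call <- designate_alleles(sc, m$matches, gene = "HLA-A", db = d$mdb)
  expect_setequal(call$alleles, c("HLA-A*01:01:01G", "HLA-A*03:01:01"))
  expect_false(call$homozygous)
  expect_false(call$no_call)

  ## homozygote: a single candidate explains everything
  hom <- contig_set(as_contig(exA, 30), as_contig(exA3, 28))
  mh <- match_contigs(hom, d$mdb, "HLA-A")
  ch <- designate_alleles(score_alleles(mh$matches, hom), mh$matches,
                          gene = "HLA-A", db = d$mdb)
  expect_identical(ch$alleles, "HLA-A*01:01:01G")
  expect_true(ch$homozygous)

  ## a third candidate with its own unique contig is documented, not called
  d3 <- toy_dbs(seed = 95)
  crec <- derive_allele(d3$a1, "11:01:01", n_subs = 5, seed = 123)
  dbs3 <- build_exact_dbs(list(d3$a1, d3$a2, d3$b, crec))
  tri <- contig_set(as_contig(exon_of(d3$a1, 2L), 25),
                    as_contig(exon_of(d3$b, 2L), 20),
                    as_contig(exon_of(crec, 2L), 15))
  mt <- match_contigs(tri, dbs3$mdb, "HLA-A")
  ct <- designate_alleles(score_alleles(mt$matches, tri), mt$matches,
                          gene = "HLA-A", db = dbs3$mdb)
  expect_length(ct$alleles, 2L)
  expect_true("HLA-A*11:01:01" %in% names(ct$extra_alleles))
})

test_that("no-call is reported when no candidate owns a unique contig", {
  d <- toy_dbs()
  sc <- score_alleles(data.frame(), contig_set())
  call <- designate_alleles(sc, data.frame(contig = integer(0)), gene = "HLA-A")
  expect_true(call$no_call)
})

test_that("minor-exon evidence upgrades a G-group to six digits", {
  d <- toy_dbs()
  ex2 <- exon_of(d$a1, 2L); ex3 <- exon_of(d$a1, 3L)
  minor1 <- exon_of(d$a1, 4L)   # member 01:01:01's exon 4
  contigs <- contig_set(as_contig(ex2, 20), as_contig(ex3, 20),
                        as_contig(minor1, 15))
  m <- match_contigs(contigs, d$mdb, "HLA-A")
  call <- designate_alleles(score_alleles(m$matches, contigs), m$matches,
                            gene = "HLA-A", db = d$mdb)
  expect_identical(call$alleles, "HLA-A*01:01:01G")
  res <- resolve_minor_exons(call, contigs, d$adb)
  expect_identical(res$alleles, "HLA-A*01:01:01")
  expect_identical(unname(res$resolution["HLA-A*01:01:01"]), "six-digit")

  ## no minor-exon contig: the G label stands
  nom <- contig_set(as_contig(ex2, 20), as_contig(ex3, 20))
  m2 <- match_contigs(nom, d$mdb, "HLA-A")
  c2 <- designate_alleles(score_alleles(m2$matches, nom), m2$matches,
                          gene = "HLA-A", db = d$mdb)
  expect_identical(resolve_minor_exons(c2, nom, d$adb)$alleles, "HLA-A*01:01:01G")

  ## a mutated minor-exon contig matches no member: label kept
  mut <- contig_set(as_contig(ex2, 20), as_contig(ex3, 20),
                    as_contig(sub_at(minor1, c(30L, 60L, 90L)), 15))
  m3 <- match_contigs(mut, d$mdb, "HLA-A")
  c3 <- designate_alleles(score_alleles(m3$matches, mut), m3$matches,
                          gene = "HLA-A", db = d$mdb)
  expect_identical(resolve_minor_exons(c3, mut, d$adb)$alleles, "HLA-A*01:01:01G")
})

test_that("members identical on the minor exon leave the label unchanged", {
  a1 <- toy_class1_record("HLA-A", "02:02:01", seed = 97)
  a2 <- a1; a2$name <- "02:02:02"      # identical everywhere: same G, same minor
  b <- derive_allele(a1, "09:01:01", n_subs = 5, seed = 98)
  dbs <- build_exact_dbs(list(a1, a2, b))
  ex2 <- exon_of(a1, 2L); ex3 <- exon_of(a1, 3L); ex4 <- exon_of(a1, 4L)
  contigs <- contig_set(as_contig(ex2, 20), as_contig(ex3, 20), as_contig(ex4, 15))
  m <- match_contigs(contigs, dbs$mdb, "HLA-A")
  call <- designate_alleles(score_alleles(m$matches, contigs), m$matches,
                            gene = "HLA-A", db = dbs$mdb)
  res <- resolve_minor_exons(call, contigs, dbs$adb)
  expect_identical(res$alleles, "HLA-A*02:02:01G")  # nothing to discriminate
})

test_that("frequency tie-breaking ranks by sum, then max, then label", {
  pairs <- list(c("A*01", "A*02"), c("A*03", "A*04"), c("A*05", "A*06"))
  ## binary-exact frequencies so the equal-sum tie is an exact tie
  freq <- c("A*01" = 0.25, "A*02" = 0.25, "A*03" = 0.001, "A*04" = 0,
            "A*05" = 0.375, "A*06" = 0.125)
  expect_identical(break_ties_by_frequency(pairs[1:2], freq), pairs[[1L]])
  ## equal sums decided by the larger single member
  expect_identical(break_ties_by_frequency(pairs[c(1, 3)], freq), pairs[[3L]])
  ## a single pair is returned unchanged
  expect_identical(break_ties_by_frequency(pairs[2], freq), pairs[[2L]])
  ## unknown frequencies count as zero; ties fall back to label order
  expect_identical(break_ties_by_frequency(list(c("B*02", "B*09"), c("B*01", "B*10"))),
                   c("B*01", "B*10"))
})

## ---- phase ambiguity (fixtures in helper-phase.R) ------------------------

test_that("blocks separated by a run longer than the read length are ambiguous", {
  dbs <- block_swap_db(gap = 150)
  call <- detect_phase_ambiguity(phase_call(dbs$mdb), dbs$mdb, read_length = 100)
  expect_true(call$phase_ambiguous)
  known <- Filter(function(p) !any(p == "unknown"), call$phase_pairs)
  oracle <- consistent_pairs_oracle(dbs$mdb, c("HLA-DQB1*01:01", "HLA-DQB1*02:01"),
                                    L = 100)
  expect_setequal(vapply(known, paste, character(1), collapse = "/"),
                  vapply(oracle, paste, character(1), collapse = "/"))
  expect_length(known, 2L)       # (01,02) and the recombinant (03,04)
})

test_that("variants within read reach are never phase-ambiguous", {
  dbs <- block_swap_db(gap = 30)
  call <- detect_phase_ambiguity(phase_call(dbs$mdb), dbs$mdb, read_length = 100)
  expect_false(call$phase_ambiguous)
  oracle <- consistent_pairs_oracle(dbs$mdb, c("HLA-DQB1*01:01", "HLA-DQB1*02:01"),
                                    L = 100)
  expect_length(oracle, 1L)
})

test_that("the reported pair among phase alternatives is the most frequent", {
  dbs <- block_swap_db(gap = 150)
  freq <- c("HLA-DQB1*01:01" = 0.01, "HLA-DQB1*02:01" = 0.01,
            "HLA-DQB1*03:01" = 0.20, "HLA-DQB1*04:01" = 0.20)
  call <- detect_phase_ambiguity(phase_call(dbs$mdb), dbs$mdb, read_length = 100,
                                 freq = freq)
  expect_true(call$phase_ambiguous)
  expect_setequal(call$alleles, c("HLA-DQB1*03:01", "HLA-DQB1*04:01"))
})
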