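test_that("segmented-FASTA dialect round-trips through writer and parser", {
  recs <- list(
    toy_class1_record("HLA-A", "01:01:01", seed = 1),
    toy_class1_record("HLA-A", "02:01:01", seed = 2),
    allele_record("HLA-DQB1", "05:02",
                  data.frame(kind = "exon", index = 2L,
                             sequence = rand_dna(260, seed = 3)))
  )
  path <- tempfile(fileext = ".fasta")
  write_allele_set(recs, path)
  back <- read_allele_set(path)
  expect_length(back, 3L)
  expect_identical(vapply(back, function(r) r$name, character(1)),
                   c("01:01:01", "02:01:01", "05:02"))
  ## the exon-only record keeps a single segment, introns absent
  dq <- back[[3L]]
  expect_identical(dq$segments$kind, "exon")
  expect_identical(dq$segments$sequence, recs[[3L]]$segments$sequence)
  ## full structural round trip
  for (i in 1:2) expect_identical(back[[i]]$segments, recs[[i]]$segments)
})

test_that("annotated whole-allele dialect is parsed via its sidecar TSV", {
  rec <- toy_class1_record("HLA-B", "07:02:01", seed = 4)
  full <- record_seq(rec)
  fa <- tempfile(fileext = ".fasta")
  x <- Biostrings::DNAStringSet(full)
  names(x) <- "HLA-B*07:02:01"
  Biostrings::writeXStringSet(x, fa)
  ends <- cumsum(nchar(rec$segments$sequence))
  starts0 <- ends - nchar(rec$segments$sequence)       # 0-based half-open
  ann <- data.frame(allele = "HLA-B*07:02:01", gene = "HLA-B",
                    segment = paste0(rec$segments$kind, rec$segments$index),
                    start = starts0, end = ends)
  tsv <- paste0(fa, ".segments.tsv")
  write.table(ann, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_allele_set(fa)                          # sidecar auto-detected
  expect_length(back, 1L)
  expect_identical(back[[1L]]$segments, rec$segments)
})

test_that("parser rejects malformed and duplicate records, accepts empty input", {
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_length(read_allele_set(empty), 0L)

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">HLA-A*01:01:01", "ACGT"), bad)        # no segment tag
  expect_error(read_allele_set(bad), "malformed")

  ## the same allele listed twice with the same segment collides on the
  ## exon-index invariant; duplicate names across builders are integrity
  ## errors
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">HLA-A*01:01|exon2", "ACGTACGTACGTACGT",
               ">HLA-A*01:01|exon2", "ACGTACGTACGTACGT"), dup)
  expect_error(read_allele_set(dup), "strictly increasing")

  rec <- toy_class1_record("HLA-A", "01:01:01", seed = 200)
  expect_error(build_exact_dbs(list(rec, rec)), "duplicate")
  expect_error(build_crp(list(rec, rec), target_genes = "HLA-A"), "duplicate")
})

test_that("panel entries have flanked-exon geometry and recover the exon", {
  rec <- allele_record("HLA-A", "01:01",
    data.frame(kind = c("intron", "exon", "intron"),
               index = c(1L, 2L, 2L),
               sequence = c(rand_dna(100, seed = 5), rand_dna(270, seed = 6),
                            rand_dna(100, seed = 7))))
  crp <- build_crp(list(rec), target_genes = "HLA-A", flank_len = 50L)
  e2 <- crp[crp$exon == 2L, ]
  expect_equal(nchar(e2$sequence), 370L)
  expect_equal(c(e2$exon_start, e2$exon_end), c(51L, 320L))
  expect_identical(substr(e2$sequence, e2$exon_start, e2$exon_end),
                   rec$segments$sequence[2L])

  ## flank_len = 0: the entry is exactly the exon
  crp0 <- build_crp(list(rec), target_genes = "HLA-A", flank_len = 0L)
  expect_identical(crp0$sequence[crp0$exon == 2L], rec$segments$sequence[2L])
})

test_that("alleles without introns borrow flanks from a same-gene sibling", {
  donor <- toy_class1_record("HLA-A", "01:01:01", seed = 8)
  orphan_segs <- donor$segments[donor$segments$kind == "exon", , drop = FALSE]
  orphan_segs$sequence[1L] <- sub_at(orphan_segs$sequence[1L], 5L)
  orphan <- allele_record("HLA-A", "02:01:01", orphan_segs)
  crp <- build_crp(list(orphan, donor), target_genes = "HLA-A", flank_len = 50L)
  d2 <- crp[crp$exon == 2L & crp$source_allele == "HLA-A*01:01:01", ]
  o2 <- crp[crp$exon == 2L & crp$source_allele == "HLA-A*02:01:01", ]
  ## the orphan's flanks equal the donor's intron ends
  expect_identical(substr(o2$sequence, 1L, 50L), substr(d2$sequence, 1L, 50L))
  expect_identical(substr(o2$sequence, o2$exon_end + 1L, nchar(o2$sequence)),
                   substr(d2$sequence, d2$exon_end + 1L, nchar(d2$sequence)))
  ## and stripping flanks still recovers the orphan's own exon
  expect_identical(substr(o2$sequence, o2$exon_start, o2$exon_end),
                   orphan_segs$sequence[1L])
})

test_that("gene with no introns at all yields zero-length flanks with a warning", {
  rec <- allele_record("HLA-A", "01:01",
    data.frame(kind = "exon", index = 2L, sequence = rand_dna(270, seed = 9)))
  expect_warning(crp <- build_crp(list(rec), target_genes = "HLA-A"),
                 "zero-length flanks")
  expect_identical(crp$sequence[crp$exon == 2L], rec$segments$sequence)
})

test_that("alleles sharing all major exons collapse into a G-group", {
  a1 <- toy_class1_record("HLA-A", "03:03:02", seed = 10)
  a2 <- a1; a2$name <- "03:03:04"
  ## same exons 2 and 3, different exon 4 (minor)
  i4 <- which(a2$segments$kind == "exon" & a2$segments$index == 4L)
  a2$segments$sequence[i4] <- sub_at(a2$segments$sequence[i4], c(10L, 20L))
  a3 <- derive_allele(a1, "24:02:01", n_subs = 4, seed = 11)
  dbs <- build_exact_dbs(list(a1, a2, a3))
  labs <- names(dbs$mdb$entries[["HLA-A"]])
  expect_setequal(labs, c("HLA-A*03:03:02G", "HLA-A*24:02:01"))
  expect_setequal(dbs$mdb$g_members[["HLA-A*03:03:02G"]],
                  c("HLA-A*03:03:02", "HLA-A*03:03:04"))
  ## aDB carries the minor exons of the members (distinct sequences)
  expect_false(identical(
    dbs$adb$entries[["HLA-A"]][["HLA-A*03:03:02"]]$exons[["4"]],
    dbs$adb$entries[["HLA-A"]][["HLA-A*03:03:04"]]$exons[["4"]]))
})

test_that("pairwise-distinct alleles produce no G-groups; class II groups on exon 2", {
  base <- toy_class1_record("HLA-A", "00:00", seed = 12)
  recs <- lapply(1:4, function(i) {
    r <- base
    r$name <- sprintf("%02d:01", i)
    for (j in which(r$segments$kind == "exon")) {
      ## deterministic, allele-specific substitution positions
      r$segments$sequence[j] <- sub_at(r$segments$sequence[j],
                                       c(10L + 3L * i, 100L + 5L * i))
    }
    r
  })
  dbs <- build_exact_dbs(recs)
  expect_length(dbs$mdb$g_members, 0L)

  ## class II: identity on exon 2 alone groups, exon 3 goes to the aDB
  base <- allele_record("HLA-DRB1", "12:01:01",
    data.frame(kind = c("exon", "exon"), index = c(2L, 3L),
               sequence = c(rand_dna(270, seed = 30), rand_dna(250, seed = 31))))
  twin <- base; twin$name <- "12:10"
  i3 <- which(twin$segments$index == 3L)
  twin$segments$sequence[i3] <- sub_at(twin$segments$sequence[i3], 7L)
  other <- derive_allele(base, "15:01", n_subs = 3, seed = 32, exons = 2L)
  dbs2 <- build_exact_dbs(list(base, twin, other))
  expect_length(dbs2$mdb$entries[["HLA-DRB1"]], 2L)
  expect_setequal(dbs2$mdb$g_members[["HLA-DRB1*12:01:01G"]],
                  c("HLA-DRB1*12:01:01", "HLA-DRB1*12:10"))
  expect_length(dbs2$adb$entries[["HLA-DRB1"]], 3L)
})

test_that("every allele belongs to exactly one mDB label and build is order-independent", {
  sm <- small_mock()
  recs <- sm$mock$records
  dbs <- build_exact_dbs(recs)
  all_names <- vapply(recs, function(r) paste0(r$gene, "*", r$name), character(1))
  covered <- unlist(lapply(names(dbs$mdb$entries), function(g) {
    unlist(lapply(names(dbs$mdb$entries[[g]]), label_members, db = dbs$mdb))
  }))
  expect_setequal(covered, all_names)
  expect_equal(anyDuplicated(covered), 0L)

  set.seed(99)
  shuffled <- recs[sample(seq_along(recs))]
  dbs2 <- build_exact_dbs(shuffled)
  expect_identical(dbs$mdb$entries, dbs2$mdb$entries)
  expect_identical(dbs$mdb$g_members, dbs2$mdb$g_members)
  expect_identical(dbs$adb$entries, dbs2$adb$entries)

  crp1 <- build_crp(recs, target_genes = unique(vapply(recs, `[[`, character(1), "gene")))
  crp2 <- build_crp(shuffled, target_genes = unique(vapply(recs, `[[`, character(1), "gene")))
  expect_identical(as.data.frame(crp1), as.data.frame(crp2))
})

test_that("frequency table reader attaches frequencies and db JSON serializes", {
  recs <- list(toy_class1_record("HLA-A", "01:01:01", seed = 40))
  ft <- tempfile(fileext = ".tsv")
  write_frequency_table(c("HLA-A*01:01:01" = 0.25), ft)
  freq <- read_frequency_table(ft)
  expect_equal(unname(freq["HLA-A*01:01:01"]), 0.25)
  fa <- tempfile(fileext = ".fasta")
  write_allele_set(recs, fa)
  back <- read_allele_set(fa, frequencies = ft)
  expect_equal(back[[1L]]$frequency, 0.25)

  dbs <- build_exact_dbs(recs)
  js <- tempfile(fileext = ".json")
  write_db_json(dbs$mdb, js)
  parsed <- jsonlite::read_json(js)
  expect_identical(parsed$tier, "major")
})
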