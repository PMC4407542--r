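## Mock database generator and read simulator.

test_that("planted G-groups surface in the built databases", {
  cfg <- sim_config(genes = c("HLA-A" = "I"), competitors = character(0),
                    alleles_per_gene = 4L, g_group_fraction = 0.5, seed = 120)
  mock <- make_mock_alleles(cfg)
  dbs <- build_exact_dbs(mock$records)
  expect_length(dbs$mdb$g_members, 1L)
  expect_length(dbs$mdb$g_members[[1L]], 2L)
  expect_identical(sort(unlist(mock$g_groups[["HLA-A"]])),
                   sort(dbs$mdb$g_members[[1L]]))
})

test_that("an infeasible configuration is rejected", {
  expect_error(sim_config(alleles_per_gene = 1L, g_group_fraction = 0.5),
               "at least 2 alleles")
  expect_error(sim_config(allelic_balance = 0), "allelic_balance")
  expect_error(sim_config(error_rate = 1), "error_rate")
})

test_that("generation is byte-identical under the same seed", {
  cfg <- sim_config(genes = c("HLA-A" = "I", "HLA-DQB1" = "II"),
                    competitors = character(0), alleles_per_gene = 6L, seed = 121)
  m1 <- make_mock_alleles(cfg)
  m2 <- make_mock_alleles(cfg)
  expect_identical(m1$records, m2$records)
  expect_identical(m1$frequencies, m2$frequencies)
  s1 <- simulate_reads(m1$genome_records, cfg, freq = m1$frequencies, seed = 7)
  s2 <- simulate_reads(m2$genome_records, cfg, freq = m2$frequencies, seed = 7)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("the truth table is complete and reads trace to their source", {
  sm <- small_mock()
  sim <- simulate_reads(sm$mock$genome_records, sm$cfg,
                        freq = sm$mock$frequencies, seed = 122)
  expect_equal(anyDuplicated(sim$truth$id), 0L)
  expect_setequal(sim$reads$id, sim$truth$id)
  names_full <- vapply(sm$mock$genome_records,
                       function(r) paste0(r$gene, "*", r$name), character(1))
  ## with zero error rate every read is an exact substring of its source
  cfg0 <- sm$cfg; cfg0$error_rate <- 0
  sim0 <- simulate_reads(sm$mock$genome_records, cfg0,
                         freq = sm$mock$frequencies, seed = 123)
  for (i in sample(nrow(sim0$reads), 50)) {
    src <- sm$mock$genome_records[[which(names_full == sim0$truth$allele[i])]]
    full <- record_seq(src)
    s <- sim0$reads$sequence[i]
    expect_true(grepl(s, full, fixed = TRUE) || grepl(revcomp(s), full, fixed = TRUE))
  }
  expect_true(all(sim0$truth$n_errors == 0L))
  expect_true(any(sim$truth$n_errors > 0L))
})

test_that("realized mean exon depth lands within 15% of the target", {
  cfg <- sim_config(genes = c("HLA-A" = "I", "HLA-DQB1" = "II"),
                    competitors = character(0), alleles_per_gene = 6L,
                    coverage = 40, seed = 124)
  mock <- make_mock_alleles(cfg)
  sim <- simulate_reads(mock$genome_records, cfg, freq = mock$frequencies,
                        seed = 125)
  names_full <- vapply(mock$genome_records,
                       function(r) paste0(r$gene, "*", r$name), character(1))
  for (g in names(sim$genotype)) {
    rec <- mock$genome_records[[which(names_full == sim$genotype[[g]][1L])]]
    ends <- cumsum(nchar(rec$segments$sequence))
    starts <- ends - nchar(rec$segments$sequence) + 1L
    i2 <- which(rec$segments$kind == "exon" & rec$segments$index == 2L)
    tr <- sim$truth[sim$truth$gene == g, ]
    ## mean raw depth over all exon-2 positions (both alleles' reads land on
    ## homologous coordinates; exon length >= 200 bp)
    pos <- starts[i2]:ends[i2]
    depth <- vapply(pos, function(p)
      sum(tr$start <= p & p <= tr$start + cfg$read_length - 1L), integer(1))
    expect_gt(mean(depth), cfg$coverage * 0.85)
    expect_lt(mean(depth), cfg$coverage * 1.15)
  }
})

test_that("paralog divergence controls the ambiguous-read exclusion rate", {
  run_amb <- function(divergence) {
    cfg <- sim_config(genes = c("HLA-A" = "I"), competitors = c("HLA-E" = "HLA-A"),
                      alleles_per_gene = 4L, alleles_per_competitor = 2L,
                      paralog_divergence = divergence, g_group_fraction = 0,
                      allele_divergence = 0.004, error_rate = 0, seed = 126)
    mock <- make_mock_alleles(cfg)
    ref <- build_reference(mock$records, competitor_genes = "HLA-E")
    sim <- simulate_reads(mock$genome_records, cfg, freq = mock$frequencies,
                          seed = 127)
    cls <- classify_reads(sim$reads, ref$index)
    cls$stats[["ambiguous"]] / cls$stats[["total"]]
  }
  ## at zero divergence the only target-vs-competitor differences are the
  ## alleles' own sparse substitutions, so reads from the shared stretches
  ## match both genes perfectly and are excluded in large numbers; at the
  ## realistic 6% divergence almost nothing is
  expect_gt(run_amb(0), 0.3)
  expect_lt(run_amb(0.06), 0.05)
})

test_that("WGS mode spreads reads over introns, WES confines them to exons", {
  cfgw <- sim_config(genes = c("HLA-A" = "I"), competitors = character(0),
                     alleles_per_gene = 4L, mode = "wgs", seed = 128)
  mock <- make_mock_alleles(cfgw)
  simw <- simulate_reads(mock$genome_records, cfgw, freq = mock$frequencies,
                         seed = 129)
  cfge <- cfgw; cfge$mode <- "wes"
  sime <- simulate_reads(mock$genome_records, cfge, freq = mock$frequencies,
                         seed = 129, genotype = simw$genotype)
  names_full <- vapply(mock$genome_records,
                       function(r) paste0(r$gene, "*", r$name), character(1))
  rec <- mock$genome_records[[which(names_full == simw$genotype[[1]][1L])]]
  ends <- cumsum(nchar(rec$segments$sequence))
  starts <- ends - nchar(rec$segments$sequence) + 1L
  i2 <- which(rec$segments$kind == "exon" & rec$segments$index == 2L)
  lo <- starts[i2] - cfgw$capture_flank - cfgw$read_length
  ## WES reads never start deeper than flank+readlength before exon 2 unless
  ## they belong to another exon's window
  exon_windows <- cbind(pmax(1L, starts[rec$segments$kind == "exon"] -
                               cfgw$capture_flank),
                        ends[rec$segments$kind == "exon"] + cfgw$capture_flank)
  in_window <- function(st) {
    any(st >= exon_windows[, 1L] & st + cfgw$read_length - 1L <= exon_windows[, 2L])
  }
  tre <- sime$truth[sime$truth$allele == names_full[which(names_full == simw$genotype[[1]][1L])], ]
  expect_true(all(vapply(tre$start, in_window, logical(1))))
  trw <- simw$truth[simw$truth$allele == simw$genotype[[1]][1L], ]
  expect_false(all(vapply(trw$start, in_window, logical(1))))
})

test_that("the database view drops introns for some alleles, the genome never does", {
  sm <- small_mock()
  has_intron <- function(r) any(r$segments$kind == "intron")
  db_intronless <- sum(!vapply(sm$mock$records, has_intron, logical(1)))
  expect_gt(db_intronless, 0L)
  expect_true(all(vapply(sm$mock$genome_records, has_intron, logical(1))))
  ## exon content agrees between the two views
  for (i in seq_along(sm$mock$records)) {
    a <- sm$mock$records[[i]]$segments
    b <- sm$mock$genome_records[[i]]$segments
    expect_identical(a$sequence[a$kind == "exon"], b$sequence[b$kind == "exon"])
  }
})
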