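## Fixture generator: mock allele databases with controlled structure
## (G-groups sharing major exons, paralogous competitor genes, dense exon
## polymorphism as in real HLA) and a WES/WGS read simulator with
## configurable coverage, allelic balance, read length and per-base
## substitution error.

#' Simulation configuration
#'
#' Defaults emulate the targeted-capture sequencing regime the typing
#' pipeline is designed for: 100 bp reads, 40-fold combined coverage of the
#' targeted exons, balanced alleles, 0.5% per-base substitution error.
#'
#' @param genes named character vector of target genes mapped to class
#'   (`"I"`/`"II"`); defaults to three class I and three class II loci.
#' @param competitors named character vector: competitor gene -> the target
#'   gene it is paralogous to.
#' @param alleles_per_gene alleles per target gene (default 24).
#' @param alleles_per_competitor alleles per competitor gene (default 8).
#' @param g_group_fraction fraction of a gene's alleles planted inside
#'   G-groups (pairs sharing all major exons, distinct minor exons).
#' @param paralog_divergence per-base substitution rate between a competitor
#'   and its paralog target (default 0.06).
#' @param allele_divergence per-base substitution rate of each allele's
#'   exons relative to the gene consensus (default 0.02; at least one
#'   substitution per exon is forced, matching the hyperpolymorphism of the
#'   HLA antigen-binding exons).
#' @param exon_len_range exon length range in bp (default 250-300).
#' @param intron_len intron length in bp (default 150).
#' @param intronless_fraction fraction of alleles stored without intron
#'   sequence (their panel flanks are borrowed from a same-gene allele).
#' @param coverage target combined (both alleles) depth at region-interior
#'   positions (default 40, comfortably above the method's 30-fold
#'   on-target recommendation; positions within a read length of a region
#'   edge receive proportionally less).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param allelic_balance fraction of reads drawn from the first allele.
#' @param paired emit `/1`,`/2` mate ids (mates are still classified
#'   independently).
#' @param mode `"wes"` (reads confined to exons +/- `capture_flank`) or
#'   `"wgs"` (reads uniform over the whole allele record).
#' @param capture_flank capture margin around exons in WES mode (default 50).
#' @param sample_genotype optional named list gene -> character(2) of full
#'   allele names; when `NULL`, [simulate_reads()] draws a genotype from the
#'   population frequencies.
#' @param seed integer seed; all generation is deterministic given the seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genes = c("HLA-A" = "I", "HLA-B" = "I", "HLA-C" = "I",
                                 "HLA-DRB1" = "II", "HLA-DQB1" = "II",
                                 "HLA-DQA1" = "II"),
                       competitors = c("HLA-E" = "HLA-A", "HLA-DOB" = "HLA-DQB1"),
                       alleles_per_gene = 24L,
                       alleles_per_competitor = 8L,
                       g_group_fraction = 0.25,
                       paralog_divergence = 0.06,
                       allele_divergence = 0.02,
                       exon_len_range = c(250L, 300L),
                       intron_len = 150L,
                       intronless_fraction = 0.2,
                       coverage = 40,
                       read_length = 100L,
                       error_rate = 0.005,
                       allelic_balance = 0.5,
                       paired = FALSE,
                       mode = c("wes", "wgs"),
                       capture_flank = 50L,
                       sample_genotype = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  assert_that(coverage > 0, "coverage must be > 0")
  assert_that(error_rate >= 0 && error_rate < 1, "error_rate must be in [0,1)")
  assert_that(allelic_balance > 0 && allelic_balance < 1,
              "allelic_balance must be in (0,1)")
  assert_that(alleles_per_gene >= 1L, "alleles_per_gene must be >= 1")
  if (g_group_fraction > 0 && alleles_per_gene < 2L) {
    stop("g_group_fraction > 0 requires at least 2 alleles per gene", call. = FALSE)
  }
  assert_that(all(competitors %in% names(genes)),
              "each competitor must name a target gene it is paralogous to")
  structure(list(genes = genes, competitors = competitors,
                 alleles_per_gene = as.integer(alleles_per_gene),
                 alleles_per_competitor = as.integer(alleles_per_competitor),
                 g_group_fraction = g_group_fraction,
                 paralog_divergence = paralog_divergence,
                 allele_divergence = allele_divergence,
                 exon_len_range = as.integer(exon_len_range),
                 intron_len = as.integer(intron_len),
                 intronless_fraction = intronless_fraction,
                 coverage = coverage, read_length = as.integer(read_length),
                 error_rate = error_rate, allelic_balance = allelic_balance,
                 paired = paired, mode = mode,
                 capture_flank = as.integer(capture_flank),
                 sample_genotype = sample_genotype, seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## substitute `pos` (or `n` random) positions of `s` with different bases
mutate_seq <- function(s, n = NULL, pos = NULL) {
  chars <- strsplit(s, "")[[1L]]
  if (is.null(pos)) pos <- sample.int(length(chars), n)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

## exon/intron layout for a gene class: class I types exons 2,3,4; class II
## types exons 2,3; introns bracket every exon
gene_layout <- function(class) {
  exon_idx <- if (class == "I") c(2L, 3L, 4L) else c(2L, 3L)
  kinds <- c("intron", rep(c("exon", "intron"), length(exon_idx)))
  idx <- c(exon_idx[1L] - 1L, as.vector(rbind(exon_idx, exon_idx)))
  data.frame(kind = kinds, index = idx, stringsAsFactors = FALSE)
}

#' Generate a mock allele database
#'
#' Builds target and competitor genes with class-appropriate exon/intron
#' structure (class I: exons 2,3,4; class II: exons 2,3), plants G-groups by
#' duplicating the major exons of a founder allele and mutating only the
#' minor exon, derives competitor genes from their paralog target at the
#' configured divergence, drops intron sequence from a fraction of alleles
#' (exercising flank borrowing), and assigns Dirichlet-distributed
#' population frequencies. Deterministic per seed.
#'
#' @param cfg [sim_config()].
#' @return list with `records` (the database view: an `hla_allele_set` where
#'   a fraction of alleles lack intron sequence), `genome_records` (the
#'   complete genomic view every read is simulated from), `frequencies`
#'   (named vector over all alleles), `g_groups` (planted group
#'   memberships) and `cfg`.
#' @export
make_mock_alleles <- function(cfg) {
  set.seed(cfg$seed)
  records <- list()
  freqs <- numeric(0)
  g_groups <- list()

  gene_class_of <- c(cfg$genes,
                     stats::setNames(cfg$genes[cfg$competitors], names(cfg$competitors)))
  base_seq <- list()

  make_base <- function(gene) {
    layout <- gene_layout(gene_class_of[[gene]])
    lens <- ifelse(layout$kind == "exon",
                   sample(cfg$exon_len_range[1L]:cfg$exon_len_range[2L],
                          nrow(layout), replace = TRUE),
                   cfg$intron_len)
    data.frame(layout, sequence = vapply(lens, random_dna, character(1)),
               stringsAsFactors = FALSE)
  }

  for (g in names(cfg$genes)) base_seq[[g]] <- make_base(g)
  for (comp in names(cfg$competitors)) {
    src <- base_seq[[cfg$competitors[[comp]]]]
    src$sequence <- vapply(src$sequence, function(s) {
      n <- stats::rbinom(1L, nchar(s), cfg$paralog_divergence)
      if (n == 0L) s else mutate_seq(s, n)
    }, character(1))
    base_seq[[comp]] <- src
  }

  gen_gene <- function(gene, n_alleles, plant_g) {
    base <- base_seq[[gene]]
    class <- gene_class_of[[gene]]
    major <- if (class == "I") c(2L, 3L) else 2L
    minor <- if (class == "I") 4L else 3L
    n_groups <- if (plant_g) max(0L, round(cfg$g_group_fraction * n_alleles / 2)) else 0L
    out <- list()
    major_keys <- character(0)
    fam <- 0L
    while (length(out) < n_alleles) {
      fam <- fam + 1L
      segs <- base
      is_exon <- segs$kind == "exon"
      for (i in which(is_exon)) {
        n <- max(1L, stats::rbinom(1L, nchar(segs$sequence[i]), cfg$allele_divergence))
        segs$sequence[i] <- mutate_seq(segs$sequence[i], n)
      }
      key <- paste(segs$sequence[is_exon & segs$index %in% major], collapse = "+")
      if (key %in% major_keys) next    # avoid accidental G-groups
      members <- 1L
      if (fam <= n_groups && length(out) + 2L <= n_alleles) members <- 2L
      member_minor <- character(0)
      for (m in seq_len(members)) {
        msegs <- segs
        name <- sprintf("%02d:01:%02d", fam, m)
        if (m > 1L) {
          ## same major exons, mutated minor exon
          i <- which(msegs$kind == "exon" & msegs$index == minor)
          repeat {
            cand <- mutate_seq(base$sequence[i], n = 2L)
            if (!(cand %in% member_minor)) break
          }
          msegs$sequence[i] <- cand
        }
        member_minor <- c(member_minor,
                          msegs$sequence[msegs$kind == "exon" & msegs$index == minor])
        out[[length(out) + 1L]] <- allele_record(gene, name, msegs)
      }
      major_keys <- c(major_keys, key)
      if (members == 2L) {
        g_groups[[gene]] <<- c(g_groups[[gene]],
                               list(paste0(gene, "*", sprintf("%02d:01:%02d", fam, 1:2))))
      }
    }
    out
  }

  for (g in names(cfg$genes)) {
    recs <- gen_gene(g, cfg$alleles_per_gene, plant_g = TRUE)
    f <- stats::rgamma(length(recs), 1)
    f <- f / sum(f)
    for (i in seq_along(recs)) recs[[i]]$frequency <- f[i]
    freqs <- c(freqs, stats::setNames(f, vapply(recs, allele_full_name, character(1))))
    records <- c(records, recs)
  }
  for (comp in names(cfg$competitors)) {
    recs <- gen_gene(comp, cfg$alleles_per_competitor, plant_g = FALSE)
    f <- stats::rgamma(length(recs), 1)
    f <- f / sum(f)
    for (i in seq_along(recs)) recs[[i]]$frequency <- f[i]
    freqs <- c(freqs, stats::setNames(f, vapply(recs, allele_full_name, character(1))))
    records <- c(records, recs)
  }
  ## the database view drops intron sequence from a fraction of alleles
  ## (their panel flanks must then be borrowed from a same-gene sibling);
  ## the genomic view stays complete -- reads always come from the genome,
  ## the IMGT-style database merely lacks the intron annotation
  genome_records <- records
  gene_of <- vapply(records, `[[`, character(1), "gene")
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    idx <- idx[order(vapply(records[idx], `[[`, character(1), "name"),
                     method = "radix")]
    strip <- idx[-1L][stats::runif(length(idx) - 1L) < cfg$intronless_fraction]
    for (i in strip) {
      segs <- records[[i]]$segments
      records[[i]]$segments <- segs[segs$kind == "exon", , drop = FALSE]
    }
  }
  list(records = structure(records, class = "hla_allele_set"),
       genome_records = structure(genome_records, class = "hla_allele_set"),
       frequencies = freqs, g_groups = g_groups, cfg = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a two-allele genotype per target gene from population frequencies
#'
#' @param records allele records.
#' @param freq named frequency vector.
#' @param genes target genes (default: all genes present).
#' @return named list gene -> character(2) of full allele names (possibly
#'   identical: homozygote).
#' @export
draw_genotype <- function(records, freq, genes = NULL) {
  all_genes <- vapply(records, `[[`, character(1), "gene")
  names_full <- vapply(records, allele_full_name, character(1))
  if (is.null(genes)) genes <- unique(all_genes)
  out <- list()
  for (g in genes) {
    alleles <- names_full[all_genes == g]
    p <- freq[alleles]
    p[is.na(p)] <- 0
    if (sum(p) == 0) p <- rep(1, length(alleles))
    out[[g]] <- sample(alleles, 2L, replace = TRUE, prob = p)
  }
  out
}

#' Simulate sequencing reads from a two-allele genotype
#'
#' Reads are drawn uniformly over each chosen allele's targeted exons plus
#' `capture_flank` bp of flanking intron (WES mode) or over the whole allele
#' record (WGS mode), to the configured combined coverage split by
#' `allelic_balance`, on a random strand, with substitution errors injected
#' at `error_rate`. Deterministic per seed.
#'
#' @param records allele records the genotype alleles belong to; use the
#'   complete genomic records (`genome_records` from [make_mock_alleles()]),
#'   not the intron-stripped database view.
#' @param cfg [sim_config()].
#' @param genotype named list gene -> character(2) full allele names;
#'   defaults to `cfg$sample_genotype`, or a frequency-drawn genotype.
#' @param freq frequencies for genotype drawing (required if drawing).
#' @param seed seed for this sample (default `cfg$seed`).
#' @return list with `reads` (data.frame `id`, `sequence`, `quality`),
#'   `truth` (data.frame `id`, `gene`, `allele`, `start`, `strand`,
#'   `n_errors`) and `genotype`.
#' @export
simulate_reads <- function(records, cfg, genotype = NULL, freq = NULL,
                           seed = cfg$seed) {
  set.seed(seed)
  if (is.null(genotype)) genotype <- cfg$sample_genotype
  if (is.null(genotype)) {
    assert_that(!is.null(freq), "need frequencies to draw a genotype")
    genotype <- draw_genotype(records, freq, genes = setdiff(
      unique(vapply(records, `[[`, character(1), "gene")), names(cfg$competitors)))
  }
  names_full <- vapply(records, allele_full_name, character(1))
  L <- cfg$read_length
  reads_id <- character(0); reads_seq <- character(0)
  tr <- list()
  counter <- 0L

  for (g in names(genotype)) {
    pair <- genotype[[g]]
    assert_that(all(pair %in% names_full),
                sprintf("genotype alleles for %s missing from records", g))
    shares <- c(cfg$allelic_balance, 1 - cfg$allelic_balance)
    for (ai in 1:2) {
      rec <- records[[which(names_full == pair[ai])[1L]]]
      segs <- rec$segments
      full <- paste(segs$sequence, collapse = "")
      seg_end <- cumsum(nchar(segs$sequence))
      seg_start <- seg_end - nchar(segs$sequence) + 1L
      regions <- if (cfg$mode == "wgs") {
        data.frame(start = 1L, end = nchar(full))
      } else {
        ex <- which(segs$kind == "exon" & segs$index %in% targeted_exons(g, "all"))
        data.frame(start = pmax(1L, seg_start[ex] - cfg$capture_flank),
                   end = pmin(nchar(full), seg_end[ex] + cfg$capture_flank))
      }
      depth <- cfg$coverage * shares[ai]
      for (ri in seq_len(nrow(regions))) {
        rs <- regions$start[ri]; re <- regions$end[ri]
        if (re - rs + 1L < L) next
        ## read count calibrated so the interior (plateau) depth of the
        ## region equals the target: n starts over (len - L + 1) positions,
        ## each position covered by up to L admissible starts
        n <- stats::rpois(1L, depth * (re - rs + 1L - L + 1L) / L)
        if (n == 0L) next
        starts <- rs + sample.int(re - rs + 1L - L + 1L, n, replace = TRUE) - 1L
        for (st in starts) {
          counter <- counter + 1L
          s <- substr(full, st, st + L - 1L)
          ne <- stats::rbinom(1L, L, cfg$error_rate)
          if (ne > 0L) s <- mutate_seq(s, ne)
          strand <- if (stats::runif(1L) < 0.5) "+" else "-"
          if (strand == "-") s <- revcomp(s)
          id <- sprintf("sim%07d%s", counter,
                        if (cfg$paired) c("/1", "/2")[1L + counter %% 2L] else "")
          reads_id <- c(reads_id, id); reads_seq <- c(reads_seq, s)
          tr[[counter]] <- data.frame(id = id, gene = g, allele = pair[ai],
                                      start = st, strand = strand, n_errors = ne,
                                      stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- if (length(tr)) do.call(rbind, tr) else
    data.frame(id = character(0), gene = character(0), allele = character(0),
               start = integer(0), strand = character(0), n_errors = integer(0))
  list(reads = data.frame(id = reads_id, sequence = reads_seq,
                          quality = strrep("I", nchar(reads_seq)),
                          stringsAsFactors = FALSE),
       truth = truth, genotype = genotype)
}

## mDB label that explains an allele (its own name, or its G-group label)
mdb_label <- function(allele, mdb) {
  for (lab in names(mdb$g_members)) {
    if (allele %in% mdb$g_members[[lab]]) return(lab)
  }
  allele
}

#' Expected reported labels for a simulated genotype
#'
#' Given the two simulated alleles of a gene, returns the label set the
#' pipeline should report at full resolution, accounting for G-group
#' structure: two distinct members of the same G-group are only separable by
#' their minor exons, and when both are present the minor-exon evidence
#' retains both sequence classes, so the G-group label is the correct call.
#'
#' @param pair character(2) full allele names.
#' @param mdb,adb databases from [build_exact_dbs()].
#' @return character vector of expected labels (length 1 for homozygous or
#'   within-group calls, else 2).
#' @export
expected_calls <- function(pair, mdb, adb) {
  l1 <- mdb_label(pair[1L], mdb)
  l2 <- mdb_label(pair[2L], mdb)
  if (l1 != l2) {
    sort(unique(c(expected_label(pair[1L], mdb, adb),
                  expected_label(pair[2L], mdb, adb))))
  } else if (pair[1L] == pair[2L]) {
    expected_label(pair[1L], mdb, adb)
  } else {
    ## distinct members of one G-group: upgraded only if they share the
    ## minor exon class, otherwise the G label stands
    e1 <- expected_label(pair[1L], mdb, adb)
    e2 <- expected_label(pair[2L], mdb, adb)
    if (identical(e1, e2)) e1 else l1
  }
}

#' Expected reported label for a simulated truth allele
#'
#' Maps a simulated allele to the label the pipeline should report at full
#' resolution: its own name if it is not in a G-group; otherwise the
#' six-digit upgrade when the group's minor exons discriminate the members,
#' or the G-group label when they do not.
#'
#' @param allele full allele name (`GENE*NAME`).
#' @param mdb,adb databases from [build_exact_dbs()].
#' @return expected label (character).
#' @export
expected_label <- function(allele, mdb, adb) {
  for (lab in names(mdb$g_members)) {
    members <- mdb$g_members[[lab]]
    if (allele %in% members) {
      gene <- sub("\\*.*$", "", allele)
      seqs <- vapply(members, function(m) {
        ent <- adb$entries[[gene]][[m]]
        if (is.null(ent)) NA_character_ else paste(unlist(ent$exons), collapse = "+")
      }, character(1))
      own <- seqs[[allele]]
      if (is.na(own)) return(lab)
      same <- members[!is.na(seqs) & seqs == own]
      if (all(members %in% same)) return(lab)   # minor exon does not discriminate
      short <- truncate_fields(sub("^.*\\*", "", sort(same)[1L]), 3L)
      return(paste0(gene, "*", short))
    }
  }
  allele
}
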