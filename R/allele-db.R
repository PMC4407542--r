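## Allele reference set: parsing, the comprehensive mapping panel (CRP) and
## the exact-match typing databases (mDB / aDB) with G-group collapsing.

#' Construct an allele record
#'
#' One named allele with its ordered exon/intron segments. Segment order in
#' `segments` is the genomic order; the full allele sequence is their
#' concatenation.
#'
#' @param gene gene symbol (e.g. `"HLA-A"`).
#' @param name allele designation in colon-delimited nomenclature,
#'   e.g. `"02:01:01"` (the gene symbol is not part of the name).
#' @param segments data.frame with columns `kind` (`"exon"`/`"intron"`),
#'   `index` (positive integer) and `sequence` (uppercase DNA).
#' @param frequency population frequency in `[0,1]`, or `NA` if unknown.
#' @return an object of class `hla_allele`.
#' @export
allele_record <- function(gene, name, segments, frequency = NA_real_) {
  assert_that(is.character(gene) && length(gene) == 1L, "gene must be a single string")
  assert_that(is.character(name) && length(name) == 1L, "name must be a single string")
  assert_that(is.data.frame(segments) &&
                all(c("kind", "index", "sequence") %in% names(segments)),
              "segments needs columns kind, index, sequence")
  assert_that(all(segments$kind %in% c("exon", "intron")),
              "segment kind must be exon or intron")
  assert_that(all(nchar(segments$sequence) > 0L) && is_dna(segments$sequence),
              sprintf("allele %s*%s: segment sequences must be non-empty uppercase DNA",
                      gene, name))
  ex <- segments$index[segments$kind == "exon"]
  assert_that(length(ex) == 0L || all(diff(ex) > 0L),
              sprintf("allele %s*%s: exon indices must be strictly increasing", gene, name))
  structure(list(gene = gene, name = name,
                 segments = data.frame(kind = as.character(segments$kind),
                                       index = as.integer(segments$index),
                                       sequence = as.character(segments$sequence),
                                       stringsAsFactors = FALSE),
                 frequency = as.numeric(frequency)),
            class = "hla_allele")
}

#' @export
print.hla_allele <- function(x, ...) {
  cat(sprintf("<hla_allele> %s*%s  (%d segments%s)\n", x$gene, x$name,
              nrow(x$segments),
              if (is.na(x$frequency)) "" else sprintf(", freq %.4g", x$frequency)))
  invisible(x)
}

allele_full_name <- function(rec) paste0(rec$gene, "*", rec$name)

## pull a named segment sequence, or NA if absent
segment_seq <- function(rec, kind, index) {
  i <- which(rec$segments$kind == kind & rec$segments$index == index)
  if (length(i) == 0L) NA_character_ else rec$segments$sequence[i[1L]]
}

check_unique_names <- function(records) {
  nm <- vapply(records, allele_full_name, character(1))
  dup <- nm[duplicated(nm)]
  assert_that(length(dup) == 0L,
              paste0("duplicate allele name(s): ", paste(unique(dup), collapse = ", ")))
  invisible(nm)
}

#' Read an allele reference set
#'
#' Two plain-text dialects are understood and auto-detected:
#'
#' * **Segmented FASTA**: one FASTA record per segment with ids of the form
#'   `GENE*NAME|exon2` or `GENE*NAME|segkind=exon2` (intron segments use
#'   `intronN`).
#' * **Whole-allele FASTA plus annotation TSV**: each FASTA record is the
#'   full allele (`GENE*NAME`), and a sidecar TSV with columns
#'   `allele  gene  segment  start  end` (0-based half-open coordinates into
#'   the record) delimits the segments. The sidecar is given via
#'   `annotation`, or found automatically at `<path>.segments.tsv`.
#'
#' @param path FASTA file.
#' @param annotation optional path to the segment-annotation TSV.
#' @param frequencies optional named numeric vector or path to a TSV
#'   (`allele<TAB>frequency`) used to fill the records' frequency field.
#' @return list of [allele_record()] objects (class `hla_allele_set`).
#' @export
read_allele_set <- function(path, annotation = NULL, frequencies = NULL) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (is.null(annotation)) {
    side <- paste0(path, ".segments.tsv")
    if (file.exists(side)) annotation <- side
  }
  if (length(seqs) == 0L) {
    out <- structure(list(), class = "hla_allele_set")
    return(out)
  }
  records <- if (!is.null(annotation)) {
    parse_annotated_dialect(seqs, annotation)
  } else {
    parse_segmented_dialect(seqs)
  }
  check_unique_names(records)
  if (!is.null(frequencies)) {
    freq <- if (is.character(frequencies) && length(frequencies) == 1L) {
      read_frequency_table(frequencies)
    } else frequencies
    records <- lapply(records, function(r) {
      f <- unname(freq[allele_full_name(r)])
      if (length(f) == 1L && !is.na(f)) r$frequency <- f
      r
    })
  }
  structure(records, class = "hla_allele_set")
}

parse_segment_tag <- function(tag, where) {
  tag <- sub("^segkind=", "", tag)
  m <- regmatches(tag, regexec("^(exon|intron)([0-9]+)$", tag))[[1L]]
  assert_that(length(m) == 3L, sprintf("malformed segment tag '%s' in %s", tag, where))
  list(kind = m[2L], index = as.integer(m[3L]))
}

parse_segmented_dialect <- function(seqs) {
  ids <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  assert_that(length(bad) == 0L,
              sprintf("malformed record id '%s' (record %d): expected GENE*NAME|segment",
                      ids[bad[1L]], bad[1L]))
  allele <- vapply(parts, `[`, character(1), 1L)
  star <- regexpr("*", allele, fixed = TRUE)
  assert_that(all(star > 0L), "record ids must contain GENE*NAME")
  gene <- substr(allele, 1L, star - 1L)
  name <- substr(allele, star + 1L, nchar(allele))
  segtag <- vapply(parts, `[`, character(1), 2L)
  seqchr <- as.character(seqs)
  recs <- lapply(split(seq_along(seqs), allele), function(i) {
    tags <- lapply(seq_along(i), function(j)
      parse_segment_tag(segtag[i[j]], sprintf("record '%s'", ids[i[j]])))
    segs <- data.frame(kind = vapply(tags, `[[`, character(1), "kind"),
                       index = vapply(tags, `[[`, integer(1), "index"),
                       sequence = toupper(unname(seqchr[i])),
                       stringsAsFactors = FALSE)
    allele_record(gene[i[1L]], name[i[1L]], segs)
  })
  unname(recs[unique(allele)])  # keep file order of first appearance
}

parse_annotated_dialect <- function(seqs, annotation) {
  ann <- utils::read.table(annotation, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("allele", "gene", "segment", "start", "end")
  assert_that(all(need %in% names(ann)),
              sprintf("annotation TSV must have columns: %s", paste(need, collapse = ", ")))
  ids <- sub("\\s.*$", "", names(seqs))
  seqchr <- as.character(seqs)
  names(seqchr) <- ids
  recs <- lapply(split(seq_len(nrow(ann)), ann$allele), function(i) {
    a <- ann[i, , drop = FALSE]
    full <- seqchr[[a$allele[1L]]]
    assert_that(!is.null(full), sprintf("annotation names allele '%s' absent from FASTA",
                                        a$allele[1L]))
    assert_that(all(a$start >= 0L & a$end <= nchar(full) & a$start < a$end),
                sprintf("bad coordinates for allele '%s'", a$allele[1L]))
    tags <- lapply(a$segment, parse_segment_tag,
                   where = sprintf("annotation of '%s'", a$allele[1L]))
    segs <- data.frame(kind = vapply(tags, `[[`, character(1), "kind"),
                       index = vapply(tags, `[[`, integer(1), "index"),
                       sequence = toupper(substring(full, a$start + 1L, a$end)),
                       stringsAsFactors = FALSE)
    ## order segments by their start coordinate (genomic order)
    segs <- segs[order(a$start), , drop = FALSE]
    star <- regexpr("*", a$allele[1L], fixed = TRUE)
    allele_record(substr(a$allele[1L], 1L, star - 1L),
                  substr(a$allele[1L], star + 1L, nchar(a$allele[1L])), segs)
  })
  unname(recs[unique(ann$allele)])
}

#' Write an allele set in the segmented-FASTA dialect
#'
#' @param records `hla_allele_set` (or plain list of [allele_record()]).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_set <- function(records, path) {
  headers <- character(0); seqs <- character(0)
  for (r in records) {
    h <- sprintf("%s|%s%d", allele_full_name(r), r$segments$kind, r$segments$index)
    headers <- c(headers, h)
    seqs <- c(seqs, r$segments$sequence)
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an allele population-frequency table
#'
#' Plain TSV with two columns, `allele` (full name `GENE*NAME`) and
#' `frequency`. A header line is optional.
#'
#' @param path TSV path.
#' @return named numeric vector of frequencies.
#' @export
read_frequency_table <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) > 0L && identical(tolower(tab[1L, 1L]), "allele")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  freq <- suppressWarnings(as.numeric(tab[[2L]]))
  assert_that(!anyNA(freq) && all(freq >= 0), "frequencies must be non-negative numbers")
  names(freq) <- tab[[1L]]
  freq
}

#' Write a frequency table
#' @param freq named numeric vector (names are full allele names).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freq, path) {
  utils::write.table(data.frame(allele = names(freq), frequency = unname(freq)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## flanks of exon `idx` inside record `rec`: up to `flank_len` bases of the
## adjacent introns (intron idx-1 on the left, intron idx on the right, by
## the usual intron numbering; we look them up by adjacency in segment order).
exon_flanks <- function(rec, idx, flank_len) {
  segs <- rec$segments
  i <- which(segs$kind == "exon" & segs$index == idx)
  if (length(i) == 0L) return(NULL)
  left <- ""
  right <- ""
  if (i > 1L && segs$kind[i - 1L] == "intron") {
    s <- segs$sequence[i - 1L]
    left <- substring(s, max(1L, nchar(s) - flank_len + 1L), nchar(s))
  }
  if (i < nrow(segs) && segs$kind[i + 1L] == "intron") {
    s <- segs$sequence[i + 1L]
    right <- substring(s, 1L, min(flank_len, nchar(s)))
  }
  list(left = left, right = right)
}

#' Build the comprehensive reference panel (CRP)
#'
#' One panel entry per (allele, targeted exon): the exon sequence extended by
#' up to `flank_len` bases of flanking intron on each side, so reads falling
#' partly outside the exon are still captured during mapping. Alleles of
#' `competitor_genes` are included with role `"competitor"`; they absorb
#' reads from paralogous minor genes and sharpen classification. Alleles
#' lacking the flanking introns borrow them from the first same-gene allele
#' (lexicographically by allele name) that has them; if no allele of the gene
#' has introns the entry is emitted with zero-length flanks and a warning.
#'
#' @param records allele records ([read_allele_set()]).
#' @param target_genes character vector of genes to type.
#' @param competitor_genes character vector of mapping-competitor genes.
#' @param flank_len intron flank length in bp (default 50).
#' @return data.frame of class `hla_crp` with one row per entry: columns
#'   `source_allele`, `gene`, `role`, `exon`, `sequence`, `exon_start`,
#'   `exon_end` (1-based, closed) and `flank_len`.
#' @export
build_crp <- function(records, target_genes, competitor_genes = character(0),
                      flank_len = 50L) {
  assert_that(flank_len >= 0L, "flank_len must be >= 0")
  assert_that(length(intersect(target_genes, competitor_genes)) == 0L,
              "target and competitor gene sets must be disjoint")
  check_unique_names(records)
  genes <- vapply(records, `[[`, character(1), "gene")
  keep <- genes %in% c(target_genes, competitor_genes)
  records <- records[keep]; genes <- genes[keep]

  rows <- vector("list", 0L)
  for (g in unique(genes)) {
    recs <- records[genes == g]
    ord <- order(vapply(recs, `[[`, character(1), "name"), method = "radix")
    recs <- recs[ord]
    role <- if (g %in% competitor_genes) "competitor" else "target"
    exons <- targeted_exons(g, "all")
    for (idx in exons) {
      have_exon <- !vapply(recs, function(r) is.na(segment_seq(r, "exon", idx)),
                           logical(1))
      if (!any(have_exon)) next
      ## flank donors (per side): first allele (lexicographic) with that flank
      donor <- list(left = "", right = "")
      if (flank_len > 0L) {
        for (r in recs[have_exon]) {
          fl <- exon_flanks(r, idx, flank_len)
          if (nchar(donor$left) == 0L && nchar(fl$left) > 0L) donor$left <- fl$left
          if (nchar(donor$right) == 0L && nchar(fl$right) > 0L) donor$right <- fl$right
          if (nchar(donor$left) > 0L && nchar(donor$right) > 0L) break
        }
        if (nchar(donor$left) == 0L && nchar(donor$right) == 0L) {
          warning(sprintf(
            "gene %s exon %d: no allele carries intron sequence; using zero-length flanks",
            g, idx), call. = FALSE)
        }
      }
      for (r in recs[have_exon]) {
        ex <- segment_seq(r, "exon", idx)
        fl <- exon_flanks(r, idx, flank_len)
        if (nchar(fl$left) == 0L) fl$left <- donor$left
        if (nchar(fl$right) == 0L) fl$right <- donor$right
        seqs <- paste0(fl$left, ex, fl$right)
        rows[[length(rows) + 1L]] <- data.frame(
          source_allele = allele_full_name(r), gene = g, role = role,
          exon = idx, sequence = seqs,
          exon_start = nchar(fl$left) + 1L,
          exon_end = nchar(fl$left) + nchar(ex),
          flank_len = flank_len, stringsAsFactors = FALSE)
      }
    }
  }
  crp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_allele = character(0), gene = character(0),
               role = character(0), exon = integer(0), sequence = character(0),
               exon_start = integer(0), exon_end = integer(0),
               flank_len = integer(0), stringsAsFactors = FALSE)
  crp <- crp[order(crp$gene, crp$exon, crp$source_allele, method = "radix"), ,
             drop = FALSE]
  rownames(crp) <- NULL
  class(crp) <- c("hla_crp", "data.frame")
  crp
}

#' Build the exact-match typing databases (mDB and aDB)
#'
#' The major database (mDB) holds, per gene, the major polymorphic exon
#' sequences (exons 2 and 3 for class I, exon 2 for class II) of every
#' allele. Alleles identical across all major exons of their gene are
#' collapsed into a G-group labelled with the lexicographically smallest
#' member name truncated to three colon fields plus suffix `"G"`. The
#' additional database (aDB) holds minor polymorphic exon sequences (exon 4
#' class I, exon 3 class II) keyed by allele name; it always covers every
#' G-group member that has the minor exon. Neither database carries intron
#' sequence or competitor entries.
#'
#' @param records allele records.
#' @return list with elements `mdb` and `adb`, each of class `hla_exactdb`
#'   with fields `tier`, `entries` (per gene, a list of
#'   `list(label, exons = named list of sequences)`) and for the mDB
#'   `g_members` (G-group label -> member allele names).
#' @export
build_exact_dbs <- function(records) {
  assert_that(length(records) > 0L, "records must be non-empty")
  check_unique_names(records)
  genes <- vapply(records, `[[`, character(1), "gene")
  m_entries <- list(); a_entries <- list(); g_members <- list()

  for (g in sort(unique(genes))) {
    recs <- records[genes == g]
    ord <- order(vapply(recs, `[[`, character(1), "name"), method = "radix")
    recs <- recs[ord]
    major <- targeted_exons(g, "major")
    minor <- targeted_exons(g, "minor")
    keys <- vapply(recs, function(r) {
      s <- vapply(major, function(i) segment_seq(r, "exon", i), character(1))
      if (anyNA(s)) NA_character_ else paste(s, collapse = "+")
    }, character(1))
    if (all(is.na(keys))) {
      warning(sprintf("gene %s: no allele carries its major exons; excluded", g),
              call. = FALSE)
      next
    }
    recs <- recs[!is.na(keys)]; keys <- keys[!is.na(keys)]
    groups <- split(seq_along(recs), keys)
    ## order entries by smallest member name for reproducibility
    smallest <- vapply(groups, function(i)
      min(vapply(recs[i], `[[`, character(1), "name")), character(1))
    groups <- groups[order(smallest, method = "radix")]
    gene_entries <- list()
    for (grp in groups) {
      members <- vapply(recs[grp], `[[`, character(1), "name")
      r1 <- recs[[grp[1L]]]
      exseq <- lapply(major, function(i) segment_seq(r1, "exon", i))
      names(exseq) <- as.character(major)
      if (length(grp) >= 2L) {
        label <- paste0(g, "*", truncate_fields(min(members), 3L), "G")
        g_members[[label]] <- paste0(g, "*", sort(members))
      } else {
        label <- paste0(g, "*", members)
      }
      gene_entries[[label]] <- list(label = label, gene = g, exons = exseq)
    }
    m_entries[[g]] <- gene_entries
    ## aDB: minor exons for every allele that has them (superset of G members)
    a_list <- list()
    for (r in recs) {
      s <- segment_seq(r, "exon", minor)
      if (!is.na(s)) {
        lab <- allele_full_name(r)
        ex <- list(s); names(ex) <- as.character(minor)
        a_list[[lab]] <- list(label = lab, gene = g, exons = ex)
      }
    }
    if (length(a_list)) a_entries[[g]] <- a_list
  }
  mdb <- structure(list(tier = "major", entries = m_entries, g_members = g_members),
                   class = "hla_exactdb")
  adb <- structure(list(tier = "additional", entries = a_entries,
                        g_members = g_members),
                   class = "hla_exactdb")
  ## reference-semantics scratch space: exon k-mer maps memoized across calls
  attr(mdb, "kmer_cache") <- new.env(parent = emptyenv())
  attr(adb, "kmer_cache") <- new.env(parent = emptyenv())
  list(mdb = mdb, adb = adb)
}

#' @export
print.hla_exactdb <- function(x, ...) {
  cat(sprintf("<hla_exactdb> tier=%s, %d gene(s), %d entries, %d G-group(s)\n",
              x$tier, length(x$entries), sum(lengths(x$entries)),
              if (x$tier == "major") length(x$g_members) else length(x$g_members)))
  invisible(x)
}

## all member allele names explained by an mDB label (the label itself for
## singletons)
label_members <- function(db, label) {
  if (!is.null(db$g_members[[label]])) db$g_members[[label]] else label
}

## frequency of an mDB label = sum of member frequencies (unknown -> 0)
label_frequency <- function(label, freq, db = NULL) {
  if (identical(label, "unknown")) return(0)
  members <- if (!is.null(db)) label_members(db, label) else label
  f <- freq[members]
  f[is.na(f)] <- 0
  sum(f)
}

#' Serialize built databases to JSON
#'
#' @param x an `hla_crp` or `hla_exactdb` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_db_json <- function(x, path) {
  if (inherits(x, "hla_crp")) {
    jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "hla_exactdb")) {
    jsonlite::write_json(list(tier = x$tier, entries = x$entries,
                              g_members = x$g_members),
                         path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported object for JSON serialization")
  invisible(path)
}
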