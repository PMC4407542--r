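## Stepwise typing: exact matching of contigs to the allele databases,
## contig/allele scoring, descending-score designation, minor-exon (aDB)
## resolution of G-groups, phase-ambiguity enumeration and frequency
## tie-breaking.

## positions (1-based) at which `key` occurs in `s`, via a memoized k-mer
## position map for `s` (all occurrences, including overlapping ones)
kmer_positions <- function(s, key, cache = NULL, cache_key = NULL) {
  k <- nchar(key)
  if (!is.null(cache) && !is.null(cache_key)) {
    idx <- cache[[cache_key]]
    if (is.null(idx)) {
      n <- nchar(s)
      if (n < k) {
        idx <- new.env(parent = emptyenv())
      } else {
        starts <- seq_len(n - k + 1L)
        idx <- new.env(parent = emptyenv())
        list2env(split(starts, substring(s, starts, starts + k - 1L)), idx)
      }
      cache[[cache_key]] <- idx
    }
    p <- idx[[key]]
    return(if (is.null(p)) integer(0) else p)
  }
  n <- nchar(s)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  which(substring(s, starts, starts + k - 1L) == key)
}

## all ungapped perfect-overlap alignments between a contig string and an
## exon string: overlap >= min_overlap, zero mismatches over the
## exon-intersecting region, overhang beyond either exon end <= max_overhang.
## Returns data.frame(span_start, span_end, exon_offset) in contig
## coordinates (1-based closed; exon_offset = exon position aligned to
## span_start).
overlap_alignments <- function(contig, exon, min_overlap, max_overhang,
                               ccache = NULL, ecache = NULL,
                               contig_key = NULL, exon_key = NULL) {
  lc <- nchar(contig); le <- nchar(exon)
  if (lc < min_overlap || le < min_overlap) return(NULL)
  out <- NULL
  ## case 1: contig start lies inside the exon -> anchor contig prefix in exon
  key <- substr(contig, 1L, min_overlap)
  hit <- kmer_positions(exon, key, ecache, exon_key)
  for (d in hit - 1L) {              # contig[1] aligns exon[d+1]
    ov <- min(lc, le - d)
    if (ov < min_overlap) next
    if (substr(contig, 1L, ov) != substr(exon, d + 1L, d + ov)) next
    right_over <- lc - ov            # contig past the exon 3' end
    if (right_over > max_overhang) next
    out <- rbind(out, data.frame(span_start = 1L, span_end = ov, exon_offset = d + 1L))
  }
  ## case 2: contig starts before the exon -> anchor exon prefix in contig
  key <- substr(exon, 1L, min_overlap)
  hit <- kmer_positions(contig, key, ccache, contig_key)
  for (h in hit - 1L) {              # exon[1] aligns contig[h+1]
    if (h == 0L) next                # already covered by case 1 (d = 0)
    if (h > max_overhang) next       # left overhang beyond the intron flank
    ov <- min(lc - h, le)
    if (ov < min_overlap) next
    if (substr(contig, h + 1L, h + ov) != substr(exon, 1L, ov)) next
    right_over <- (lc - h) - ov
    if (right_over > max_overhang) next
    out <- rbind(out, data.frame(span_start = h + 1L, span_end = h + ov,
                                 exon_offset = 1L))
  }
  out
}

#' Match contigs against an exact-match allele database
#'
#' A match is emitted when the contig (or its reverse complement) aligns to
#' an allele exon with zero mismatches over their overlap, the overlap is at
#' least `min_overlap`, and any contig overhang past the exon ends (intron
#' flank carried over from assembly) is at most `flank_len` per side; the
#' overhang itself is ignored. Contigs matching no allele are returned
#' separately: they are candidate novel alleles (or residual error contigs).
#'
#' @param contigs `hla_contig_set` (already depth-filtered).
#' @param db `hla_exactdb` (mDB or aDB).
#' @param gene gene symbol to match against.
#' @param min_overlap minimum exact overlap (default 20).
#' @param flank_len maximum ignored overhang per side (default 50).
#' @return list with `matches` (data.frame: `contig`, `allele_label`, `exon`,
#'   `span_start`, `span_end`, `exonic_fraction`, `strand`) and `unmatched`
#'   (integer indices into `contigs`).
#' @export
match_contigs <- function(contigs, db, gene, min_overlap = 20L, flank_len = 50L) {
  entries <- db$entries[[gene]]
  empty <- data.frame(contig = integer(0), allele_label = character(0),
                      exon = integer(0), span_start = integer(0),
                      span_end = integer(0), exon_start = integer(0),
                      exon_end = integer(0), exonic_fraction = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (length(contigs) == 0L || is.null(entries)) {
    return(list(matches = empty, unmatched = seq_along(contigs)))
  }
  ## memoized k-mer position maps: per contig orientation within this call,
  ## and per database exon persistently (the cache environment travels with
  ## the db object)
  ecache <- attr(db, "kmer_cache")
  if (is.null(ecache)) ecache <- new.env(parent = emptyenv())
  ccache <- new.env(parent = emptyenv())
  rows <- list()
  for (ci in seq_along(contigs)) {
    cseq <- contigs[[ci]]$sequence
    crev <- revcomp(cseq)
    ckey <- paste0("c:", cseq)
    lc <- nchar(cseq)
    for (ent in entries) {
      for (ex_name in names(ent$exons)) {
        exon <- ent$exons[[ex_name]]
        ekey <- paste0("e:", gene, "|", ent$label, "|", ex_name, "|", min_overlap)
        best <- NULL
        for (strand in c("+", "-")) {
          s <- if (strand == "+") cseq else crev
          al <- overlap_alignments(s, exon, min_overlap, flank_len, ccache, ecache,
                                   contig_key = paste0(ckey, strand), exon_key = ekey)
          if (is.null(al)) next
          al$strand <- strand
          ## report the deepest exonic overlap for this (contig, entry, exon)
          al <- al[which.max(al$span_end - al$span_start), , drop = FALSE]
          if (is.null(best) ||
              (al$span_end - al$span_start) > (best$span_end - best$span_start)) {
            best <- al
          }
        }
        if (!is.null(best)) {
          ov <- best$span_end - best$span_start + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            contig = ci, allele_label = ent$label, exon = as.integer(ex_name),
            span_start = best$span_start, span_end = best$span_end,
            exon_start = best$exon_offset,
            exon_end = best$exon_offset + ov - 1L,
            exonic_fraction = ov / lc, strand = best$strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else empty
  unmatched <- setdiff(seq_along(contigs), unique(matches$contig))
  list(matches = matches, unmatched = unmatched)
}

#' Score candidate alleles from contig matches
#'
#' The score of a contig (towards one allele) is the product of the contig
#' size in base pairs, its average coverage depth, and the fraction of the
#' contig lying in the allele's exon; an allele supported by several contigs
#' scores their sum. A contig matching an allele on more than one exon
#' contributes only its deepest match.
#'
#' @param matches match table from [match_contigs()].
#' @param contigs the matched `hla_contig_set`.
#' @return data.frame of class `hla_allele_scores` with columns
#'   `allele_label`, `total`, `n_contigs`, sorted by descending total (ties
#'   by label); the per-contig trace is in `attr(, "contig_scores")`.
#' @export
score_alleles <- function(matches, contigs) {
  if (nrow(matches) == 0L) {
    out <- data.frame(allele_label = character(0), total = numeric(0),
                      n_contigs = integer(0), stringsAsFactors = FALSE)
    attr(out, "contig_scores") <- data.frame(allele_label = character(0),
                                             contig = integer(0), score = numeric(0))
    class(out) <- c("hla_allele_scores", "data.frame")
    return(out)
  }
  lens <- vapply(contigs, function(cg) nchar(cg$sequence), integer(1))
  depths <- vapply(contigs, `[[`, numeric(1), "mean_depth")
  cs <- matches
  cs$score <- lens[cs$contig] * depths[cs$contig] * cs$exonic_fraction
  ## one contribution per (contig, allele): keep the largest
  cs <- cs[order(cs$allele_label, cs$contig, -cs$score), , drop = FALSE]
  cs <- cs[!duplicated(cs[, c("allele_label", "contig")]), , drop = FALSE]
  tot <- tapply(cs$score, cs$allele_label, sum)
  ncg <- tapply(cs$contig, cs$allele_label, function(x) length(unique(x)))
  out <- data.frame(allele_label = names(tot), total = as.numeric(tot),
                    n_contigs = as.integer(ncg[names(tot)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$allele_label, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contig_scores") <- cs[, c("allele_label", "contig", "score")]
  class(out) <- c("hla_allele_scores", "data.frame")
  out
}

new_typing_call <- function(gene) {
  structure(list(gene = gene, alleles = character(0), homozygous = FALSE,
                 resolution = character(0), second_allele_ambiguous = FALSE,
                 phase_ambiguous = FALSE, phase_pairs = list(),
                 extra_alleles = list(), novel_contigs = integer(0),
                 no_call = FALSE, diagnostic = NA_character_,
                 scores = NULL, qc = NULL),
            class = "hla_typing_call")
}

#' @export
print.hla_typing_call <- function(x, ...) {
  al <- if (x$no_call) sprintf("no call (%s)", x$diagnostic)
        else if (x$homozygous) sprintf("%s (homozygous)", x$alleles)
        else paste(x$alleles, collapse = "; ")
  cat(sprintf("<typing call> %s: %s%s%s\n", x$gene, al,
              if (x$phase_ambiguous) " [phase-ambiguous]" else "",
              if (length(x$extra_alleles)) " [extra alleles detected]" else ""))
  invisible(x)
}

#' Designate up to two alleles from sorted scores
#'
#' Walks candidates in descending score order (ties broken by frequency,
#' then label) and designates a candidate when at least one of its
#' supporting contigs is uniquely matched -- matched by no other
#' not-yet-designated candidate -- and not already assigned to a designated
#' allele. The walk stops recording designations at two; further candidates
#' that would qualify are documented as possible contamination
#' (third/fourth allele). A single designation explaining every matched
#' contig is reported homozygous.
#'
#' @param scores [score_alleles()] output.
#' @param matches match table from [match_contigs()].
#' @param freq named frequency vector (optional).
#' @param gene gene symbol for the call.
#' @param db the mDB (used only to translate labels to member frequencies).
#' @return an `hla_typing_call`.
#' @export
designate_alleles <- function(scores, matches, freq = NULL, gene = NA_character_,
                              db = NULL) {
  call <- new_typing_call(gene)
  call$scores <- scores
  if (nrow(scores) == 0L) {
    call$no_call <- TRUE
    call$diagnostic <- if (nrow(matches) == 0L) "no contigs matched the database"
                       else "empty score table"
    return(call)
  }
  fr <- vapply(scores$allele_label, label_frequency, numeric(1),
               freq = if (is.null(freq)) numeric(0) else freq, db = db)
  walk <- scores$allele_label[order(-scores$total, -fr, scores$allele_label,
                                    method = "radix")]
  support <- split(matches$contig, matches$allele_label)
  support <- lapply(support, unique)
  designated <- character(0)
  assigned <- integer(0)
  extras <- list()
  for (cand in walk) {
    contigs_c <- support[[cand]]
    others <- setdiff(names(support), c(designated, cand))
    other_contigs <- unique(unlist(support[others], use.names = FALSE))
    uniq <- setdiff(contigs_c, other_contigs)
    usable <- setdiff(uniq, assigned)
    if (length(usable) == 0L) next
    if (length(designated) < 2L) {
      designated <- c(designated, cand)
      assigned <- union(assigned, contigs_c)
    } else {
      extras[[cand]] <- usable
    }
  }
  if (length(designated) == 0L) {
    call$no_call <- TRUE
    call$diagnostic <- "no candidate owns a uniquely matched contig"
    return(call)
  }
  call$alleles <- designated
  call$resolution <- ifelse(grepl("G$", designated), "G-group", "allele")
  names(call$resolution) <- designated
  call$extra_alleles <- extras
  if (length(designated) == 1L) {
    explained <- support[[designated]]
    if (all(unique(matches$contig) %in% explained)) {
      call$homozygous <- TRUE
    } else {
      call$second_allele_ambiguous <- TRUE
      call$diagnostic <- "unexplained contigs but no uniquely matched second candidate"
    }
  }
  call
}

#' Resolve G-group designations via minor exons (aDB)
#'
#' For each designated G-group, the group members whose minor polymorphic
#' exon perfectly matches one of the assembled contigs are retained. Only
#' matches that cover at least one position where the members' minor exons
#' differ are informative: a short contig lying entirely in a region the
#' members share matches every member and cannot discriminate. If exactly
#' one minor-exon sequence class survives, the designation is upgraded and
#' reported at six digits (three colon fields); intronic evidence being out
#' of scope, eight-digit resolution is never claimed. If several classes
#' survive, or no informative minor-exon contig exists, the G-group label is
#' kept.
#'
#' @param call `hla_typing_call` with at least one G-group designation.
#' @param contigs the depth-filtered `hla_contig_set` for the gene.
#' @param adb additional database from [build_exact_dbs()].
#' @param min_overlap,flank_len as in [match_contigs()].
#' @return the updated call (fields `alleles`, `resolution`).
#' @export
resolve_minor_exons <- function(call, contigs, adb, min_overlap = 20L,
                                flank_len = 50L) {
  if (!length(call$alleles) || !any(grepl("G$", call$alleles))) return(call)
  am <- match_contigs(contigs, adb, call$gene, min_overlap, flank_len)$matches
  orig_alleles <- call$alleles
  for (i in seq_along(orig_alleles)) {
    lab <- orig_alleles[i]
    if (!grepl("G$", lab)) next
    members <- adb$g_members[[lab]]
    if (is.null(members)) next
    ## contigs already explained by the partner designation are not evidence
    ## for this group's members (a fragment of the partner's minor exon can
    ## coincide with a member over a shared stretch)
    partners <- orig_alleles[-i]
    partner_alleles <- unlist(lapply(partners, function(p) {
      if (grepl("G$", p) && !is.null(adb$g_members[[p]])) adb$g_members[[p]] else p
    }))
    excl <- unique(am$contig[am$allele_label %in% partner_alleles])
    minor_of <- lapply(members, function(m) {
      ent <- adb$entries[[call$gene]][[m]]
      if (is.null(ent)) NULL else unlist(ent$exons)
    })
    names(minor_of) <- members
    have <- !vapply(minor_of, is.null, logical(1))
    if (!any(have)) next
    ## positions where the members' minor exons differ (discriminating sites)
    seqs <- minor_of[have]
    lens <- vapply(seqs, nchar, integer(1))
    disc <- if (length(unique(lens)) > 1L) {
      seq_len(max(lens))             # length differences: everything counts
    } else {
      mat <- vapply(seqs, function(s) utf8ToInt(s), integer(lens[1L]))
      which(apply(mat, 1L, function(x) length(unique(x)) > 1L))
    }
    hit <- character(0)
    mm <- am[am$allele_label %in% members & !(am$contig %in% excl), , drop = FALSE]
    for (j in seq_len(nrow(mm))) {
      covered <- disc[disc >= mm$exon_start[j] & disc <= mm$exon_end[j]]
      if (length(covered)) hit <- c(hit, mm$allele_label[j])
    }
    hit <- unique(hit)
    if (length(hit) == 0L) next    # no informative minor-exon contig: keep G
    minor_seq <- vapply(hit, function(m) paste(minor_of[[m]], collapse = "+"),
                        character(1))
    classes <- unique(minor_seq)
    if (length(classes) == 1L) {
      survivors <- sort(hit)
      gene_prefix <- paste0(call$gene, "*")
      short <- truncate_fields(sub(gene_prefix, "", survivors[1L], fixed = TRUE), 3L)
      new_lab <- paste0(gene_prefix, short)
      names(call$resolution)[names(call$resolution) == lab] <- new_lab
      call$resolution[new_lab] <- "six-digit"
      call$alleles[i] <- new_lab
      ## remember the group it came from (phase enumeration needs the mDB label)
      attr(call, "g_origin") <- c(attr(call, "g_origin"),
                                  stats::setNames(lab, new_lab))
    }
  }
  call
}

## identical-run lengths between consecutive variant positions decide
## linkage: two variants on the same exon are phase-linked iff the identical
## run between them is <= read_length (a single read can span both)
segment_blocks <- function(diff_pos, read_length) {
  if (length(diff_pos) == 0L) return(list())
  diff_pos <- sort(diff_pos)
  gaps <- diff(diff_pos) - 1L
  cut <- c(0L, cumsum(gaps > read_length))
  split(diff_pos, cut)
}

#' Detect and enumerate phase ambiguity for a heterozygous call
#'
#' Phase becomes an issue when the identical run between two heterozygous
#' blocks exceeds the read length: the polymorphic blocks can then be
#' recombined across the two haplotypes without contradicting any read, and
#' different combinations may spell different database alleles. Blocks on
#' different exons are never linked (contigs are per-exon). Alternative
#' explanations are reported when a recombined haplotype equals another mDB
#' allele of the gene; the partner haplotype may be a known allele or an
#' `"unknown"` placeholder. The reported pair is then chosen by
#' [break_ties_by_frequency()] over all consistent pairs.
#'
#' @param call heterozygous `hla_typing_call` (two designations).
#' @param mdb major database.
#' @param read_length read length in bp.
#' @param freq named frequency vector (optional).
#' @param max_blocks safety cap on enumerated blocks (default 12).
#' @return the updated call (`phase_ambiguous`, `phase_pairs`, `alleles`).
#' @export
detect_phase_ambiguity <- function(call, mdb, read_length, freq = NULL,
                                   max_blocks = 12L) {
  if (length(call$alleles) != 2L || call$no_call) return(call)
  gene <- call$gene
  entries <- mdb$entries[[gene]]
  ## the designated labels may have been upgraded to six digits; map back
  g_origin <- attr(call, "g_origin")
  lab <- vapply(call$alleles, function(a) {
    if (!is.null(g_origin) && a %in% names(g_origin)) g_origin[[a]] else a
  }, character(1))
  if (!all(lab %in% names(entries))) return(call)
  ex1 <- entries[[lab[1L]]]$exons
  ex2 <- entries[[lab[2L]]]$exons
  if (!identical(names(ex1), names(ex2))) return(call)
  if (!all(nchar(unlist(ex1)) == nchar(unlist(ex2)))) return(call)

  blocks <- list()   # list of list(exon =, pos =)
  for (e in names(ex1)) {
    a <- strsplit(ex1[[e]], "")[[1L]]
    b <- strsplit(ex2[[e]], "")[[1L]]
    dp <- which(a != b)
    for (blk in segment_blocks(dp, read_length)) {
      blocks[[length(blocks) + 1L]] <- list(exon = e, pos = blk)
    }
  }
  ## heterozygous only where both exons of an exon pair differ; single block
  ## (or none) means every variant is read-linked: no ambiguity
  if (length(blocks) <= 1L || length(blocks) > max_blocks) return(call)

  seq_lookup <- new.env(parent = emptyenv())
  for (ent in entries) {
    keyseq <- paste(unlist(ent$exons), collapse = "+")
    if (is.null(seq_lookup[[keyseq]])) seq_lookup[[keyseq]] <- ent$label
  }
  hap_label <- function(exs) {
    v <- seq_lookup[[paste(unlist(exs), collapse = "+")]]
    if (is.null(v)) NA_character_ else v
  }

  recombine <- function(assign) {
    h1 <- lapply(ex1, function(x) strsplit(x, "")[[1L]])
    h2 <- lapply(ex2, function(x) strsplit(x, "")[[1L]])
    for (j in seq_along(blocks)) {
      if (assign[j] == 2L) {      # swap this block between the haplotypes
        b <- blocks[[j]]
        tmp <- h1[[b$exon]][b$pos]
        h1[[b$exon]][b$pos] <- h2[[b$exon]][b$pos]
        h2[[b$exon]][b$pos] <- tmp
      }
    }
    list(lapply(h1, paste, collapse = ""), lapply(h2, paste, collapse = ""))
  }

  nb <- length(blocks)
  pairs <- list(sort(lab))
  grid <- as.matrix(expand.grid(rep(list(1:2), nb - 1L)))
  for (gi in seq_len(nrow(grid))) {
    assign <- c(1L, as.integer(grid[gi, ]))    # first block fixed: unordered pairs
    if (all(assign == 1L)) next
    rec <- recombine(assign)
    l1 <- hap_label(rec[[1L]]); l2 <- hap_label(rec[[2L]])
    if (is.na(l1) && is.na(l2)) next           # no database allele involved
    pr <- sort(c(ifelse(is.na(l1), "unknown", l1),
                 ifelse(is.na(l2), "unknown", l2)))
    if (identical(pr, pairs[[1L]])) next
    pairs[[length(pairs) + 1L]] <- pr
  }
  pairs <- unique(pairs)
  if (length(pairs) <= 1L) return(call)

  call$phase_ambiguous <- TRUE
  call$phase_pairs <- pairs
  chosen <- break_ties_by_frequency(pairs, freq, mdb)
  if (!identical(sort(chosen), sort(lab))) {
    call$alleles <- chosen
    call$resolution <- ifelse(grepl("G$", chosen), "G-group",
                              ifelse(chosen == "unknown", "none", "allele"))
    names(call$resolution) <- chosen
  }
  call
}

#' Choose among alternative allele pairs by population frequency
#'
#' Pairs are ranked by the sum of member frequencies, then the maximum
#' member frequency, then lexicographically; alleles with unknown frequency
#' (including the `"unknown"` placeholder) count as zero. G-group labels take
#' the summed frequency of their members.
#'
#' @param pairs list of character(2) allele-label pairs.
#' @param freq named frequency vector (optional; all-zero if `NULL`).
#' @param db optional `hla_exactdb` used to expand G-group labels.
#' @return the winning pair (character(2)).
#' @export
break_ties_by_frequency <- function(pairs, freq = NULL, db = NULL) {
  assert_that(length(pairs) >= 1L, "need at least one pair")
  if (is.null(freq)) freq <- numeric(0)
  f <- lapply(pairs, function(p) vapply(p, label_frequency, numeric(1),
                                        freq = freq, db = db))
  sums <- vapply(f, sum, numeric(1))
  maxs <- vapply(f, max, numeric(1))
  keys <- vapply(pairs, function(p) paste(sort(p), collapse = ";"), character(1))
  ord <- order(-sums, -maxs, keys, method = "radix")
  pairs[[ord[1L]]]
}
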