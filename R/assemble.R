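## Targeted de-novo assembly of a gene's read bin into contigs, admitting
## only overlaps with 100% identity (zero mismatches), with per-base depth.
##
## Greedy seed-and-extend: contigs are seeded from not-yet-used reads in a
## deterministic order (descending minimum k-mer multiplicity, ties by id)
## and extended base by base. At every step all reads whose suffix-anchored
## overlap with the contig is >= min_overlap and identical vote on the next
## base, weighted by their overlap lengths; a read that disagrees at any
## overlapped position is rejected for that contig but remains available to
## seed or join others, which is what separates the two haplotypes of a
## heterozygote. Reads containing a k-mer seen only once in the bin (the
## signature of a sequencing error at these depths) never seed an
## extension: they are left as unjoined single-read contigs for the
## five-fold depth filter to remove.

#' Assemble a read bin into zero-mismatch contigs
#'
#' @param bin data.frame with columns `id` and `sequence` (reads oriented to
#'   the reference strand, as produced by [classify_reads()]); both
#'   orientations are still considered during overlap detection.
#' @param min_overlap minimum exact overlap in bp (default 20, must be >= 15).
#' @param seed reserved for optional randomized restarts; the default
#'   algorithm is fully deterministic and ignores it.
#' @param gene optional gene symbol annotated on the contigs.
#' @return list of contigs (class `hla_contig_set`); each contig is a list
#'   with `gene`, `sequence`, `depth` (integer per-base coverage),
#'   `support` (reads incorporated) and `mean_depth`. Contigs are in
#'   canonical order (lexicographic by sequence).
#' @export
assemble_bin <- function(bin, min_overlap = 20L, seed = NULL, gene = NA_character_) {
  assert_that(min_overlap >= 15L, "min_overlap must be >= 15")
  empty <- structure(list(), class = "hla_contig_set")
  if (is.null(bin) || nrow(bin) == 0L) return(empty)
  st <- new.env(parent = emptyenv())
  st$fwd <- bin$sequence
  st$rvs <- revcomp(st$fwd)
  st$n <- length(st$fwd)
  st$lens <- nchar(st$fwd)
  st$k <- as.integer(min_overlap)
  st$max_read_len <- max(st$lens)
  st$max_contig_len <- sum(st$lens)
  st$used <- rep(FALSE, st$n)

  usable <- st$lens >= st$k
  if (!any(usable)) return(empty)

  ## prefix k-mer index over both orientations: kmer -> codes, where code
  ## <= n is read `code` forward and code > n is read `code - n` reversed
  pref <- c(substr(st$fwd, 1L, st$k), substr(st$rvs, 1L, st$k))
  codes <- c(seq_len(st$n), seq_len(st$n) + st$n)
  keep <- rep(usable, 2L)
  st$pidx <- new.env(parent = emptyenv())
  list2env(split(codes[keep], pref[keep]), st$pidx)

  ## seeding order: descending minimum canonical k-mer multiplicity,
  ## ties broken by read id
  canon_kmers <- function(i) {
    km <- seq_kmers(st$fwd[i], st$k)
    rkm <- base::rev(seq_kmers(st$rvs[i], st$k))
    ifelse(km < rkm, km, rkm)
  }
  all_km <- unlist(lapply(which(usable), canon_kmers), use.names = FALSE)
  km_tab <- table(all_km)
  min_mult <- rep(NA_integer_, st$n)
  ## trust: a sequencing error taints a window of k-mers in the middle of a
  ## read, so a unique k-mer strictly between multiply-seen k-mers marks the
  ## read untrusted. Unique k-mers confined to a read end are the normal
  ## signature of a coverage boundary (the outermost read of a region) and
  ## do not discredit the read.
  st$trusted <- rep(FALSE, st$n)
  for (i in which(usable)) {
    mult <- as.integer(km_tab[canon_kmers(i)])
    min_mult[i] <- min(mult)
    nu <- which(mult >= 2L)
    u <- which(mult == 1L)
    st$trusted[i] <- length(nu) > 0L &&
      !any(u > min(nu) & u < max(nu))
  }
  seed_order <- order(-min_mult, bin$id, method = "radix")
  seed_order <- seed_order[usable[seed_order]]

  ## copies of each read sequence (either orientation): lets unextended
  ## single-read contigs skip the placement machinery (equal-width bins only,
  ## where containment implies identity)
  canon_read <- ifelse(st$fwd <= st$rvs, st$fwd, st$rvs)
  uniform_width <- length(unique(st$lens)) == 1L

  contigs <- list()
  for (i in seed_order) {
    if (st$used[i]) next
    if (st$trusted[i] && min_mult[i] >= 2L) {
      ## only reads whose every k-mer is independently confirmed may seed an
      ## extension; trusted boundary reads (unique k-mers at one end, which
      ## may hide an error there) still vote and extend other seeds but
      ## cannot found a consensus of their own
      contig <- asm_extend_right(st$fwd[i], st)
      contig <- revcomp(asm_extend_right(revcomp(contig), st))
    } else {
      contig <- st$fwd[i]     # unconfirmed read: no extension attempted
    }
    if (uniform_width && contig == st$fwd[i]) {
      ## unextended seed: the only perfect placements are its exact copies
      copies <- which(canon_read == canon_read[i])
      st$used[copies] <- TRUE
      contigs[[length(contigs) + 1L]] <- list(
        sequence = contig,
        pl = list(read = copies, start = rep(1L, length(copies)),
                  end = rep(st$lens[i], length(copies))))
    } else {
      pl <- asm_place(contig, st)
      if (length(pl$read)) st$used[unique(pl$read)] <- TRUE else st$used[i] <- TRUE
      contigs[[length(contigs) + 1L]] <- list(sequence = contig, pl = pl)
    }
  }

  finalize_contigs(contigs, st, gene)
}

## oriented read sequence for an index code (<= n: forward; > n: reversed)
asm_seq <- function(code, st) if (code <= st$n) st$fwd[code] else st$rvs[code - st$n]

## all perfect full-length placements of the bin's reads on `contig`: every
## such placement is anchored by the read's prefix k-mer at its start
asm_place <- function(contig, st) {
  clen <- nchar(contig)
  out_r <- integer(0); out_s <- integer(0); out_e <- integer(0)
  if (clen >= st$k) {
    starts <- seq_len(clen - st$k + 1L)
    keys <- substring(contig, starts, starts + st$k - 1L)
    for (p in starts) {
      for (code in st$pidx[[keys[p]]]) {
        r <- if (code <= st$n) code else code - st$n
        rl <- st$lens[r]
        if (p + rl - 1L > clen) next
        if (substr(contig, p, p + rl - 1L) == asm_seq(code, st)) {
          out_r <- c(out_r, r); out_s <- c(out_s, p); out_e <- c(out_e, p + rl - 1L)
        }
      }
    }
  }
  dup <- duplicated(paste(out_r, out_s))   # palindromic reads double-place
  list(read = out_r[!dup], start = out_s[!dup], end = out_e[!dup])
}

## extend `contig` rightward; any read (used or not) may extend.
##
## Haplotype discipline: positions where reads demonstrably disagree
## (verification failures against the seed, contested votes) are recorded as
## conflicts. When a vote is contested, the extension continues only with
## the base supported by reads anchored at or before the last conflict --
## reads that have been validated across a discriminating position and
## therefore belong to this contig's haplotype. If no such read is active,
## the junction is unresolvable by read evidence (the identical run since
## the last variant exceeds what a read spans) and the contig stops there;
## the other block assembles separately. Reads carrying a unique k-mer
## (sequencing-error signature) never vote while trusted reads are active.
asm_extend_right <- function(contig, st) {
  k <- st$k
  clen <- nchar(contig)
  a_code <- integer(0); a_off <- integer(0); a_seq <- character(0); a_ok <- logical(0)
  last_conflict <- 0L
  fail_pos <- integer(0)
  civ <- utf8ToInt(contig)
  scan_from <- max(1L, clen - st$max_read_len + 2L)
  for (p in scan_from:(clen - k + 1L)) {
    for (code in st$pidx[[substr(contig, p, p + k - 1L)]]) {
      s <- asm_seq(code, st)
      ov <- clen - p + 1L
      if (nchar(s) <= ov) next                       # contained: no extension
      if (substr(s, 1L, ov) == substr(contig, p, clen)) {
        r <- if (code <= st$n) code else code - st$n
        a_code <- c(a_code, code); a_off <- c(a_off, p)
        a_seq <- c(a_seq, s); a_ok <- c(a_ok, st$trusted[r])
      } else if (st$trusted[if (code <= st$n) code else code - st$n]) {
        ## a trusted read disagreeing with the seed: note the first
        ## mismatching base of the overlap as a candidate junction
        mm <- which(utf8ToInt(substr(s, 1L, ov)) != civ[p:clen])[1L]
        fail_pos <- c(fail_pos, p + mm - 1L)
      }
    }
  }
  ## keep only balanced disagreements as haplotype junctions: a position
  ## contradicted by a lone read pair that agrees with the consensus
  ## everywhere else (two reads sharing a coincident error) is not a variant
  for (q in unique(fail_pos)) {
    nfail <- sum(fail_pos == q)
    ncov <- sum(a_ok & a_off <= q & (a_off + nchar(a_seq) - 1L) >= q)
    if (nfail >= 2L && nfail >= 0.2 * (nfail + ncov)) {
      last_conflict <- max(last_conflict, q)
    }
  }
  while (length(a_code) && clen < st$max_contig_len) {
    ov <- clen - a_off + 1L
    bases <- substr(a_seq, ov + 1L, ov + 1L)
    elig <- if (any(a_ok)) a_ok else rep(TRUE, length(a_code))
    ub <- unique(bases[elig])
    if (length(ub) == 1L) {
      b <- ub
    } else {
      eb <- bases[elig]; eov <- ov[elig]
      counts <- vapply(ub, function(x) sum(eb == x), integer(1))
      minority <- sum(counts) - max(counts)
      if (minority < 2L || minority < 0.2 * sum(counts)) {
        ## lopsided disagreement (coincident errors, stray read): majority
        ## wins and the junction bookkeeping is left untouched
        top <- ub[counts == max(counts)]
        if (length(top) > 1L) {
          sums <- vapply(top, function(x) sum(eov[eb == x]), numeric(1))
          top <- top[sums == max(sums)]
        }
        b <- sort(top)[1L]
      } else {
        ## balanced contest -- a haplotype junction: trust only reads
        ## validated across the last junction
        anchored <- a_ok & a_off <= last_conflict
        if (!any(anchored)) break
        ab <- bases[anchored]; aov <- ov[anchored]
        cand <- unique(ab)
        vote <- vapply(cand, function(x) sum(aov[ab == x]), numeric(1))
        top <- cand[vote == max(vote)]
        if (length(top) > 1L) {
          deepest <- vapply(top, function(x) max(aov[ab == x]), numeric(1))
          top <- sort(top[deepest == max(deepest)])
        }
        b <- top[1L]
        last_conflict <- clen + 1L
      }
    }
    sel <- bases == b
    a_code <- a_code[sel]; a_off <- a_off[sel]; a_seq <- a_seq[sel]; a_ok <- a_ok[sel]
    contig <- paste0(contig, b)
    clen <- clen + 1L
    ## drop reads now fully contained
    still <- (a_off + nchar(a_seq) - 1L) > clen
    a_code <- a_code[still]; a_off <- a_off[still]
    a_seq <- a_seq[still]; a_ok <- a_ok[still]
    ## admit reads entering at overlap exactly k (prefix k-mer == contig tail)
    p <- clen - k + 1L
    for (code in st$pidx[[substr(contig, p, clen)]]) {
      s <- asm_seq(code, st)
      if (nchar(s) <= k) next
      r <- if (code <= st$n) code else code - st$n
      a_code <- c(a_code, code); a_off <- c(a_off, p)
      a_seq <- c(a_seq, s); a_ok <- c(a_ok, st$trusted[r])
    }
  }
  contig
}

## depth-annotate contigs (with cached placements), splitting at positions
## no perfectly placed read covers (every consensus base must be covered),
## then deduplicate and order canonically
finalize_contigs <- function(contigs, st, gene) {
  out <- list()
  seen <- character(0)
  todo <- contigs
  while (length(todo)) {
    item <- todo[[1L]]; todo <- todo[-1L]
    cg <- item$sequence
    if (cg %in% seen) next
    seen <- c(seen, cg)
    pl <- if (!is.null(item$pl)) item$pl else asm_place(cg, st)
    if (!length(pl$read)) next
    cov <- as.integer(IRanges::coverage(IRanges::IRanges(pl$start, pl$end),
                                        width = nchar(cg)))
    if (any(cov == 0L)) {
      r <- rle(cov > 0L)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      todo <- c(todo, lapply(substring(cg, starts[r$values], ends[r$values]),
                             function(s) list(sequence = s, pl = NULL)))
      next
    }
    out[[length(out) + 1L]] <- list(
      gene = gene, sequence = cg, depth = cov,
      support = length(unique(pl$read)),
      mean_depth = sum(cov) / nchar(cg))
  }
  seqs <- vapply(out, `[[`, character(1), "sequence")
  out <- out[!duplicated(seqs)]
  seqs <- seqs[!duplicated(seqs)]
  out <- out[order(seqs, method = "radix")]
  structure(out, class = "hla_contig_set")
}

#' @export
print.hla_contig_set <- function(x, ...) {
  cat(sprintf("<hla_contig_set> %d contig(s)\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  [%d] %s  %d bp, mean depth %.1f, support %d\n", i,
                if (is.na(x[[i]]$gene)) "" else x[[i]]$gene,
                nchar(x[[i]]$sequence), x[[i]]$mean_depth, x[[i]]$support))
  }
  invisible(x)
}

#' Filter contigs by mean coverage depth
#'
#' Contigs supported by an average read coverage depth below
#' `min_mean_depth` (default five-fold) are excluded as unreliable; contigs
#' at exactly the threshold are kept. No length filter is applied: contigs
#' of any length at five-fold or above are considered.
#'
#' @param contigs `hla_contig_set` from [assemble_bin()].
#' @param min_mean_depth minimum mean depth (default 5).
#' @return filtered `hla_contig_set`.
#' @export
filter_contigs <- function(contigs, min_mean_depth = 5) {
  assert_that(min_mean_depth >= 0, "min_mean_depth must be >= 0")
  keep <- vapply(contigs, function(cg) cg$mean_depth >= min_mean_depth, logical(1))
  structure(contigs[keep], class = "hla_contig_set")
}

#' Write contigs as FASTA (depth summary in the description line)
#' @param contigs `hla_contig_set`.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  if (!length(contigs)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(vapply(contigs, `[[`, character(1), "sequence"))
  names(x) <- vapply(seq_along(contigs), function(i) {
    cg <- contigs[[i]]
    sprintf("contig%03d gene=%s len=%d mean_depth=%.2f support=%d",
            i, cg$gene, nchar(cg$sequence), cg$mean_depth, cg$support)
  }, character(1))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export contig depth vectors as TSV
#' @param contigs `hla_contig_set`.
#' @param path output TSV (`contig`, `position`, `depth`).
#' @return `path`, invisibly.
#' @export
write_contig_depth_tsv <- function(contigs, path) {
  rows <- do.call(rbind, lapply(seq_along(contigs), function(i) {
    data.frame(contig = i, position = seq_along(contigs[[i]]$depth),
               depth = contigs[[i]]$depth)
  }))
  if (is.null(rows)) rows <- data.frame(contig = integer(0), position = integer(0),
                                        depth = integer(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
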