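## Internal short-read mapper over the comprehensive reference panel, and
## classification of reads into per-gene bins with the ambiguity-exclusion
## rule (a read perfectly matching two different genes is discarded; equal
## best scores with imperfect alignment are kept in every such gene).

MAP_DEFAULTS <- list(
  seed_len = 15L,      # exact k-mer seed length
  min_score_frac = 0.6,# hits below min_score_frac * read length are dropped
  match = 1, mismatch = -1, gap_open = -3, gap_extend = -1
)

#' Mapping parameters
#'
#' @param seed_len exact k-mer seed length (default 15).
#' @param min_score_frac minimum alignment score as a fraction of read
#'   length (default 0.6). Scoring is end-to-end over the read: match +1,
#'   mismatch -1, affine gaps (open -3, extend -1).
#' @param ... override `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @return list of mapping parameters.
#' @export
mapping_params <- function(seed_len = 15L, min_score_frac = 0.6, ...) {
  p <- utils::modifyList(MAP_DEFAULTS,
                         c(list(seed_len = as.integer(seed_len),
                                min_score_frac = min_score_frac), list(...)))
  p
}

#' Build a reusable mapping index over a CRP
#'
#' Indexes every `seed_len`-mer of every panel entry (forward strand) in a
#' hash map from k-mer to global positions in the concatenated panel.
#' Building once and passing the index to [classify_reads()] amortises the
#' cost across samples typed against the same panel.
#'
#' @param crp panel from [build_crp()].
#' @param params from [mapping_params()].
#' @return opaque index object (class `hla_map_index`).
#' @export
build_read_index <- function(crp, params = mapping_params()) {
  assert_that(inherits(crp, "hla_crp") && nrow(crp) > 0L, "panel must be non-empty")
  k <- params$seed_len
  lens <- nchar(crp$sequence)
  offsets <- c(0L, cumsum(lens))[seq_len(nrow(crp))]  # 0-based entry offsets
  bigseq <- paste(crp$sequence, collapse = "")
  kmers <- character(0); gpos <- integer(0)
  for (i in seq_len(nrow(crp))) {
    km <- seq_kmers(crp$sequence[i], k)
    if (length(km)) {
      kmers <- c(kmers, km)
      gpos <- c(gpos, offsets[i] + seq_along(km))  # 1-based global positions
    }
  }
  idx <- new.env(parent = emptyenv(), size = length(kmers))
  sp <- split(gpos, kmers)
  list2env(sp, idx)
  structure(list(index = idx, k = k, crp = crp, lens = lens, offsets = offsets,
                 bigseq = bigseq,
                 entry_starts = offsets + 1L,
                 entry_ends = offsets + lens,
                 params = params),
            class = "hla_map_index")
}

## candidate global read-start positions from seed hits for one oriented
## read sequence; returns integer vector of global starts, filtered so the
## read lies entirely within a single entry
seed_candidates <- function(seqchr, mi) {
  k <- mi$k
  n <- nchar(seqchr)
  if (n < k) return(integer(0))
  seed_starts <- unique(c(seq(1L, n - k + 1L, by = k), n - k + 1L))
  cand <- integer(0)
  for (s in seed_starts) {
    km <- substr(seqchr, s, s + k - 1L)
    hit <- mi$index[[km]]
    if (!is.null(hit)) cand <- c(cand, hit - (s - 1L))
  }
  if (!length(cand)) return(integer(0))
  cand <- unique(cand)
  cand <- cand[cand >= 1L]
  entry <- findInterval(cand, mi$entry_starts)
  ok <- entry >= 1L & (cand + n - 1L) <= mi$entry_ends[entry]
  cand[ok]
}

## ungapped end-to-end hits of one oriented read at candidate global
## `starts`: data.frame(entry, score, mismatches, perfect)
ungapped_hits <- function(seqchr, mi, min_score, starts) {
  if (!length(starts)) return(NULL)
  n <- nchar(seqchr)
  riv <- utf8ToInt(seqchr)
  mm <- vapply(starts, function(gs) {
    sum(utf8ToInt(substr(mi$bigseq, gs, gs + n - 1L)) != riv)
  }, integer(1))
  score <- mi$params$match * (n - mm) + mi$params$mismatch * mm
  keep <- score >= min_score
  if (!any(keep)) return(NULL)
  entry <- findInterval(starts[keep], mi$entry_starts)
  list(entry = entry, start = starts[keep] - mi$offsets[entry],
       score = score[keep], mismatches = mm[keep],
       perfect = mm[keep] == 0L)
}

## affine-gap rescue for candidate entries whose ungapped score missed the
## threshold (read may carry indels); end-to-end over the read
gapped_hits <- function(seqchr, entries, mi, min_score) {
  if (!length(entries)) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = mi$params$match,
                                                  mismatch = mi$params$mismatch)
  out <- NULL
  for (e in entries) {
    al <- Biostrings::pairwiseAlignment(
      pattern = seqchr, subject = mi$crp$sequence[e], type = "global-local",
      substitutionMatrix = mat,
      gapOpening = abs(mi$params$gap_open), gapExtension = abs(mi$params$gap_extend))
    sc <- Biostrings::score(al)
    if (sc >= min_score) {
      h <- list(entry = e, start = Biostrings::start(Biostrings::subject(al)),
                score = sc,
                mismatches = Biostrings::nmismatch(al) +
                  Biostrings::nindel(al)@insertion[1L] +
                  Biostrings::nindel(al)@deletion[1L],
                perfect = FALSE)
      out <- if (is.null(out)) h else Map(c, out, h)
    }
  }
  out
}

#' Map one read against the panel
#'
#' Seed-and-extend: exact `seed_len`-mer seeds locate candidate end-to-end
#' placements on both strands, each verified by mismatch counting; when a
#' seeded entry has no ungapped placement above threshold, a banded
#' global-local affine-gap alignment is tried. Returns all placements with
#' score at least `min_score_frac * read length`; perfect means a
#' full-length zero-mismatch match.
#'
#' @param sequence read sequence (character).
#' @param index from [build_read_index()] (or an `hla_crp`, indexed on the
#'   fly).
#' @param params from [mapping_params()]; ignored when `index` is prebuilt.
#' @param rc optional precomputed reverse complement of `sequence`.
#' @return data.frame of hits: `entry` (row in the CRP), `gene`, `role`,
#'   `start` (1-based in the entry), `score`, `mismatches`, `perfect`,
#'   `strand`. Zero rows when nothing reaches the threshold; reads shorter
#'   than the seed length yield zero rows with a warning.
#' @export
map_read <- function(sequence, index, params = mapping_params(), rc = NULL) {
  if (inherits(index, "hla_crp")) index <- build_read_index(index, params)
  mi <- index
  n <- nchar(sequence)
  empty <- data.frame(entry = integer(0), gene = character(0), role = character(0),
                      start = integer(0), score = numeric(0), mismatches = integer(0),
                      perfect = logical(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (n < mi$k) {
    warning("read shorter than seed length; unmapped", call. = FALSE)
    return(empty)
  }
  if (is.null(rc)) rc <- revcomp(sequence)
  min_score <- mi$params$min_score_frac * n
  hits <- NULL
  strands <- character(0)
  cand_by_strand <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else rc
    starts <- seed_candidates(s, mi)
    cand_by_strand[[strand]] <- unique(findInterval(starts, mi$entry_starts))
    h <- ungapped_hits(s, mi, min_score, starts)
    if (!is.null(h)) {
      strands <- c(strands, rep(strand, length(h$entry)))
      hits <- if (is.null(hits)) h else Map(c, hits, h)
    }
  }
  if (is.null(hits)) {
    ## gapped rescue (read may carry indels): tried only when no ungapped
    ## placement reaches the threshold anywhere
    for (strand in c("+", "-")) {
      s <- if (strand == "+") sequence else rc
      hg <- gapped_hits(s, cand_by_strand[[strand]], mi, min_score)
      if (!is.null(hg)) {
        strands <- c(strands, rep(strand, length(hg$entry)))
        hits <- if (is.null(hits)) hg else Map(c, hits, hg)
      }
    }
  }
  if (is.null(hits) || !length(hits$entry)) return(empty)
  hits <- data.frame(entry = hits$entry, start = hits$start, score = hits$score,
                     mismatches = hits$mismatches, perfect = hits$perfect,
                     strand = strands, stringsAsFactors = FALSE)
  ## keep best-scoring hits plus all perfect hits
  keep <- hits$perfect | hits$score == max(hits$score)
  hits <- hits[keep, , drop = FALSE]
  ## one placement per entry (best score, then leftmost)
  hits <- hits[order(hits$entry, -hits$score, hits$start), , drop = FALSE]
  hits <- hits[!duplicated(hits$entry), , drop = FALSE]
  hits$gene <- mi$crp$gene[hits$entry]
  hits$role <- mi$crp$role[hits$entry]
  rownames(hits) <- NULL
  hits[, c("entry", "gene", "role", "start", "score", "mismatches", "perfect", "strand")]
}

#' Read a FASTQ file into the internal read representation
#'
#' @param path FASTQ path (plain or gzipped). A second path may be given for
#'   the mate file of a pair; mates are classified independently.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  out <- NULL
  for (p in path) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    out <- rbind(out, data.frame(
      id = sub("\\s.*$", "", names(x)),
      sequence = as.character(x),
      quality = as.character(S4Vectors::mcols(x)$qualities),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Write reads as FASTQ
#' @param reads data.frame with `id`, `sequence` and optionally `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  q <- if (!is.null(reads$quality)) Biostrings::BStringSet(reads$quality) else
    Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

## batch perfect-placement pass: every zero-mismatch full-length placement
## is anchored by the read's first k-mer, so one index lookup plus direct
## string comparison per candidate finds them all. Returns
## data.frame(read, entry, start, strand).
batch_perfect_hits <- function(seqs, mi, rc = revcomp(seqs)) {
  k <- mi$k
  out_read <- integer(0); out_entry <- integer(0)
  out_start <- integer(0); out_strand <- character(0)
  for (i in seq_along(seqs)) {
    w <- nchar(seqs[i])
    if (w < k) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[i] else rc[i]
      cand <- mi$index[[substr(s, 1L, k)]]
      for (gs in cand) {
        entry <- findInterval(gs, mi$entry_starts)
        if (gs + w - 1L > mi$entry_ends[entry]) next
        if (substr(mi$bigseq, gs, gs + w - 1L) == s) {
          out_read <- c(out_read, i); out_entry <- c(out_entry, entry)
          out_start <- c(out_start, gs - mi$offsets[entry])
          out_strand <- c(out_strand, strand)
        }
      }
    }
  }
  if (!length(out_read)) return(NULL)
  data.frame(read = out_read, entry = out_entry, start = out_start,
             strand = out_strand, stringsAsFactors = FALSE)
}

#' Classify reads into per-gene bins
#'
#' Applies the ambiguity-exclusion rule: a read with perfect (full-length,
#' zero-mismatch) matches in two or more distinct genes is excluded; a read
#' perfect in exactly one gene is binned there; otherwise the read is binned
#' into every gene holding one of its best-scoring imperfect hits (this
#' level of similarity is expected between HLA paralogs). Reads whose hits
#' are confined to competitor genes are absorbed (dropped); competitor genes
#' never receive bins.
#'
#' @param reads data.frame with `id` and `sequence` (see [read_fastq()]).
#' @param index [build_read_index()] result (or an `hla_crp`).
#' @param params [mapping_params()]; ignored when `index` is prebuilt.
#' @return list with
#'   * `bins`: named list (gene) of data.frames `id`, `sequence` (oriented to
#'     the reference strand), `entry`, `start` of the read's best placement
#'     in that gene;
#'   * `stats`: counts `total`, `binned`, `ambiguous`, `competitor_only`,
#'     `unmapped`, `too_short`.
#' @export
classify_reads <- function(reads, index, params = mapping_params()) {
  if (inherits(index, "hla_crp")) index <- build_read_index(index, params)
  mi <- index
  n <- nrow(reads)
  stats <- c(total = n, binned = 0L, ambiguous = 0L, competitor_only = 0L,
             unmapped = 0L, too_short = 0L)
  bins <- list()
  if (n == 0L) return(list(bins = bins, stats = stats))
  assert_that(!anyDuplicated(reads$id), "read ids must be unique")

  widths <- nchar(reads$sequence)
  short <- widths < mi$k
  stats["too_short"] <- sum(short)
  if (any(short)) warning(sprintf("%d read(s) shorter than the seed length", sum(short)),
                          call. = FALSE)

  rc_all <- revcomp(reads$sequence)
  perf <- batch_perfect_hits(reads$sequence[!short], mi, rc_all[!short])
  if (!is.null(perf)) perf$read <- which(!short)[perf$read]

  add_to_bin <- list()  # per read: data.frame(gene, entry, start, strand)
  ambiguous <- logical(n); comp_only <- logical(n); unmapped <- logical(n)

  resolved <- rep(FALSE, n)
  if (!is.null(perf) && nrow(perf)) {
    perf$gene <- mi$crp$gene[perf$entry]
    perf$role <- mi$crp$role[perf$entry]
    for (grp in split(seq_len(nrow(perf)), perf$read)) {
      r <- perf$read[grp[1L]]
      genes <- unique(perf$gene[grp])
      resolved[r] <- TRUE
      if (length(genes) >= 2L) {
        ambiguous[r] <- TRUE
      } else if (all(perf$role[grp] == "competitor")) {
        comp_only[r] <- TRUE
      } else {
        add_to_bin[[as.character(r)]] <- perf[grp[1L], c("gene", "entry", "start", "strand")]
      }
    }
  }

  ## remaining reads: full seed-and-extend mapping
  todo <- which(!resolved & !short)
  for (r in todo) {
    hits <- map_read(reads$sequence[r], mi, rc = rc_all[r])
    if (!nrow(hits)) { unmapped[r] <- TRUE; next }
    ## no perfect hits here by construction: best-score-per-gene rule on
    ## integer-rounded scores (avoids float ties)
    rs <- round(hits$score)
    gene_best <- tapply(rs, hits$gene, max)
    top_genes <- names(gene_best)[gene_best == max(gene_best)]
    hb <- hits[hits$gene %in% top_genes & rs == max(gene_best), , drop = FALSE]
    tg <- hb[hb$role == "target", , drop = FALSE]
    if (!nrow(tg)) { comp_only[r] <- TRUE; next }
    ## best placement per gene
    tg <- tg[order(tg$gene, -tg$score, tg$entry), , drop = FALSE]
    tg <- tg[!duplicated(tg$gene), , drop = FALSE]
    add_to_bin[[as.character(r)]] <- tg[, c("gene", "entry", "start", "strand")]
  }

  stats["ambiguous"] <- sum(ambiguous)
  stats["competitor_only"] <- sum(comp_only)
  stats["unmapped"] <- sum(unmapped) + stats[["too_short"]]
  stats["binned"] <- length(add_to_bin)

  if (length(add_to_bin)) {
    placed <- do.call(rbind, lapply(names(add_to_bin), function(rn) {
      d <- add_to_bin[[rn]]; d$read <- as.integer(rn); d
    }))
    oriented <- ifelse(placed$strand == "+", reads$sequence[placed$read],
                       rc_all[placed$read])
    placed$id <- reads$id[placed$read]
    placed$sequence <- oriented
    for (g in sort(unique(placed$gene))) {
      d <- placed[placed$gene == g, c("id", "sequence", "entry", "start", "strand")]
      d <- d[!duplicated(d$id), , drop = FALSE]
      rownames(d) <- NULL
      bins[[g]] <- d
    }
  }
  list(bins = bins, stats = stats)
}
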