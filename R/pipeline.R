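## Orchestration: reference building, full per-sample typing, and report
## emission. Stage order: classify -> assemble -> depth filter -> match(mDB)
## -> score -> designate -> resolve(aDB) -> phase -> QC gating.

#' Build all reference structures from an allele set
#'
#' @param records allele records ([read_allele_set()]).
#' @param target_genes genes to type; defaults to every non-competitor gene.
#' @param competitor_genes mapping-competitor genes (absorb paralog reads).
#' @param flank_len intron flank length for the mapping panel (default 50).
#' @param params [mapping_params()].
#' @return list of class `hla_reference`: `crp`, `mdb`, `adb`, `index`,
#'   `target_genes`, `competitor_genes`, `flank_len`.
#' @export
build_reference <- function(records, target_genes = NULL,
                            competitor_genes = character(0),
                            flank_len = 50L, params = mapping_params()) {
  genes <- unique(vapply(records, `[[`, character(1), "gene"))
  if (is.null(target_genes)) target_genes <- setdiff(genes, competitor_genes)
  crp <- build_crp(records, target_genes, competitor_genes, flank_len)
  dbs <- build_exact_dbs(records[vapply(records, `[[`, character(1), "gene")
                                 %in% target_genes])
  structure(list(crp = crp, mdb = dbs$mdb, adb = dbs$adb,
                 index = build_read_index(crp, params),
                 target_genes = target_genes,
                 competitor_genes = competitor_genes,
                 flank_len = as.integer(flank_len)),
            class = "hla_reference")
}

#' @export
print.hla_reference <- function(x, ...) {
  cat(sprintf("<hla_reference> %d target gene(s), %d competitor(s), %d panel entries\n",
              length(x$target_genes), length(x$competitor_genes), nrow(x$crp)))
  invisible(x)
}

#' Type a sample's reads against a reference
#'
#' Runs the full stepwise typing process for every target gene and returns
#' one call per gene plus classification statistics. A gene with an empty
#' read bin, or failing coverage QC with only a single designated allele
#' (possible allele dropout), is reported as a no-call, never an error.
#'
#' @param reads data.frame `id`, `sequence` (see [read_fastq()]).
#' @param reference from [build_reference()].
#' @param freq named population-frequency vector (optional).
#' @param min_overlap assembly/matching overlap (default 20).
#' @param min_mean_depth contig depth filter (default 5).
#' @param read_length read length for the phase rule; default: median
#'   observed.
#' @return object of class `hla_typing_report`: `calls` (named list of
#'   `hla_typing_call`), `stats`, `parameters`.
#' @export
hla_type <- function(reads, reference, freq = NULL, min_overlap = 20L,
                     min_mean_depth = 5, read_length = NULL) {
  assert_that(inherits(reference, "hla_reference"), "reference must come from build_reference()")
  if (is.null(read_length) && nrow(reads) > 0L) {
    read_length <- as.integer(stats::median(nchar(reads$sequence)))
  }
  cls <- classify_reads(reads, reference$index)
  calls <- list()
  for (gene in sort(reference$target_genes)) {
    bin <- cls$bins[[gene]]
    qc <- coverage_profile(bin, reference$crp, gene)
    if (is.null(bin) || nrow(bin) == 0L) {
      call <- new_typing_call(gene)
      call$no_call <- TRUE
      call$diagnostic <- "no reads classified to this gene"
      call$qc <- qc
      calls[[gene]] <- call
      next
    }
    contigs <- assemble_bin(bin, min_overlap = min_overlap, gene = gene)
    kept <- filter_contigs(contigs, min_mean_depth)
    mm <- match_contigs(kept, reference$mdb, gene, min_overlap, reference$flank_len)
    sc <- score_alleles(mm$matches, kept)
    call <- designate_alleles(sc, mm$matches, freq, gene, db = reference$mdb)
    call$qc <- qc
    call <- resolve_minor_exons(call, kept, reference$adb, min_overlap,
                                reference$flank_len)
    ## novel-allele documentation: high-depth contigs matching neither database
    am <- match_contigs(kept, reference$adb, gene, min_overlap, reference$flank_len)
    call$novel_contigs <- intersect(mm$unmatched, am$unmatched)
    if (length(call$alleles) == 2L && !is.null(read_length)) {
      call <- detect_phase_ambiguity(call, reference$mdb, read_length, freq)
    }
    ## QC gating: a lone designation under failed QC is a possible dropout
    if (length(call$alleles) == 1L && !qc_passed(qc)) {
      call$homozygous <- FALSE
      call$no_call <- TRUE
      call$diagnostic <- "possible allele dropout: single designation under failed coverage QC"
    }
    attr(call, "contigs") <- kept
    calls[[gene]] <- call
  }
  structure(list(calls = calls, stats = cls$stats,
                 parameters = list(min_overlap = min_overlap,
                                   min_mean_depth = min_mean_depth,
                                   read_length = read_length,
                                   flank_len = reference$flank_len)),
            class = "hla_typing_report")
}

#' @export
print.hla_typing_report <- function(x, ...) {
  cat(sprintf("<hla_typing_report> %d gene(s); reads: %d total, %d binned, %d ambiguous, %d competitor, %d unmapped\n",
              length(x$calls), x$stats[["total"]], x$stats[["binned"]],
              x$stats[["ambiguous"]], x$stats[["competitor_only"]],
              x$stats[["unmapped"]]))
  for (call in x$calls) print(call)
  invisible(x)
}

#' Flatten a typing report to a data.frame (one row per gene)
#' @param report `hla_typing_report`.
#' @return data.frame with allele labels, resolution, flags and QC tier.
#' @export
report_table <- function(report) {
  rows <- lapply(report$calls, function(call) {
    data.frame(
      gene = call$gene,
      allele1 = if (length(call$alleles) >= 1L) call$alleles[1L] else NA_character_,
      allele2 = if (length(call$alleles) >= 2L) call$alleles[2L]
                else if (call$homozygous) call$alleles[1L] else NA_character_,
      resolution = paste(unname(call$resolution), collapse = ";"),
      homozygous = call$homozygous,
      no_call = call$no_call,
      phase_ambiguous = call$phase_ambiguous,
      phase_pairs = paste(vapply(call$phase_pairs, paste, character(1),
                                 collapse = "/"), collapse = " | "),
      extra_alleles = paste(names(call$extra_alleles), collapse = ";"),
      n_novel_contigs = length(call$novel_contigs),
      qc_tier = if (!is.null(call$qc)) call$qc$tier else NA_character_,
      qc_warning = if (!is.null(call$qc)) call$qc$warning else NA,
      diagnostic = call$diagnostic,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a typing report as TSV and JSON
#'
#' @param report `hla_typing_report`.
#' @param tsv,json output paths (either may be `NULL`).
#' @return invisibly, the report table.
#' @export
write_typing_report <- function(report, tsv = NULL, json = NULL) {
  tab <- report_table(report)
  if (!is.null(tsv)) {
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(
      stats = as.list(report$stats),
      parameters = report$parameters,
      calls = lapply(report$calls, function(call) {
        list(gene = call$gene, alleles = call$alleles,
             resolution = as.list(call$resolution),
             homozygous = call$homozygous, no_call = call$no_call,
             diagnostic = call$diagnostic,
             phase_ambiguous = call$phase_ambiguous,
             phase_pairs = call$phase_pairs,
             extra_alleles = call$extra_alleles,
             novel_contigs = call$novel_contigs,
             scores = if (!is.null(call$scores)) as.data.frame(call$scores) else NULL,
             qc = if (!is.null(call$qc)) {
               list(tier = call$qc$tier, frac_ge_10x = call$qc$frac_ge_10x,
                    frac_ge_20x = call$qc$frac_ge_20x, warning = call$qc$warning,
                    per_exon = call$qc$per_exon)
             } else NULL)
      }))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(tab)
}

#' Run the full pipeline from files
#'
#' Thin orchestration over [build_reference()], [read_fastq()] and
#' [hla_type()]: reads the allele set, frequency table and FASTQ, types the
#' sample and writes the reports into `out_dir`.
#'
#' @param allele_set FASTA path (see [read_allele_set()]).
#' @param fastq FASTQ path(s).
#' @param frequency_table optional TSV path.
#' @param out_dir output directory (created if missing); `NULL` for no files.
#' @param target_genes,competitor_genes gene sets (defaults: all/none).
#' @param flank_len,min_overlap,min_mean_depth pipeline parameters (defaults
#'   50, 20, 5).
#' @return the `hla_typing_report`, invisibly. Attribute `"ok"` is `FALSE`
#'   when any gene is a no-call.
#' @export
run_pipeline <- function(allele_set, fastq, frequency_table = NULL,
                         out_dir = NULL, target_genes = NULL,
                         competitor_genes = character(0), flank_len = 50L,
                         min_overlap = 20L, min_mean_depth = 5) {
  records <- read_allele_set(allele_set)
  freq <- if (!is.null(frequency_table)) read_frequency_table(frequency_table) else NULL
  reference <- build_reference(records, target_genes, competitor_genes, flank_len)
  reads <- read_fastq(fastq)
  report <- hla_type(reads, reference, freq, min_overlap, min_mean_depth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_typing_report(report,
                        tsv = file.path(out_dir, "typing_report.tsv"),
                        json = file.path(out_dir, "typing_report.json"))
    for (gene in names(report$calls)) {
      contigs <- attr(report$calls[[gene]], "contigs")
      if (!is.null(contigs) && length(contigs)) {
        write_contigs_fasta(contigs, file.path(out_dir, paste0(gene, ".contigs.fasta")))
      }
    }
  }
  attr(report, "ok") <- !any(vapply(report$calls, `[[`, logical(1), "no_call"))
  invisible(report)
}
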