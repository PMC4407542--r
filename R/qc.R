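## Per-exon coverage profiles over the targeted exons and the quality tiers
## used to gate calls. Depth is computed from raw read placements (each
## binned read's best placement, projected into exon coordinates), so QC is
## available even when typing makes no call.

QC_TIERS <- c("10x=100% & 20x>=98%", "10x=100% & 20x>=90%", "10x>=95%", "fail")

#' Coverage profile and quality tier for one gene
#'
#' Depth at each exonic position is the number of binned reads whose best
#' placement covers it. The overall fractions (and hence the tier and the
#' warning flag) are computed over the gene's major polymorphic exons -- the
#' exons that determine the four-digit call; per-exon statistics are
#' reported for every targeted exon. Thresholds are inclusive (`>= 10x`,
#' `>= 20x`). The warning flag is raised when more than 2% of the exonic
#' positions have depth below 20-fold; `recommend_more_depth` is raised when
#' any position is below the recommended 30-fold.
#'
#' @param bin per-gene read bin from [classify_reads()] (placement columns
#'   `entry`, `start` required); `NULL` or empty yields a failed report.
#' @param crp the mapping panel ([build_crp()]).
#' @param gene gene symbol.
#' @return object of class `hla_qc`: fields `gene`, `per_exon` (data.frame
#'   `exon`, `length`, `frac_ge_10x`, `frac_ge_20x`, `min_depth`,
#'   `mean_depth`), `frac_ge_10x`, `frac_ge_20x` (major exons), `tier`,
#'   `warning`, `recommend_more_depth`.
#' @export
coverage_profile <- function(bin, crp, gene) {
  exons <- sort(unique(crp$exon[crp$gene == gene]))
  assert_that(length(exons) > 0L, sprintf("gene %s has no panel entries", gene))
  major <- targeted_exons(gene, "major")

  per_exon <- data.frame(exon = exons, length = NA_integer_,
                         frac_ge_10x = 0, frac_ge_20x = 0,
                         min_depth = 0L, mean_depth = 0)
  depth_by_exon <- list()
  for (j in seq_along(exons)) {
    e <- exons[j]
    sel <- crp$gene == gene & crp$exon == e
    elen <- max(crp$exon_end[sel] - crp$exon_start[sel] + 1L)
    per_exon$length[j] <- elen
    depth_by_exon[[as.character(e)]] <- integer(elen)
  }

  if (!is.null(bin) && nrow(bin) > 0L) {
    width <- nchar(bin$sequence)
    e_of <- crp$exon[bin$entry]
    exs <- crp$exon_start[bin$entry]
    exe <- crp$exon_end[bin$entry]
    ## read interval intersected with the exon span, in exon coordinates
    s <- pmax(bin$start, exs) - exs + 1L
    e <- pmin(bin$start + width - 1L, exe) - exs + 1L
    ok <- s <= e
    for (j in seq_along(exons)) {
      ex <- exons[j]
      sel <- which(ok & e_of == ex)
      if (!length(sel)) next
      elen <- per_exon$length[j]
      cov <- as.integer(IRanges::coverage(
        IRanges::IRanges(s[sel], pmin(e[sel], elen)), width = elen))
      depth_by_exon[[as.character(ex)]] <- cov
    }
  }

  for (j in seq_along(exons)) {
    d <- depth_by_exon[[as.character(exons[j])]]
    per_exon$frac_ge_10x[j] <- mean(d >= 10L)
    per_exon$frac_ge_20x[j] <- mean(d >= 20L)
    per_exon$min_depth[j] <- min(d)
    per_exon$mean_depth[j] <- mean(d)
  }

  md <- unlist(depth_by_exon[as.character(major)], use.names = FALSE)
  if (is.null(md)) md <- integer(0)
  f10 <- if (length(md)) mean(md >= 10L) else 0
  f20 <- if (length(md)) mean(md >= 20L) else 0
  tier <- if (f10 == 1 && f20 >= 0.98) QC_TIERS[1L]
          else if (f10 == 1 && f20 >= 0.90) QC_TIERS[2L]
          else if (f10 >= 0.95) QC_TIERS[3L]
          else QC_TIERS[4L]
  structure(list(gene = gene, per_exon = per_exon,
                 frac_ge_10x = f10, frac_ge_20x = f20, tier = tier,
                 warning = (length(md) == 0L) || mean(md < 20L) > 0.02,
                 recommend_more_depth = (length(md) == 0L) || any(md < 30L),
                 depth = depth_by_exon),
            class = "hla_qc")
}

#' @export
print.hla_qc <- function(x, ...) {
  cat(sprintf("<hla_qc> %s: tier '%s'  10x %.1f%%  20x %.1f%%%s\n", x$gene,
              x$tier, 100 * x$frac_ge_10x, 100 * x$frac_ge_20x,
              if (x$warning) "  [warning: >2% of exonic positions <20x]" else ""))
  invisible(x)
}

qc_passed <- function(qc) !is.null(qc) && qc$tier != "fail"

#' Write per-position depth as TSV
#' @param qc `hla_qc` object.
#' @param path output TSV (`gene`, `exon`, `position`, `depth`).
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(qc, path) {
  rows <- do.call(rbind, lapply(names(qc$depth), function(e) {
    d <- qc$depth[[e]]
    data.frame(gene = qc$gene, exon = as.integer(e),
               position = seq_along(d), depth = d)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
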