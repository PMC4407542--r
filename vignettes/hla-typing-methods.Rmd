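---
title: "Typing HLA alleles from short reads: the model behind hlatyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing HLA alleles from short reads: the model behind hlatyper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlatyper)
```

## The problem

The classical HLA loci (class I: HLA-A, -B, -C; class II: HLA-DRB1, -DQB1,
-DQA1, ...) are the most polymorphic genes in the human genome: hundreds to
thousands of named alleles per locus, differing by dense substitution
patterns concentrated in the antigen-binding exons (exons 2 and 3 for class
I, exon 2 for class II), with strong sequence similarity between paralogous
loci. Standard resequencing workflows map reads against a single reference
haplotype, which silently loses reads from the allele the reference does not
carry, and a single mismatch distinguishes alleles that differ in peptide
binding. `hlatyper` types a sample's two alleles per locus at high digit
resolution from ordinary whole-exome (WES) or whole-genome (WGS) short
reads.

## The method

The pipeline is a strict exact-match design: tolerate nothing at the two
places where errors could masquerade as alleles, and push all error
tolerance into read classification, where it is harmless.

1. **Classification against a comprehensive reference panel (CRP).** The
   panel holds, for *every known allele*, each targeted exon extended by up
   to 50 bp of flanking intron (so reads hanging off an exon edge are still
   captured), plus all alleles of a set of minor-gene "mapping competitors"
   whose only job is to absorb reads from paralogous loci. The internal
   mapper is seed-and-extend: exact 15-mer seeds, end-to-end scoring over
   the read (match +1, mismatch -1, affine gaps -3/-1), hits below 0.6
   x read length discarded. A read with perfect (full-length, zero-mismatch)
   hits in two *different* genes is excluded as inherently ambiguous; a read
   perfect in exactly one gene is binned there; a read with equal imperfect
   best scores in several genes is binned into all of them, since that level
   of similarity is expected among HLA genes. Reads landing only on
   competitors are dropped.

2. **Zero-mismatch assembly.** Each gene's bin is assembled greedily into
   contigs admitting only overlaps of at least 20 bp with 100% identity, so
   a sequencing error can never alter a consensus base: a disagreeing read
   is simply rejected (and remains available to seed or join another contig
   — this is what separates the two haplotypes of a heterozygote). Per-base
   depth counts every read that places perfectly inside the contig.
   Contigs with mean depth below five-fold are discarded as unreliable; no
   length filter is applied.

3. **Stepwise allele matching.** Contigs are matched, exactly and on the
   exonic region only (intron overhang up to the 50 bp flank is ignored),
   first against the major database (mDB: all alleles' major exons, with
   alleles identical across their major exons collapsed into G-groups named
   by their lexicographically smallest member truncated to three fields plus
   `G`), then against the additional database (aDB: minor exons — exon 4
   for class I, exon 3 for class II). The score of a contig towards an
   allele is contig length x mean depth x exonic fraction; an allele's
   score is the sum over its contigs. Walking candidates by descending
   score, an allele is designated when it owns a uniquely matched,
   not-yet-assigned contig; the walk stops at two designations, and later
   candidates that would qualify are documented as possible contamination
   (a third or fourth allele). A single designation explaining every contig
   is reported homozygous — but only under passing coverage QC; otherwise
   it becomes an allele-dropout no-call.

4. **Minor-exon resolution.** A designated G-group is upgraded to a
   six-digit call when the minor-exon contigs retain exactly one member
   sequence class. Two safeguards matter in practice: a match only counts
   if it covers at least one position where the members' minor exons
   actually differ (a fragment from a shared stretch matches every member
   and proves nothing), and contigs already explained by the partner
   designation are not evidence (a fragment of the partner's minor exon can
   coincide with the wrong member over a shared run). Intronic evidence is
   out of scope, so eight-digit resolution is never claimed.

5. **Phase ambiguity.** With reads of length $L$, two heterozygous variant
   blocks separated by an identical run longer than $L$ cannot be phased:
   swapping the blocks between haplotypes is consistent with every read. The
   caller enumerates such block swaps over the designated pair's major
   exons (blocks on different exons are never linked, contigs being
   per-exon) and reports an alternative pair whenever a recombined
   haplotype spells another database allele; the partner may be a known
   allele or an `unknown` placeholder. The reported pair is the one with
   the highest population frequency (pair ranked by summed member
   frequency, then maximum, then label; unknown frequencies count as
   zero), with all alternatives listed.

6. **Coverage QC.** Depth at every targeted exon position is computed from
   the binned reads' best placements (so QC exists even for no-calls) and
   summarized over the major exons into tiers: `10x=100% & 20x>=98%`,
   `10x=100% & 20x>=90%`, `10x>=95%`, or fail. Thresholds are inclusive on
   integer depths. Any call with more than 2% of exonic positions below
   20-fold carries a warning flag, and a separate flag recommends more
   depth whenever any position is below the recommended 30-fold.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flank_len` | 50 bp | intron flank on panel entries; also the maximum ignored contig overhang |
| `seed_len` | 15 bp | exact k-mer seed for mapping |
| `min_score_frac` | 0.6 | end-to-end score floor as fraction of read length |
| `min_overlap` | 20 bp | minimum exact overlap in assembly and contig matching |
| `min_mean_depth` | 5x | contig mean-depth filter |
| `read_length` | observed | the phase-linkage threshold |

The 50 bp flank, the five-fold contig filter, the 2% warning rule and the
30-fold recommendation are the method's fixed constants; the seed length,
score floor and overlap are implementation choices of the internal mapper
and assembler (the overlap threshold balances chimera risk against
fragmentation at 100 bp reads).

## Assembly design notes

The assembler is deliberately conservative about two things.

*Error discipline.* A read whose k-mer spectrum contains a k-mer seen only
once in the bin, strictly between multiply-seen k-mers, is treated as
error-tainted: it can neither seed a contig nor vote on a consensus base
(it still counts towards depth wherever it places perfectly, which for an
erroneous read is nowhere). Unique k-mers confined to a read's end are the
normal signature of the outermost read of a region and do not discredit it
— that read may still vote and extend a contig into single-coverage
territory. Founding a *new* contig is stricter still: only reads whose
every k-mer is seen at least twice may seed an extension, because an error
within one k-mer length of a read's end is indistinguishable from a
coverage boundary, and a seed's content cannot be out-voted. Unjoined
reads become single-read contigs and die at the five-fold filter.

*Junction discipline.* When the next base is contested between reads, the
extension trusts only reads that have been validated across the most recent
*conflict position* — a position where a substantial minority of reads
(at least two, and at least 20% of local coverage) demonstrably disagrees
with the consensus, i.e. a heterozygous site rather than a coincidental
shared error. If no active read spans back to that position, no read
evidence links the two sides and the contig honestly stops; the far block
assembles separately, and exact matching of both fragments still designates
the right alleles. A chimeric joint is therefore only possible in the
regime the phase machinery flags anyway. Lopsided disagreements (a lone
read, or a pair of reads sharing a coincident error) are resolved to the
majority without disturbing the junction bookkeeping.

## What the simulator emulates

`make_mock_alleles()` builds a mock IMGT-like database: class-appropriate
exon/intron structure (exons 250-300 bp, introns 150 bp), per-allele exon
substitution at 2% (at least one substitution per exon — HLA antigen-binding
exons are hyperpolymorphic), planted G-groups (major exons copied from a
founder, minor exon mutated), competitor genes derived from a paralog
target at 6% divergence, Dirichlet population frequencies, and a fraction
of alleles stored without intron sequence so the panel must borrow flanks
from a sibling. The *database view* and the *genomic view* are returned
separately: reads are always simulated from the complete genomic records,
while the pipeline only ever sees the (possibly intron-less) database
records, exactly as with a real reference database.

`simulate_reads()` draws uniform reads (default 100 bp) over each genotype
allele's targeted exons +/- 50 bp (WES mode, emulating capture) or over the
whole record (WGS mode), splits them by allelic balance, flips a fair coin
for strand, and injects substitution errors at 0.5% per base. Indels, GC
bias, quality-score profiles and capture-affinity variation are *not*
modelled: the assembly stage is defined on mismatch-free overlaps, so the
substitution-only model exercises every decision path of the method, but
passing tests say nothing about indel-rich platforms or strongly biased
capture chemistry.

Coverage semantics: `coverage` is the depth at region-interior positions
(read counts are calibrated so the plateau of the sequenced region equals
the target, and the realized mean over an exon lands within 15% of it).
Positions within a read length of a region edge receive proportionally
less — in WES mode because capture windows end 50 bp beyond the exon, in
WGS mode because only reads falling entirely within the 50 bp flank window
are mappable — so both modes deliver the same on-target profile at equal
nominal coverage. The default of 40x was chosen to sit comfortably above
the method's 30-fold on-every-location recommendation: at 30x nominal the
exon-edge positions drop toward 15-20x, exactly the regime in which the
five-fold contig filter starts to cost alleles and the quality tiers
degrade. The spread of exon-edge depths is also what distributes simulated
genes across the quality tiers (roughly a third reach the strictest tier
at 40x) rather than trivially passing all of them. Problem sizes for the
shipped validation: a database of 6 typed genes x 24 alleles (plus 2
competitor genes), 60 samples (30 WES, 30 WGS) at 40x for genotype
recovery, 8 samples at 22x for the degraded-coverage behaviour, 500
randomized assembly fixtures and 1000 randomized scoring fixtures.

## Numerical and degenerate-input choices

* Scores are compared exactly; ties in allele totals are broken by
  population frequency, then label order. Mapping-score ties across genes
  are evaluated on integer-rounded scores.
* Contigs are deduplicated by sequence and reported in lexicographic
  order, making assembly output invariant to read order.
* An empty read bin is a no-call with a failed QC report, never an error;
  an empty allele file parses to an empty record set.
* Genes where no allele carries intron sequence get zero-length flanks and
  a warning.
* Consensus positions left uncovered by any perfectly placed read (possible
  when a voting read is later rejected) split the contig rather than
  surviving unsupported.
* The phase enumeration caps at 12 blocks (4096 recombinations); beyond
  that the call is left unflagged — in practice two alleles that different
  are distinguished by every read.

## Known limitations

* Substitution-only error handling: an indel-bearing read is either
  rescued by the gapped aligner during classification and then rejected at
  assembly, or unmapped; indel-rich data will lose depth.
* Reads retained in several gene bins (equal imperfect best scores) fully
  count in each bin, which can inflate depth between close paralogs.
* Phase alternatives are enumerated only against database alleles plus a
  single unknown placeholder; a sample carrying two novel recombinants is
  reported by its contigs, not by name.
* Six digits is the resolution ceiling: intron evidence is not used.
* The QC tiers gate homozygous reporting, but a heterozygote whose second
  allele is entirely uncovered while QC narrowly passes will still be
  mistyped homozygous — the same failure mode the quality tiers are
  designed to make visible, and the reason calls below the 20-fold/2%
  rule always carry the warning flag.
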