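# hlatyper

HLA genotyping from short-read sequencing (WES/WGS) in R: comprehensive
multi-allele reference mapping, zero-mismatch targeted assembly, and
stepwise exact matching of contigs to allele databases with G-group
resolution, phase-ambiguity reporting and coverage quality tiers.

## The problem and the method

The classical HLA loci carry hundreds to thousands of alleles each,
differing by dense substitutions in the antigen-binding exons, with strong
similarity between paralogous genes. Mapping reads against a single
reference haplotype silently loses the reads of the allele the reference
does not carry, and one mismatched base distinguishes clinically different
alleles — so `hlatyper` is built around exact matching:

1. **Classify** raw reads against a *comprehensive reference panel* (CRP):
   every known allele's targeted exons (class I: exons 2–4; class II:
   exons 2–3) with 50 bp intron flanks, plus "mapping competitor" genes
   that absorb paralog reads. A read perfectly matching two different
   genes is excluded as ambiguous; equal imperfect best scores keep the
   read in every such gene.
2. **Assemble** each gene's bin into contigs admitting only overlaps
   ≥ 20 bp with 100% identity (sequencing errors can drop reads but never
   alter a consensus base), with per-base depth; contigs under five-fold
   mean depth are discarded.
3. **Designate** alleles by matching contigs exactly (exonic region only)
   to the major-exon database (mDB, with alleles identical across major
   exons collapsed into G-groups), scoring each candidate as
   Σ contig length × mean depth × exonic fraction, and walking scores in
   descending order: an allele is called when it owns a uniquely matched,
   unassigned contig; two calls maximum, extra qualifying candidates are
   documented as possible contamination.
4. **Resolve** G-groups to six digits via the minor-exon database (aDB),
   report **phase ambiguity** whenever heterozygous blocks separated by an
   identical run longer than the read length can be recombined into other
   database alleles (ties broken by population frequency), and attach
   per-exon **coverage QC tiers** with a warning on any call where more
   than 2% of exonic positions are below 20-fold.

A mock-database generator and read simulator (`make_mock_alleles()`,
`simulate_reads()`) make the whole pipeline testable end to end without any
external data.

## Worked example

```r
library(hlatyper)

# a mock allele database: 6 HLA genes x 24 alleles, planted G-groups,
# 2 paralogous competitor genes, population frequencies
cfg  <- sim_config(seed = 11)
mock <- make_mock_alleles(cfg)
ref  <- build_reference(mock$records, competitor_genes = names(cfg$competitors))
#> <hla_reference> 6 target gene(s), 2 competitor(s), 400 panel entries

# one simulated sample: 100 bp reads at 40x, 0.5% error
sim <- simulate_reads(mock$genome_records, cfg, freq = mock$frequencies, seed = 101)
report <- hla_type(sim$reads, ref, freq = mock$frequencies)
report
#> <hla_typing_report> 6 gene(s); reads: 1644 total, 1644 binned, 0 ambiguous, 0 competitor, 0 unmapped
#> <typing call> HLA-A: HLA-A*20:01:01; HLA-A*06:01:01
#> <typing call> HLA-B: HLA-B*15:01:01; HLA-B*02:01:01
#> ...
report_table(report)[4:5, c("gene", "allele1", "allele2", "resolution", "qc_tier")]
#>       gene           allele1           allele2       resolution             qc_tier
#> 4 HLA-DQA1 HLA-DQA1*03:01:02 HLA-DQA1*12:01:01 six-digit;allele 10x=100% & 20x>=90%
#> 5 HLA-DQB1 HLA-DQB1*11:01:01 HLA-DQB1*01:01:01 allele;six-digit 10x=100% & 20x>=98%
```

Every reported pair above equals the simulated truth (`sim$genotype`); a
`six-digit` resolution means the allele was first called as a G-group on
the major exons and then resolved by its minor exon. The header line is the
read accounting: total = binned + ambiguous + competitor + unmapped.

The same pipeline runs from files (`run_pipeline()`), and a command-line
wrapper with `build-db` / `simulate` / `type` / `qc` subcommands is
installed at `inst/cli/hla-typer.R`:

```sh
Rscript inst/cli/hla-typer.R simulate --out sim --seed 7
Rscript inst/cli/hla-typer.R type --alleles sim/alleles.fasta \
    --fastq sim/reads.fastq --frequencies sim/frequencies.tsv \
    --competitors HLA-E,HLA-DOB --out typed
```

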