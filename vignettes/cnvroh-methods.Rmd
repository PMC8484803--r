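---
title: "Methods: CNV/ROH post-analysis with cnvroh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV/ROH post-analysis with cnvroh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvroh)
library(data.table)
```

## What the package computes

SNP-array genotyping yields, per individual, copy number variant (CNV)
calls from tools such as PennCNV or CNVPartition, and runs of homozygosity
(ROH) from `plink --homozyg`.  The analyses that follow detection — region
calling, gene annotation, cross-study comparison, coordinate conversion,
inbreeding estimation, haplotype extraction — are individually simple but
error-prone when stitched together by hand.  `cnvroh` implements them as
one tested library with a single coordinate convention.

Four recurring mistakes in CNV post-analysis motivate specific design
choices here:

1. **Annotating genes at region level without carrier frequency.**  A CNVR
   (copy number variation region) merged across a cohort may owe a gene
   overlap to a single sample.  `gene_frequency()` therefore always counts
   carriers from per-sample CNV annotation, never from CNVR-level
   annotation, and reports `n_samples` next to `n_cnv`.
2. **Comparing studies only at population level.**  `compare_cnv()` always
   runs both levels: population (same regions found?) and individual
   (found in the same samples?).  The individual-level pair set is a
   subset of the population-level one by construction.
3. **Converting coordinates between assemblies carelessly.**  SNP order
   and even chromosome assignment can change between assemblies.
   `convert_coord()` is SNP-anchored — only matched marker positions
   define the converted span — and flags order inversion, chromosome
   changes, and intervals whose markers scatter across target chromosomes.
4. **Venn counts of overlapping regions.**  One long interval can overlap
   several short ones, so a single "overlap count" is ill-defined.
   `compare_interval()` reports A-anchored, B-anchored, and merged-region
   counts plus the full multiplicity distribution.

For ROH, two easily forgotten steps are built in: SNP density per
chromosome (`snp_density()`) should be inspected before trusting ROH calls,
and haplotype frequencies inside interesting regions (`get_haplotype()`)
complete the story a gene list alone does not tell.

## Coordinate convention

All internal coordinates are 1-based, fully closed intervals, the PLINK
convention.  Two intervals overlap iff they share at least one base pair:
`[100, 200]` and `[200, 300]` overlap (position 200), `[100, 200]` and
`[201, 300]` are bookended and do not.  UCSC gene tables are the only
0-based half-open input; the shift (`start = txStart + 1`) happens once, in
`read_refgene()`, and nowhere else.  BED export shifts back on the way
out.  Chromosome labels are normalized by stripping any `chr` prefix; X,
Y, and MT are retained but excluded from autosome-only computations
(F_roh, ROH incidence).

## CNVR calling

`call_cnvr()` merges CNVs from all samples into CNVRs defined as the union
of sets of calls overlapping by at least one base pair: per chromosome,
calls are sorted by start and a sweep opens a new region whenever a start
exceeds the running maximum end.  This is exactly the connected-components
partition of the >= 1 bp overlap graph, and the test suite verifies that
equivalence against an independent union-find oracle on 20 seeded sets of
1,000 random intervals.  Region type is `Deletion` when every member has
copy number < 2, `Duplication` when every member has > 2, `Mixed`
otherwise.  `n_samples` counts distinct carriers regardless of member
type; rare-CNV weighting is handled downstream at annotation, not by
filtering during calling, so calling and thresholding stay orthogonal.

`high_freq_cnvr()` retains regions with `n_samples / sample_size >=
common_cnv_threshold`.  The default threshold of 0.05 is the conventional
common-variant cutoff; the originating tools expose but do not document a
default, so ours is explicit and overridable.

## Length groups

Neither CNV nor ROH length-class boundaries are standardized, so both are
parameters with explicit defaults: CNVs bin at 0–100 kb–500 kb–1 Mb–5 Mb–∞
and ROH at 0–2–4–8–16–>16 Mb (standard ROH classes reflecting the
relationship between segment length and inbreeding recency).  Bins are
half-open `[b_i, b_{i+1})`, so a 3 Mb segment falls in 2–4 Mb and a
boundary value belongs to the upper bin.

## F_roh

The ROH-based inbreeding coefficient is

\[ F_{roh} = \frac{\sum L_{roh}}{\sum L_{auto}} \]

the total autosomal ROH length of an individual divided by the total
autosome length.  The denominator's source matters: when explicit assembly
lengths are not supplied, `froh()` derives chip-covered spans per autosome
(max − min SNP position + 1) from the map, which is reproducible from the
data alone; pass `autosome_lengths` to use assembly lengths instead.
Per-length-group components use the same denominator, so they sum exactly
to the total over disjoint bins (tested at 1e-12).

## High-frequency ROH regions

`roh_incidence()` counts, at every autosomal map SNP, the distinct
individuals with an ROH spanning that position; `high_freq_roh()` then
reports maximal runs of consecutive map SNPs at or above the carrier
threshold (default 0.3, overridable).  Counting is SNP-anchored rather
than fixed-width binning because chip density varies along the chromosome;
region bounds are the first and last SNP positions of the run, so reported
regions never extend past observed markers.  The frequency denominator is
all individuals present in the `.hom` file (override via `n_individuals`
if the genotyped cohort was larger than the ROH-carrying subset).

## SNP-anchored liftover

`convert_map()` joins two maps of the same chip by marker name and
classifies every marker (`same_chr`, `chr_changed`, `missing_in_target`,
`missing_in_default`).  `convert_coord()` lifts an interval by taking the
markers inside it, letting them vote on the target chromosome, and
spanning their target positions.  Decisions taken where the behaviour was
genuinely open:

- **No interpolation.**  Only observed marker positions define the
  converted span; positions are never invented between markers.
  Consequently `length_default` is the default-side span of the same
  retained markers, so `length_delta` isolates what the assembly change
  did to them — an identity liftover gives `length_delta = 0` exactly.
- **Minority tolerance.**  If more than 10% of in-interval markers map off
  the modal target chromosome the interval fails as
  `snps_split_across_chromosomes`; a smaller minority is dropped and
  counted.  The 10% default is exposed (`minority_tol`).
- **Tie-break.**  A modal-chromosome tie resolves toward the interval's
  own chromosome when it is among the modes, else the lexicographically
  smallest — deterministic and tested.
- **Order.**  `order_inverted` flags target positions that are not
  monotone in default positions; a whole-arm reversal (monotone
  decreasing) is orientation change, not scrambling, and is not flagged.

## Haplotypes and diplotypes

`closer_snp()` maps a region to the SNPs inside it (falling back, flagged,
to the two flanking markers when the region contains none).
`get_haplotype()` tabulates the distinct allele strings among the 2N
haploid sequences (haplotype table, frequencies out of 2N) and the
unordered pairs per individual (diplotype table, frequencies out of N).
Pairs are unordered because statistical phasing does not identify parent
of origin.  Haplotype ids `H1, H2, ...` follow descending count with
lexicographic tie-break, so numbering is deterministic.  Missing allele
codes are an error, not an imputation target: the supported input is
complete phased output (Beagle-style `0|1` fields), read through `vcfR`.

## Plot specs

Every figure is produced in two stages: a `prepare_*` function emits a
`plot_spec` whose tables (clipped intervals, first-fit lane assignment,
gene track, ideogram lanes) are plain data and individually testable, and
`render_plotspec()` turns a spec into a ggplot without recomputing
anything.  Tests assert on prepared tables and on layer data, never on
pixels.

## The synthetic cohort generator

`gen_cohort()` emulates every input dialect the package reads, with
planted, recoverable structure recorded in a truth ledger.  Defaults were
chosen once as a realistic desk-scale cohort and are not tuned per test:
100 samples on a 5-autosome, 100 Mb/chromosome genome with a 10,000-marker
chip; one common deletion CNVR planted at 20% carrier frequency; one gene
(`GENE_TARGET`) overlapped by duplications in 17% of samples; 150 private
background CNVs; 50 ROH individuals with a 2 Mb shared segment at 40%
carrier frequency plus three private background segments each; a
three-haplotype pool at frequencies 0.6/0.3/0.1 sampled into 2N = 400
phased haploids; and a target map perturbed at 3% missing / 1%
chromosome-changed / 5% shifted markers.

Two generator properties make exact assertions possible: carrier sets are
drawn without replacement so planted counts are exactly
`round(fraction x n)`, and background CNVs/ROH are placed on disjoint slot
grids far from planted regions, so private noise can never aggregate into
a spurious common region.  What the fixtures deliberately do not emulate —
linkage disequilibrium, chip-specific intensity artifacts, call-boundary
jitter between carriers of the same variant — bounds what passing tests
show: recovery guarantees concern the post-analysis arithmetic, not the
upstream detection step, which is out of scope (run PennCNV/PLINK/Beagle
upstream).

## Problem sizes and determinism

The test and acceptance workloads are desk-scale by design: 1,000-interval
region-calling sets, 500 x 500 comparison sets, 10,000-marker maps, and
the default cohort above; each completes in seconds while still exercising
every code path, and the oracle checks are exact rather than statistical
wherever the generator's bookkeeping allows.  All randomness flows from a
single integer seed (`fixture_config(seed = ...)`, `--seed` in
`scripts/acceptance.R`); the same seed reproduces every generated file
byte for byte.

## Known limitations

- CNVPartition's export layout is not standardized across versions; the
  reader assumes `SampleID, Chr, StartPosition, EndPosition, CopyNumber,
  Confidence` and takes a `col_map` to remap anything else.
- Only biallelic, fully phased VCF sites are accepted; multi-allelic
  records and missing genotypes error out rather than being dropped.
- Overlap is strictly >= 1 bp everywhere; reciprocal-overlap definitions
  of region identity are not offered, and significance testing of overlap
  is out of scope.
- Liftover requires the two maps to share marker names (same chip);
  chain-file liftover between arbitrary assemblies is not supported.
- BAF/LRR intensity-level plots are not implemented; they require raw
  intensity data the package does not ingest.
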