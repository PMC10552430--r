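---
title: "Calling pangenes from whole-genome alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling pangenes from whole-genome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangenes)
library(dplyr)
```

## The problem and the model

When several genome assemblies of one species (or of closely related
species) are independently annotated, the same locus ends up with different
gene identifiers, different exon structures, and sometimes no gene model at
all in some genotypes. A *pangene* is a cluster of gene models that occupy
homologous genomic positions across those assemblies. This package calls
pangenes from pairwise whole-genome alignment (WGA) evidence rather than
from protein similarity, which has two consequences that drive the whole
design:

1. clusters are anchored in genomic position, so split, merged, inverted and
   tandem-duplicated gene models are observable rather than confounding; and
2. an annotated gene in one assembly can be matched to an *unannotated*
   genomic segment in another, which turns reported presence–absence
   variation (PAV) into a testable hypothesis: lift the coding sequence over
   onto the segment and check whether an intact reading frame is there.

The pipeline is: cut cDNA/CDS/peptide sequences per transcript → decompose
PAF alignments (CIGAR) into gap-free mapped segments → project gene bodies
across assemblies through those segments → call collinear gene pairs →
greedily merge pairs into clusters → classify occupancy and build matrices →
confirm or reject PAV by spliced lift-over.

### Collinearity rule

A projected gene *b* and an annotated target gene *a* are collinear when
their genomic intervals overlap on the same chromosome, the overlap covers
at least a fraction *f* = 0.5 of **either** feature (the target gene body,
or the projected span of *b*), and the projected strand of *b* equals the
strand of *a*. The either-fraction semantics deliberately let one long gene
pair with several consecutive short models — that is how split annotations
are captured. Strand agreement is required for gene–gene pairs because gene
orientation carries real signal (inversions); the inverted flag on a pair
records that the underlying alignment was on the `-` strand.

### Greedy clustering and the neighbor constraint

Gene–gene pairs are processed in deterministic order — descending overlap,
then lexicographic member keys; the greedy order is otherwise unspecified in
the field, so determinism is the design goal of this rule — and merged with
union–find. A merge is refused whenever the merged cluster would contain two
genes of the same assembly on different chromosomes or separated by more
than `max_neighbors` (default 5) intervening annotated genes. Distance is
counted in genes, not base pairs, so the constraint is robust to intergenic
length variation; a gene whose merge is refused stays available to seed or
join other clusters. After gene–gene merging, gene–segment evidence attaches
genomic segments to the cluster of their gene member, and every remaining
annotated gene becomes a singleton, so gene members always partition the
input gene set (this is asserted in the tests). Clustering is single-pass
over the union of all pairwise evidence; we do not iterate per assembly
pair.

### Occupancy, matrices, growth curves

Occupancy is the number of assemblies contributing at least one *gene*
member; matched genomic segments are evidence of absence, so they never
count toward occupancy or POCS. Classes: core (all *n*), soft-core
(≥ ⌈0.95 *n*⌉ — ceiling, so 19 of 20 qualifies), shell (between singleton
and soft-core), singleton (exactly 1). Reported soft-core *totals* include
core, the superset convention used in pangenome tables. POCS (percentage of
conserved sequences) between assemblies A and B is
`100·(g_A + g_B)/(T_A + T_B)` where `g_X` counts clustered genes of X in
clusters shared with the partner and `T_X` all clustered genes of X; the
definition is printed in the matrix metadata because the name is used
loosely in the field. Growth curves resample assembly orders with a seeded
RNG (default 10 permutations) and report mean ± sd of pan/soft-core/core
sizes per prefix.

### Lift-over and the built-in spliced aligner

For a cluster with a matched genomic segment in an assembly that lacks a
gene member, consensus CDS isoforms (those within 50% of the mode CDS
length; the mode ties to the longest — an invented but documented stand-in
for a consensus definition that is not standardized) are aligned to the
segment padded with 1 kb of flank (spliced aligners need context for
terminal exons). The built-in aligner seeds with exact 12-mers, merges
seeds along diagonals, chains them colinearly by dynamic programming
(small overlaps between blocks, which arise when an intron head happens to
match the next exon's start, are tolerated and trimmed), classifies
inter-block gaps as substitution runs, introns (target gap ≥ 30 bp,
boundaries snapped to `GT..AG` when a compatible shift ≤ 12 bp exists), or
small indels (resolved with an affine pairwise alignment), and extends the
terminal exons only while the running score (match +1, mismatch −2) keeps
improving, so a partially deleted locus reports honest partial coverage
rather than a forced full-length alignment.

A missing gene is **confirmed** only when the best alignment has an intact
ORF (starts `ATG`, ends at a stop, length divisible by 3, no internal stop)
and full query coverage (`min_coverage` default 1.0, relaxable to 0.95).
Everything else is rejected, with the ORF status as the reason. The same
machinery supports `split` mode (one consensus CDS spanning an assembly's
multiple partial models → `split_fix`) and `merged` mode (two clusters'
consensus CDS aligning disjointly inside one long model → `merged_fix`).
Confirmations are emitted as patch GFF3; rejected verdicts never produce
records.

## What the simulator emulates — and what it does not

`simulate_pangenome()` builds an ancestor chromosome of multi-exon genes
(2–4 exons of 90–240 bp, `GT..AG` introns of 60–120 bp, clean ORFs,
intergenic spacers around 400 bp), then derives each assembly by applying
seeded SNPs and small intergenic indels plus planted structural events:
whole-gene deletions (true PAV), a hidden gene (sequence intact, GFF record
omitted), an inversion spanning two adjacent genes, a split annotation (one
record replaced by two partial records), a tandem duplication (extra
annotated copy), and optionally a partial deletion that removes all exons
but a deliberately long last one — the analogue of a gene whose early exons
are deleted while the final exon still matches perfectly.

Two choices make the planted truth exactly recoverable and are stated here
because they limit what passing tests prove about real data:

* **Alignments are derived from the edit history, not from an aligner.**
  Every pairwise PAF is composed per base from the ancestor→derived maps,
  so projection tests are exact. Real WGAs are noisy, fragmented and
  incomplete; the package parses them identically, but recall on real data
  is bounded by the aligner, not by this code.
* **Event regions are protected from SNPs/indels in every assembly**, SNPs
  avoid CDS bases and splice dinucleotides, and indels are intergenic. This
  keeps untouched genes as intact ORFs and makes the hidden-gene lift-over
  a perfect match (0 mismatches), mirroring a published-style best case.
  Real hidden genes carry variants; the `min_coverage` and consensus knobs
  exist for that reason.

The default per-assembly SNP rate of 0.03 on eligible bases yields pairwise
identities near 97% over aligned columns — the regime where WGA-based
pangene calling is intended to operate (methods of this family are
documented for ANI ≥ 95%, and degrade with divergence). No repeat
landscape is simulated; geneless-region masking is exercised only on plain
spacer tracts.

Problem sizes used throughout the tests — 3–5 assemblies, 10–50 genes,
single chromosome — are the package's chosen study conditions: large enough
that every phenomenon (split/tandem/inversion/PAV) occurs and ANI
estimation stabilizes, small enough that every expected value can be
computed by brute force next to the fast implementation.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally everywhere; GFF3 converts at
  the file boundary (1-based inclusive), BED/PAF pass through unchanged.
* "Longer than 100 bp" is implemented strictly (`> min_len`), so a 100 bp
  CDS is excluded and a 101 bp CDS kept; the cDNA and CDS filters apply
  independently per record kind, and a peptide is kept only when its CDS
  survives.
* Geneless masking is strict as well: a tract of exactly 1,000,000 bp is
  untouched.
* Multi-chromosome projection ambiguity resolves by majority covered bases,
  ties lexicographically, and the projection is marked ambiguous.
* A CDS that is not a multiple of 3 translates up to the last full codon
  and is flagged; internal stops are kept as `*` and flagged, because
  loss-of-function alleles are worth clustering, not discarding.
* ANI is the aligned-column-weighted mean of per-record identities
  (matches/(matches+mismatches), indels excluded). Aligner-internal ANI
  estimators are not printed by their authors; ours is labeled as an
  approximation in the output.
* Split-vs-tandem flagging compares an assembly's summed CDS length to the
  cluster's mode CDS length with a configurable 20% tolerance (an invented
  constant); sums within tolerance are splits, others tandems.
* Secondary PAF records (`tp:A:S`) are dropped on parse, matching the
  recommended aligner configuration for WGA; records without a CIGAR are
  rejected with a count, and `cs:Z` difference strings are converted to
  `=`/`X` CIGARs.

## A small worked run

```{r run, eval = FALSE}
dir <- tempfile()
sim <- simulate_pangenome(sim_config(seed = 1, n_assemblies = 4, n_genes = 50), dir)
asms <- Map(load_assembly, sim$fasta, sim$gff, sim$assemblies)
res <- run_pipeline(asms, sim$alignments, file.path(dir, "out"), seed = 1)
glance(res$pangene_set)
verify_against_truth(res$pangene_set, sim$truth, flags = res$flags)
```

The tidy/glance/autoplot surface follows the broom convention:
`tidy(pangene_set)` is one row per cluster member with occupancy class,
`glance()` one summary row, `autoplot()` the occupancy spectrum;
`plot_dotplot()` and `plot_growth()` cover the evidence table and the
growth curves.

## Known limitations

* Gene projection is evaluated per alignment record; a gene straddling two
  PAF records (fragmented real-world WGAs) can fall below the coverage
  threshold in each record separately. Whole-genome synteny chaining is out
  of scope.
* When evidence from two different aligners is available, runs are kept
  separate (as comparative tables in the field do); no merging policy is
  implemented.
* The spliced aligner is exact-seed based: queries diverged beyond roughly
  15% from the segment, or exons shorter than the 12-mer seed, may fail to
  chain. The external GMAP-style adapter route is intentionally out of the
  tested path.
* Fully deleted loci produce no candidate segment at all (projection
  coverage is below threshold); they are reported as rejected with
  `no_alignment` rather than attempted.
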