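# pangenes

Pangene clustering and presence–absence confirmation from whole-genome
alignments, in R.

## The problem

Given several annotated genome assemblies of one species (or very close
relatives), the same locus carries different gene identifiers — and
sometimes no gene model at all — in different genotypes. **pangenes** calls
*pangene clusters*: sets of gene models from different assemblies that
occupy homologous genomic positions, linked by pairwise whole-genome
alignment (WGA) evidence in PAF format. Because clusters are anchored in
genomic position rather than protein similarity, the package can also
*test* reported presence–absence variation (PAV): an annotated gene matched
to an unannotated genomic segment in another assembly is lifted over with a
spliced aligner, and the PAV is confirmed only if an intact open reading
frame aligns with full coverage.

It is aimed at plant (and other) comparative genomicists who have per-
assembly FASTA + GFF3 and minimap2/GSAlign-style PAF alignments, and want
occupancy-classified pangene matrices plus curated evidence for missing,
split, merged, inverted and tandem gene models.

## The method in brief

- Gene bodies are projected across assemblies through the gap-free blocks
  of each alignment's CIGAR. A projected gene *b* and an annotated gene *a*
  are **collinear** when their intervals overlap by at least half of
  *either* feature's length (`overlap ≥ 0.5·len(a)` **or**
  `≥ 0.5·len(b)`) on the same strand.
- Collinear pairs are merged greedily (descending overlap) under a
  neighbor-distance constraint: two same-assembly genes may share a cluster
  only on one chromosome with at most `N = 5` annotated genes between them.
- Clusters are classified by occupancy — core (all *n* genomes), soft-core
  (`≥ ⌈0.95·n⌉`), shell, singleton — and summarised as a BED-like pangene
  matrix, POCS and ANI matrices, and pan/core growth curves.
- For a cluster lacking a gene in some assembly but holding a matched
  genomic segment there, consensus CDS isoforms (within 50% of the mode
  length) are spliced-aligned onto the padded segment;
  `missing_gene_confirmed` requires an intact ORF at 100% query coverage,
  and confirmations are written as patch GFF3 records.

A first-class simulator generates families of assemblies with known edit
history — SNPs, indels, gene deletions, hidden (unannotated) genes,
inversions, split annotations, tandem duplications — together with the
*exact* PAF alignments implied by that history, so the whole pipeline is
testable without external aligners or downloads.

## Worked example

```r
library(pangenes)
library(dplyr)

dir <- tempfile()
sim <- simulate_pangenome(sim_config(seed = 1, n_assemblies = 4, n_genes = 50), dir)
asms <- Map(load_assembly, sim$fasta, sim$gff, sim$assemblies)
res <- run_pipeline(asms, sim$alignments, file.path(dir, "out"), seed = 1)

glance(res$pangene_set)
#> # A tibble: 1 x 9
#>   n_assemblies n_clusters n_core n_softcore n_softcore_total n_shell n_singleton
#> 1            4         50     44          0               44       6           0
#> # n_gene_members 196, n_gdna_members 1
```

50 ancestral genes yield 50 clusters: 44 core (present in all four
assemblies) and 6 shell — the five planted gene deletions plus the one
hidden gene, each missing from exactly one assembly. The hidden gene's
cluster carries a matched genomic segment (`n_gdna_members = 1`); lifting
the consensus CDS onto it distinguishes it from the real deletions:

```r
v <- verify_against_truth(res$pangene_set, sim$truth, flags = res$flags)
check_cluster(res$pangene_set, v$cluster_of[[sim$truth$hidden$anc_id]],
              asms, mode = "missing") |>
  select(target_assembly, matches, mismatches, query_coverage, orf_status, verdict)
#>   target_assembly matches mismatches query_coverage orf_status verdict
#> 1 asm2                441          0              1 intact     missing_gene_confirmed
```

441 matches, no mismatches, no indels, full coverage, intact ORF: the gene
is present in `asm2` but was never annotated there. The same call on a
deleted gene's cluster returns `rejected` (no alignable segment), and a
partially deleted locus returns `rejected` with `orf_status = "partial"` —
matching but incomplete exons never confirm a gene.

`tidy()`, `glance()`, `autoplot()`, `plot_dotplot()` and `plot_growth()`
give tibble summaries and ggplot views of every result type. A thin command
line wrapper over the same functions lives at
`inst/scripts/pangenes-cli.R` (subcommands `simulate` and `run`).

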