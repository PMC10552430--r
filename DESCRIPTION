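Package: pangenes
Title: Pangene Clustering and Presence-Absence Confirmation from Whole-Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls pangene clusters across annotated genome assemblies of
    closely related genotypes using pairwise whole-genome alignment (WGA)
    evidence in PAF format. Gene models are projected across assemblies by
    parsing alignment CIGAR strings, collinear gene pairs are called with a
    reciprocal either-fraction overlap rule that requires strand agreement,
    and pairs are greedily merged into pangene clusters under a same-genotype
    neighbor-distance constraint. Clusters are classified by occupancy
    (core, soft-core, shell, singleton), summarised as BED-like pangene and
    percentage-of-conserved-sequences (POCS) matrices, and pan/core genome
    growth curves. Candidate gene presence-absence variation is confirmed or
    rejected by lifting consensus CDS sequences over matched genomic segments
    with a built-in spliced aligner, emitting patch GFF3 records for intact
    recovered models. A seeded simulator generates families of related
    assemblies with planted SNPs, indels, deletions, inversions, split and
    hidden gene models, together with the exact PAF alignments implied by
    the edit history, so the whole pipeline is testable without external
    aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
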