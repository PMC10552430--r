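# Cross-assembly gene projection through mapped WGA segments, and collinear
# pair calling with the either-fraction overlap rule.

#' Project gene models through mapped alignment segments
#'
#' Intersects each gene body with the query intervals of the mapped segments
#' of one alignment record and transfers the covered bases to target
#' coordinates by within-segment offset (reversed for `-` strand
#' alignments). A projection is reported when the covered fraction of the
#' gene body reaches `min_coverage`. The projected strand is the gene strand
#' flipped iff the alignment strand is `-`.
#'
#' Genes are projected independently against each alignment record, so a
#' gene that is double-covered (e.g. by a tandem-duplication alignment)
#' yields one projection per record. When the segments covering a gene
#' within one record map to several target chromosomes, the chromosome with
#' the most covered bases wins (ties break lexicographically) and the
#' projection is marked `ambiguous`.
#'
#' @param genes Gene tibble (columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`) for the assembly on the segments' query side.
#' @param segments Segment tibble from [cigar_to_segments()].
#' @param min_coverage Minimum covered fraction of the gene body
#'   (default 0.5).
#' @param source_assembly,target_assembly Labels stored on the output.
#' @return A tibble of projections: `gene_id`, `source_assembly`,
#'   `target_assembly`, `aln_id`, `chrom` (target), `start`, `end` (span of
#'   projected bases), `strand` (projected), `covered_bp`, `coverage`,
#'   `gene_len`, `gene_strand`, `inverted`, `ambiguous`.
#' @export
project_genes <- function(genes, segments, min_coverage = 0.5,
                          source_assembly = NA_character_,
                          target_assembly = NA_character_) {
  if (nrow(genes) == 0 || nrow(segments) == 0) return(empty_projection())
  hits <- genes |>
    inner_join(segments, by = c("chrom" = "qname"),
               relationship = "many-to-many") |>
    mutate(
      ov_start = pmax(.data$start, .data$qstart),
      ov_end = pmin(.data$end, .data$qend)
    ) |>
    filter(.data$ov_start < .data$ov_end) |>
    mutate(
      gene_len = .data$end - .data$start,
      gene_strand = .data$strand.x
    ) |>
    mutate(
      # map overlap endpoints through the segment offset
      t_lo = ifelse(.data$strand.y == "+",
                    .data$tstart + (.data$ov_start - .data$qstart),
                    .data$tstart + (.data$qend - .data$ov_end)),
      t_hi = ifelse(.data$strand.y == "+",
                    .data$tstart + (.data$ov_end - .data$qstart),
                    .data$tstart + (.data$qend - .data$ov_start))
    )
  if (nrow(hits) == 0) return(empty_projection())

  proj <- hits |>
    group_by(.data$gene_id, .data$aln_id, .data$tname) |>
    summarise(
      covered_bp = sum(.data$ov_end - .data$ov_start),
      start = min(.data$t_lo), end = max(.data$t_hi),
      aln_strand = dplyr::first(.data$strand.y),
      gene_strand = dplyr::first(.data$gene_strand),
      gene_len = dplyr::first(.data$gene_len),
      .groups = "drop"
    ) |>
    # per (gene, alignment) keep the target chromosome with most covered bp
    group_by(.data$gene_id, .data$aln_id) |>
    mutate(ambiguous = dplyr::n() > 1) |>
    arrange(dplyr::desc(.data$covered_bp), .data$tname, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(coverage = .data$covered_bp / .data$gene_len) |>
    filter(.data$coverage >= min_coverage)
  if (nrow(proj) == 0) return(empty_projection())
  proj |>
    transmute(
      gene_id = .data$gene_id,
      source_assembly = source_assembly,
      target_assembly = target_assembly,
      aln_id = .data$aln_id,
      chrom = .data$tname,
      start = .data$start, end = .data$end,
      strand = ifelse(.data$aln_strand == "-",
                      ifelse(.data$gene_strand == "+", "-", "+"),
                      .data$gene_strand),
      covered_bp = .data$covered_bp,
      coverage = .data$coverage,
      gene_len = .data$gene_len,
      gene_strand = .data$gene_strand,
      inverted = .data$aln_strand == "-",
      ambiguous = .data$ambiguous
    ) |>
    arrange(.data$gene_id, .data$aln_id)
}

empty_projection <- function() {
  tibble(
    gene_id = character(), source_assembly = character(),
    target_assembly = character(), aln_id = integer(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    covered_bp = integer(), coverage = double(), gene_len = integer(),
    gene_strand = character(), inverted = logical(), ambiguous = logical()
  )
}

#' Call collinear gene pairs from projections
#'
#' For every projected gene overlapping an annotated gene of the target
#' assembly on the same chromosome, emits a collinear pair when the overlap
#' reaches `f` of *either* feature length (the target gene body, or the
#' projected span standing in for the query gene) *and* the projected
#' strand agrees with the target gene strand — strandedness is required for
#' gene-to-gene collinearity. One projected gene may pair with several
#' consecutive target genes (split-gene support). The inverted flag records
#' a `-` strand underlying alignment.
#'
#' @param projections Tibble from [project_genes()].
#' @param target_genes Gene tibble of the target assembly.
#' @param target_assembly Label for the A (target) side.
#' @param f Overlap fraction threshold (default 0.5, `>=` semantics).
#' @param wga_algorithm Label stored in the `wga_algorithm` column.
#' @return A collinear-pair tibble (A = target gene, B = projected gene)
#'   with the columns of [write_collinear_tsv()].
#' @export
call_collinear_pairs <- function(projections, target_genes, target_assembly,
                                 f = 0.5, wga_algorithm = "minimap2") {
  if (nrow(projections) == 0 || nrow(target_genes) == 0) return(empty_pairs())
  cand <- projections |>
    inner_join(target_genes, by = "chrom", suffix = c("_b", "_a"),
               relationship = "many-to-many") |>
    mutate(overlap = pmin(.data$end_b, .data$end_a) - pmax(.data$start_b, .data$start_a)) |>
    filter(.data$overlap > 0) |>
    mutate(
      len_a = .data$end_a - .data$start_a,
      len_b = .data$end_b - .data$start_b
    ) |>
    filter(
      (.data$overlap >= f * .data$len_a | .data$overlap >= f * .data$len_b),
      .data$strand_b == .data$strand_a
    )
  if (nrow(cand) == 0) return(empty_pairs())
  cand |>
    transmute(
      gene_id_A = .data$gene_id_a, assembly_A = target_assembly,
      chrom_A = .data$chrom, start_A = .data$start_a, end_A = .data$end_a,
      strand_A = .data$strand_a,
      gene_id_B = .data$gene_id_b, assembly_B = .data$source_assembly,
      chrom_B = .data$chrom, start_B = .data$start_b, end_B = .data$end_b,
      strand_B = .data$strand_b,
      overlap_bp = as.integer(.data$overlap),
      wga_algorithm = wga_algorithm,
      inverted = .data$inverted,
      pair_type = "gene-gene"
    ) |>
    distinct() |>
    arrange(.data$gene_id_A, .data$gene_id_B)
}

#' Match unpaired projections to genomic segments
#'
#' Projected genes that produced no gene-gene pair in the target assembly
#' are matched to their projected genomic interval instead, producing
#' `gene-gdna` evidence: the signature of a gene that is present in one
#' assembly and unannotated (or absent) at the homologous location of
#' another. These segments are the lift-over candidates used to confirm or
#' reject presence-absence variation.
#'
#' @param projections Tibble from [project_genes()] (already
#'   coverage-filtered).
#' @param pairs Gene-gene pairs already called for the same target assembly.
#' @param target_assembly Label for the segment side.
#' @param wga_algorithm Label stored in the output.
#' @return A collinear-pair tibble with `pair_type = "gene-gdna"`; the A
#'   side is the source gene, the B side the matched genomic segment (its
#'   id is a `chrom:start-end` descriptor).
#' @export
call_gdna_matches <- function(projections, pairs, target_assembly,
                              wga_algorithm = "minimap2") {
  if (nrow(projections) == 0) return(empty_pairs())
  paired <- pairs |>
    filter(.data$pair_type == "gene-gene") |>
    transmute(gene = .data$gene_id_B, asm = .data$assembly_B) |>
    bind_rows(pairs |> filter(.data$pair_type == "gene-gene") |>
                transmute(gene = .data$gene_id_A, asm = .data$assembly_A)) |>
    distinct()
  un <- projections |>
    anti_join(paired, by = c(gene_id = "gene", source_assembly = "asm"))
  if (nrow(un) == 0) return(empty_pairs())
  un |>
    transmute(
      gene_id_A = .data$gene_id, assembly_A = .data$source_assembly,
      chrom_A = NA_character_, start_A = NA_integer_, end_A = NA_integer_,
      strand_A = .data$gene_strand,
      gene_id_B = sprintf("segment:%s:%d-%d", .data$chrom, .data$start, .data$end),
      assembly_B = target_assembly,
      chrom_B = .data$chrom, start_B = .data$start, end_B = .data$end,
      strand_B = .data$strand,
      overlap_bp = .data$covered_bp,
      wga_algorithm = wga_algorithm,
      inverted = .data$inverted,
      pair_type = "gene-gdna"
    ) |>
    arrange(.data$gene_id_A, .data$gene_id_B)
}

#' Restrict alignments to homologous chromosomes
#'
#' Keeps alignments whose query and target chromosome names yield the same
#' match under `pattern` (e.g. `"^chr\\d+H"` pairs `chr1H` with `chr1H`
#' across barley assemblies). Sequences that do not match the pattern at
#' all — typically unplaced scaffolds such as `chrUn` — are dropped, which
#' reproduces the known failure mode where a gene placed on an unanchored
#' sequence can never be called collinear under this restriction.
#'
#' @param alignments Alignment tibble.
#' @param pattern Regular expression identifying the homologous-chromosome
#'   key in sequence names; the full match is compared.
#' @return The filtered alignment tibble; warns when nothing matches.
#' @export
restrict_homologous <- function(alignments, pattern) {
  if (nrow(alignments) == 0) return(alignments)
  qm <- stringr::str_extract(alignments$qname, pattern)
  tm <- stringr::str_extract(alignments$tname, pattern)
  keep <- !is.na(qm) & !is.na(tm) & qm == tm
  if (!any(!is.na(qm)) && !any(!is.na(tm))) {
    warn(sprintf("restrict_homologous: pattern '%s' matched no chromosome name", pattern))
  }
  alignments[keep, , drop = FALSE]
}
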