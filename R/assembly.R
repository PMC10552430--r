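# Assembly container: genome sequences plus a tabular gene annotation.
#
# All internal coordinates are 0-based half-open; GFF3 is converted at the
# file boundary (1-based inclusive on disk).

#' Load a genome assembly and its gene annotation
#'
#' Reads a genome FASTA and a GFF3 annotation into an `assembly` object:
#' a [Biostrings::DNAStringSet] of chromosome sequences plus tibbles of
#' genes, transcripts, exons and CDS segments. GFF3 coordinates (1-based
#' inclusive) are converted to the package-internal 0-based half-open
#' convention. Genes are ranked by position along each chromosome
#' (consecutive integers from 0), which is the distance unit used by the
#' clustering neighbor constraint.
#'
#' @param fasta_path Path to a genome FASTA file.
#' @param gff_path Path to a GFF3 annotation (must carry a `##gff-version 3`
#'   pragma). Features of type `gene`, `mRNA`/`transcript`, `exon` and `CDS`
#'   are used; other types are ignored.
#' @param assembly_id Short unique label for this assembly.
#' @return An object of class `assembly`: a list with elements
#'   `assembly_id`, `seqs` (DNAStringSet), `genes`, `transcripts`, `exons`
#'   and `cds` (tibbles). `genes` has columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `rank`, `has_transcript`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sim <- simulate_pangenome(sim_config(seed = 1, n_assemblies = 2, n_genes = 5), dir)
#' asm <- load_assembly(sim$fasta[1], sim$gff[1], "g1")
#' asm$genes
#' @export
load_assembly <- function(fasta_path, gff_path, assembly_id) {
  if (!nzchar(assembly_id)) stop_pg("assembly_id must be a non-empty label")
  if (!file.exists(fasta_path)) stop_pg("FASTA not found: %s", fasta_path)
  if (!file.exists(gff_path)) stop_pg("GFF3 not found: %s", gff_path)

  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  validate_gff_lines(gff_path)
  gr <- rtracklayer::import(gff_path)
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  getcol <- function(name, default) {
    if (name %in% names(mc)) mc[[name]] else rep(default, n)
  }
  parent <- getcol("Parent", NA_character_)
  if (methods::is(parent, "List") || is.list(parent)) {
    parent <- map_chr(as.list(parent), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    })
  }
  feat <- tibble(
    type = as.character(getcol("type", NA_character_)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(getcol("ID", NA_character_)),
    parent = parent,
    phase = suppressWarnings(as.integer(as.character(getcol("phase", NA_integer_))))
  )

  missing_chr <- setdiff(unique(feat$chrom), names(seqs))
  if (length(missing_chr) > 0) {
    stop_pg(
      "GFF3 references chromosome(s) absent from FASTA: %s",
      paste(missing_chr, collapse = ", ")
    )
  }

  genes <- feat |>
    filter(.data$type == "gene") |>
    transmute(gene_id = .data$id, .data$chrom, .data$start, .data$end, .data$strand)
  if (any(is.na(genes$gene_id))) stop_pg("gene feature without ID attribute")
  if (any(!genes$strand %in% c("+", "-"))) {
    stop_pg("gene strand must be '+' or '-' (got '%s')",
            genes$strand[!genes$strand %in% c("+", "-")][1])
  }
  if (any(genes$start >= genes$end)) stop_pg("gene with start >= end")

  transcripts <- feat |>
    filter(.data$type %in% c("mRNA", "transcript")) |>
    transmute(transcript_id = .data$id, gene_id = .data$parent)

  exons <- feat |>
    filter(.data$type == "exon") |>
    transmute(transcript_id = .data$parent, .data$start, .data$end) |>
    arrange(.data$transcript_id, .data$start)

  cds <- feat |>
    filter(.data$type == "CDS") |>
    transmute(transcript_id = .data$parent, .data$start, .data$end,
              phase = coalesce(.data$phase, 0L)) |>
    arrange(.data$transcript_id, .data$start)

  genes <- genes |>
    mutate(has_transcript = .data$gene_id %in% transcripts$gene_id) |>
    arrange(.data$chrom, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(rank = dplyr::row_number() - 1L) |>
    ungroup()

  structure(
    list(
      assembly_id = assembly_id,
      seqs = seqs,
      genes = genes,
      transcripts = transcripts,
      exons = exons,
      cds = cds
    ),
    class = "assembly"
  )
}

# Light syntactic validation so malformed lines are reported with a line
# number; semantic parsing is delegated to rtracklayer.
validate_gff_lines <- function(gff_path) {
  lines <- readr::read_lines(gff_path)
  if (length(lines) == 0 || !startsWith(lines[1], "##gff-version 3")) {
    stop_pg("GFF3 file must start with a '##gff-version 3' pragma: %s", gff_path)
  }
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfields <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  bad <- body[nfields != 9L]
  if (length(bad) > 0) {
    stop_pg("malformed GFF3 line %d in %s: expected 9 tab-separated columns, got %d",
            bad[1], gff_path, nfields[which(body == bad[1])])
  }
  invisible(TRUE)
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf(
    "<assembly> %s: %d sequence(s), %d gene(s), %d transcript(s)\n",
    x$assembly_id, length(x$seqs), nrow(x$genes), nrow(x$transcripts)
  ))
  invisible(x)
}

# chromosome sequence as character scalar
asm_seq <- function(assembly, chrom) {
  if (!chrom %in% names(assembly$seqs)) {
    stop_pg("chromosome '%s' not in assembly '%s'", chrom, assembly$assembly_id)
  }
  as.character(assembly$seqs[[chrom]])
}
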