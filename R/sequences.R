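# Sequence cutting: cDNA / CDS / peptide / gDNA records, plus geneless
# masking. Mirrors the roles of GffRead -w/-x/-y and bedtools getfasta,
# re-implemented on Biostrings.

#' Cut cDNA, CDS and peptide sequences from an assembly
#'
#' For every transcript of every gene, emits the spliced cDNA (exon
#' concatenation), the spliced CDS and its translation, reverse-complemented
#' for `-` strand genes. Records whose cDNA or CDS is not longer than
#' `min_len` are excluded (the filter is applied to each record kind
#' independently; a peptide is kept only when its CDS survives).
#'
#' A CDS whose length is not a multiple of 3 is translated after truncating
#' to the last complete codon and flagged `len_not_multiple3`; an internal
#' stop codon is retained as `*` in the peptide and flagged `internal_stop`.
#'
#' @param assembly An `assembly` from [load_assembly()].
#' @param min_len Minimum length in bp; records of length `<= min_len` are
#'   dropped (default 100, i.e. only sequences longer than 100 bp are kept).
#' @return A tibble of sequence records: `seq_id`, `kind`
#'   (`cdna`/`cds`/`pep`), `gene_id`, `transcript_id`, `assembly`, `chrom`,
#'   `start`, `end`, `strand`, `length`, `sequence`, `internal_stop`,
#'   `len_not_multiple3`.
#' @export
cut_sequences <- function(assembly, min_len = 100L) {
  stopifnot(inherits(assembly, "assembly"))
  tx <- assembly$transcripts |>
    inner_join(assembly$genes, by = "gene_id") |>
    arrange(.data$gene_id, .data$transcript_id)
  if (nrow(tx) == 0) return(empty_records())

  recs <- pmap(tx, function(transcript_id, gene_id, chrom, start, end, strand, ...) {
    chrseq <- asm_seq(assembly, chrom)
    ex <- assembly$exons |> filter(.data$transcript_id == !!transcript_id)
    cd <- assembly$cds |> filter(.data$transcript_id == !!transcript_id)
    out <- list()
    if (nrow(ex) > 0) {
      cdna <- splice_seq(chrseq, ex$start, ex$end, strand)
      out$cdna <- record_row(gene_id, transcript_id, assembly$assembly_id, "cdna",
                             cdna, chrom, min(ex$start), max(ex$end), strand)
    }
    if (nrow(cd) > 0) {
      cds_seq <- splice_seq(chrseq, cd$start, cd$end, strand)
      # phase of the 5'-most segment trims incomplete leading codon bases
      ph <- if (strand == "+") cd$phase[1] else cd$phase[nrow(cd)]
      if (is.na(ph)) ph <- 0L
      if (ph > 0) cds_seq <- substring(cds_seq, ph + 1L)
      tr <- translate_cds(cds_seq)
      out$cds <- record_row(gene_id, transcript_id, assembly$assembly_id, "cds",
                            cds_seq, chrom, min(cd$start), max(cd$end), strand,
                            internal_stop = tr$internal_stop,
                            len_not_multiple3 = tr$len_not_multiple3)
      out$pep <- record_row(gene_id, transcript_id, assembly$assembly_id, "pep",
                            tr$pep, chrom, min(cd$start), max(cd$end), strand,
                            internal_stop = tr$internal_stop,
                            len_not_multiple3 = tr$len_not_multiple3)
    }
    list_rbind(out)
  })
  recs <- list_rbind(recs)
  if (nrow(recs) == 0) return(empty_records())

  keep_cds <- recs |>
    filter(.data$kind == "cds", .data$length > min_len) |>
    pull(.data$transcript_id)
  recs |>
    filter(
      (.data$kind %in% c("cdna", "cds") & .data$length > min_len) |
        (.data$kind == "pep" & .data$transcript_id %in% keep_cds)
    ) |>
    arrange(.data$gene_id, .data$transcript_id, .data$kind)
}

empty_records <- function() {
  tibble(
    seq_id = character(), kind = character(), gene_id = character(),
    transcript_id = character(), assembly = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    length = integer(), sequence = character(),
    internal_stop = logical(), len_not_multiple3 = logical()
  )
}

record_row <- function(gene_id, transcript_id, assembly_id, kind, sequence,
                       chrom, start, end, strand,
                       internal_stop = FALSE, len_not_multiple3 = FALSE) {
  tibble(
    seq_id = paste(gene_id, transcript_id, assembly_id, sep = ":"),
    kind = kind, gene_id = gene_id, transcript_id = transcript_id,
    assembly = assembly_id, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand,
    length = nchar(sequence), sequence = sequence,
    internal_stop = internal_stop, len_not_multiple3 = len_not_multiple3
  )
}

# concatenate genomic slices in genomic order, reverse-complement for '-'
splice_seq <- function(chrseq, starts, ends, strand) {
  o <- order(starts)
  s <- paste(substring(chrseq, starts[o] + 1L, ends[o]), collapse = "")
  if (strand == "-") revcomp_chr(s) else s
}

translate_cds <- function(cds_seq) {
  n <- nchar(cds_seq)
  trimmed <- substring(cds_seq, 1L, (n %/% 3L) * 3L)
  pep <- if (nchar(trimmed) == 0) "" else {
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(trimmed),
      if.fuzzy.codon = "solve"
    )))
  }
  body <- substring(pep, 1L, max(0L, nchar(pep) - 1L))
  list(
    pep = pep,
    internal_stop = grepl("\\*", body),
    len_not_multiple3 = (n %% 3L) != 0L
  )
}

#' Mask long geneless regions of an assembly
#'
#' Replaces every maximal interval that overlaps no annotated gene and is
#' strictly longer than `min_geneless` with `N`. Bases overlapping any gene
#' body are never masked and total sequence length is conserved. This is the
#' pre-alignment masking step used for large repeat-rich genomes, where
#' geneless tracts longer than 1 Mbp accumulate repeats that defeat
#' whole-genome aligners.
#'
#' @param assembly An `assembly`.
#' @param min_geneless Minimum geneless tract length in bp to mask
#'   (default 1e6; tracts of exactly this length are left untouched).
#' @param path Optional output FASTA path; when given, the masked sequences
#'   are written wrapped at 60 columns.
#' @return A [Biostrings::DNAStringSet] of masked chromosome sequences
#'   (invisibly written to `path` when requested).
#' @export
mask_geneless <- function(assembly, min_geneless = 1000000L, path = NULL) {
  stopifnot(inherits(assembly, "assembly"))
  chars <- as.character(assembly$seqs)
  for (chrom in names(chars)) {
    len <- nchar(chars[[chrom]])
    g <- assembly$genes |> filter(.data$chrom == !!chrom)
    covered <- if (nrow(g) == 0) {
      IRanges::IRanges()
    } else {
      IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    }
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, len), covered)
    gaps <- gaps[IRanges::width(gaps) > min_geneless]
    for (i in seq_along(gaps)) {
      s <- IRanges::start(gaps)[i]
      e <- IRanges::end(gaps)[i]
      substr(chars[[chrom]], s, e) <- strrep("N", e - s + 1L)
    }
  }
  masked <- Biostrings::DNAStringSet(chars)
  if (!is.null(path)) Biostrings::writeXStringSet(masked, path, width = 60L)
  masked
}

#' Cut a genomic segment (gDNA) from an assembly
#'
#' Extracts the sequence of a genomic interval, reverse-complemented when
#' `strand` is `-`. Coordinates are 0-based half-open.
#'
#' @param assembly An `assembly`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return A one-row sequence-record tibble of kind `gdna`.
#' @export
cut_gdna <- function(assembly, chrom, start, end, strand = "+") {
  stopifnot(inherits(assembly, "assembly"))
  chrseq <- asm_seq(assembly, chrom)
  len <- nchar(chrseq)
  if (start < 0 || end > len || start >= end) {
    stop_pg(
      "interval %s:%d-%d out of bounds for chromosome of length %d (clipped would be %d-%d)",
      chrom, start, end, len, max(0L, start), min(len, end)
    )
  }
  s <- substring(chrseq, start + 1L, end)
  if (strand == "-") s <- revcomp_chr(s)
  record_row(
    gene_id = sprintf("%s:%d-%d", chrom, start, end),
    transcript_id = NA_character_,
    assembly_id = assembly$assembly_id, kind = "gdna",
    sequence = s, chrom = chrom, start = start, end = end, strand = strand
  )
}
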