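# Collinear evidence TSV: the on-disk exchange format for collinear gene
# pairs and gene/genomic-segment matches, plus conversion to PAF for
# dotplotting.

collinear_cols <- c(
  "gene_id_A", "assembly_A", "chrom_A", "start_A", "end_A", "strand_A",
  "gene_id_B", "assembly_B", "chrom_B", "start_B", "end_B", "strand_B",
  "overlap_bp", "wga_algorithm", "inverted", "pair_type"
)

empty_pairs <- function() {
  tibble(
    gene_id_A = character(), assembly_A = character(), chrom_A = character(),
    start_A = integer(), end_A = integer(), strand_A = character(),
    gene_id_B = character(), assembly_B = character(), chrom_B = character(),
    start_B = integer(), end_B = integer(), strand_B = character(),
    overlap_bp = integer(), wga_algorithm = character(),
    inverted = logical(), pair_type = character()
  )
}

#' Write collinear evidence to TSV
#'
#' Writes collinear pairs as a tab-separated file with a `#`-prefixed header.
#' The A side is always a gene model; the B side is a gene model
#' (`pair_type = "gene-gene"`) or a matched genomic segment
#' (`pair_type = "gene-gdna"`). Coordinates are 0-based half-open.
#' The write/read round trip is lossless.
#'
#' @param pairs A collinear-pair tibble (see [call_collinear_pairs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collinear_tsv <- function(pairs, path) {
  stopifnot(all(collinear_cols %in% names(pairs)))
  pairs <- pairs[, collinear_cols]
  header <- paste0("#", paste(collinear_cols, collapse = "\t"))
  body <- do.call(sprintf, c(
    list("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s\t%d\t%d\t%s\t%d\t%s\t%d\t%s"),
    as.list(pairs |> mutate(inverted = as.integer(.data$inverted)))
  ))
  readr::write_lines(c(header, if (nrow(pairs) > 0) body), path)
  invisible(path)
}

#' Read collinear evidence from TSV
#'
#' @param path Path written by [write_collinear_tsv()].
#' @return A collinear-pair tibble.
#' @export
read_collinear_tsv <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0) stop_pg("empty collinear TSV: %s", path)
  header <- sub("^#", "", lines[1])
  if (!identical(strsplit(header, "\t")[[1]], collinear_cols)) {
    stop_pg("unexpected collinear TSV header in %s", path)
  }
  body <- lines[-1]
  if (length(body) == 0) return(empty_pairs())
  out <- readr::read_tsv(
    I(body), col_names = collinear_cols,
    col_types = readr::cols(
      start_A = "i", end_A = "i", start_B = "i", end_B = "i",
      overlap_bp = "i", inverted = "i", .default = "c"
    ),
    progress = FALSE
  ) |> mutate(inverted = as.logical(.data$inverted))
  bad <- setdiff(unique(out$pair_type), c("gene-gene", "gene-gdna"))
  if (length(bad) > 0) stop_pg("unknown pair_type token '%s' in %s", bad[1], path)
  out
}

#' Convert collinear evidence TSV to PAF for dotplots
#'
#' Emits one PAF line per gene-gene pair, using the two gene intervals as
#' query (B side) and target (A side) blocks with a dummy all-`M` CIGAR of
#' the shorter interval's length and strand taken from the inverted flag.
#' `gene-gdna` rows are skipped (their count is reported). The output is
#' suitable for generic PAF dotplot tools.
#'
#' @param tsv_path Collinear TSV path.
#' @param out_path Output PAF path.
#' @return `out_path`, invisibly.
#' @export
tsv_to_paf <- function(tsv_path, out_path) {
  pairs <- read_collinear_tsv(tsv_path)
  gdna <- sum(pairs$pair_type == "gene-gdna")
  if (gdna > 0) inform(sprintf("tsv_to_paf: skipped %d gene-gdna row(s)", gdna))
  gg <- pairs |> filter(.data$pair_type == "gene-gene")
  if (nrow(gg) == 0) {
    readr::write_lines(character(), out_path)
    return(invisible(out_path))
  }
  blk <- pmin(gg$end_A - gg$start_A, gg$end_B - gg$start_B)
  lines <- sprintf(
    "%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255\tcg:Z:%dM",
    gg$chrom_B, gg$end_B, gg$start_B, gg$start_B + blk,
    ifelse(gg$inverted, "-", "+"),
    gg$chrom_A, gg$end_A, gg$start_A, gg$start_A + blk,
    blk, blk, blk
  )
  readr::write_lines(lines, out_path)
  invisible(out_path)
}
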