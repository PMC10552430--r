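# PAF parsing and CIGAR arithmetic. Alignments are tibbles with one row per
# PAF record; CIGAR strings use ops M/=/X/I/D. For '-' strand records the
# query coordinates follow PAF convention (forward strand) while the CIGAR
# describes the reverse-complemented query against the forward target, so
# CIGAR walking consumes query coordinates from `qend` downwards.

#' Parse a PAF whole-genome alignment file
#'
#' Reads PAF records (12 mandatory columns plus tags). The CIGAR is taken
#' from the `cg:Z:` tag; records carrying only a `cs:Z:` difference string
#' have it converted to an `=`/`X`/`I`/`D` CIGAR. Records flagged secondary
#' (`tp:A:S`) are dropped, records without any CIGAR are rejected, and
#' records whose CIGAR is inconsistent with the stated query/target spans
#' are rejected with their line number; counts of dropped records are
#' reported as messages.
#'
#' @param path Path to a PAF file.
#' @param source_algorithm Label stored in the `source` column
#'   (e.g. `"minimap2"`, `"gsalign"`, `"simulated"`).
#' @return A tibble with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`,
#'   `cigar`, `source`, `aln_id`. Coordinates are 0-based half-open as in
#'   PAF itself.
#' @export
parse_paf <- function(path, source_algorithm = "minimap2") {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  fields <- stringr::str_split(lines, "\t")

  n_secondary <- 0L; n_nocigar <- 0L; bad_lines <- integer()
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 12) {
      stop_pg("PAF line %d has %d columns; at least 12 required", i, length(f))
    }
    tags <- f[-(1:12)]
    if (any(startsWith(tags, "tp:A:S"))) { n_secondary <- n_secondary + 1L; next }
    cg <- sub("^cg:Z:", "", grep("^cg:Z:", tags, value = TRUE))
    if (length(cg) == 0) {
      cs <- sub("^cs:Z:", "", grep("^cs:Z:", tags, value = TRUE))
      if (length(cs) == 0) { n_nocigar <- n_nocigar + 1L; next }
      cg <- cs_to_cigar(cs[1])
    }
    row <- tibble(
      qname = f[1], qlen = as.integer(f[2]),
      qstart = as.integer(f[3]), qend = as.integer(f[4]),
      strand = f[5],
      tname = f[6], tlen = as.integer(f[7]),
      tstart = as.integer(f[8]), tend = as.integer(f[9]),
      nmatch = as.integer(f[10]), alen = as.integer(f[11]),
      mapq = as.integer(f[12]),
      cigar = cg[1], source = source_algorithm
    )
    ops <- cigar_ops(row$cigar)
    qspan <- sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
    tspan <- sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
    if (qspan != row$qend - row$qstart || tspan != row$tend - row$tstart) {
      bad_lines <- c(bad_lines, i); next
    }
    rows[[i]] <- row
  }
  if (n_secondary > 0) inform(sprintf("parse_paf: dropped %d secondary record(s)", n_secondary))
  if (n_nocigar > 0) inform(sprintf("parse_paf: rejected %d record(s) without CIGAR", n_nocigar))
  if (length(bad_lines) > 0) {
    inform(sprintf(
      "parse_paf: rejected %d record(s) with CIGAR inconsistent with coordinates (lines %s)",
      length(bad_lines), paste(bad_lines, collapse = ",")
    ))
  }
  out <- list_rbind(keep(rows, Negate(is.null)))
  if (is.null(out) || nrow(out) == 0) return(empty_paf())
  out |> mutate(aln_id = dplyr::row_number())
}

empty_paf <- function() {
  tibble(
    qname = character(), qlen = integer(), qstart = integer(), qend = integer(),
    strand = character(), tname = character(), tlen = integer(),
    tstart = integer(), tend = integer(), nmatch = integer(), alen = integer(),
    mapq = integer(), cigar = character(), source = character(), aln_id = integer()
  )
}

#' Write alignments back to PAF
#'
#' @param alignments An alignment tibble as produced by [parse_paf()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_paf <- function(alignments, path) {
  lines <- with(alignments, sprintf(
    "%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\tcg:Z:%s",
    qname, qlen, qstart, qend, strand, tname, tlen, tstart, tend,
    nmatch, alen, mapq, cigar
  ))
  readr::write_lines(lines, path)
  invisible(path)
}

# split a CIGAR into (len, op) runs
cigar_ops <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  if (sum(nchar(m[, 1])) != nchar(cigar)) stop_pg("malformed CIGAR: %s", cigar)
  tibble(len = as.integer(m[, 2]), op = m[, 3])
}

collapse_ops <- function(op_chars) {
  if (length(op_chars) == 0) return("")
  r <- rle(op_chars)
  paste0(r$lengths, r$values, collapse = "")
}

# Convert a minimap2 cs:Z: short difference string to an =/X/I/D CIGAR.
# Tokens: ":N" identical run, "*ab" substitution, "+seq" query insertion,
# "-seq" deletion from the query.
cs_to_cigar <- function(cs) {
  toks <- stringr::str_match_all(cs, ":(\\d+)|\\*([a-zA-Z]{2})|\\+([a-zA-Z]+)|-([a-zA-Z]+)")[[1]]
  if (sum(nchar(toks[, 1])) != nchar(cs)) stop_pg("malformed cs string: %s", cs)
  parts <- character(nrow(toks))
  for (i in seq_len(nrow(toks))) {
    if (!is.na(toks[i, 2])) parts[i] <- paste0(toks[i, 2], "=")
    else if (!is.na(toks[i, 3])) parts[i] <- "1X"
    else if (!is.na(toks[i, 4])) parts[i] <- paste0(nchar(toks[i, 4]), "I")
    else parts[i] <- paste0(nchar(toks[i, 5]), "D")
  }
  # merge adjacent runs of the same op
  ops <- cigar_ops(paste(parts, collapse = ""))
  merged <- ops |> mutate(grp = cumsum(c(TRUE, op[-1] != op[-dplyr::n()]))) |>
    group_by(.data$grp) |> summarise(len = sum(.data$len), op = dplyr::first(.data$op))
  paste0(merged$len, merged$op, collapse = "")
}

#' Decompose an alignment into gap-free mapped segments
#'
#' Walks the CIGAR of one alignment record and returns one segment per
#' maximal run of co-consuming ops (`M`/`=`/`X`); `I` advances only the
#' query cursor and `D` only the target cursor. For `-` strand alignments
#' the emitted query intervals are normalized to forward-strand
#' coordinates (query coordinates decrease as target coordinates increase).
#' Segments are the unit used for cross-assembly gene projection.
#'
#' @param alignments One or more alignment rows (tibble from [parse_paf()]).
#' @return A tibble of segments: `aln_id`, `qname`, `qstart`, `qend`,
#'   `tname`, `tstart`, `tend`, `strand`, ordered along the target; query
#'   and target intervals of a segment have equal lengths.
#' @export
cigar_to_segments <- function(alignments) {
  segs <- pmap(alignments, function(qname, qstart, qend, strand, tname, tstart,
                                    cigar, aln_id, ...) {
    ops <- cigar_ops(cigar)
    bad <- setdiff(unique(ops$op), c("M", "=", "X", "I", "D"))
    if (length(bad) > 0) stop_pg("unsupported CIGAR op '%s' in alignment %s", bad[1], aln_id)
    tcur <- tstart
    qcur <- if (strand == "+") qstart else qend # '-' walks query backwards
    out <- list()
    run_q <- NA_integer_; run_t <- NA_integer_; run_len <- 0L
    flush <- function() {
      if (run_len > 0L) {
        qs <- if (strand == "+") run_q else run_q - run_len
        out[[length(out) + 1L]] <<- tibble(
          aln_id = aln_id, qname = qname,
          qstart = qs, qend = qs + run_len,
          tname = tname, tstart = run_t, tend = run_t + run_len,
          strand = strand
        )
      }
      run_len <<- 0L
    }
    for (i in seq_len(nrow(ops))) {
      len <- ops$len[i]; op <- ops$op[i]
      if (op %in% c("M", "=", "X")) {
        if (run_len == 0L) { run_q <- qcur; run_t <- tcur }
        run_len <- run_len + len
        tcur <- tcur + len
        qcur <- if (strand == "+") qcur + len else qcur - len
      } else if (op == "I") {
        flush()
        qcur <- if (strand == "+") qcur + len else qcur - len
      } else { # D
        flush()
        tcur <- tcur + len
      }
    }
    flush()
    list_rbind(out)
  })
  out <- list_rbind(segs)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      aln_id = integer(), qname = character(), qstart = integer(),
      qend = integer(), tname = character(), tstart = integer(),
      tend = integer(), strand = character()
    ))
  }
  out |> arrange(.data$aln_id, .data$tstart)
}

#' Percent identity of one alignment over aligned columns
#'
#' Identity is `100 * matches / (matches + mismatches)`; indel columns are
#' excluded from the denominator. When the CIGAR distinguishes `=`/`X` the
#' counts come straight from it; `M` ops require the two sequences to be
#' supplied so matches can be resolved by direct comparison.
#'
#' @param alignment A one-row alignment tibble.
#' @param query_seq,target_seq Optional full-length sequences (character) of
#'   the query and target chromosomes, needed only for `M` CIGARs.
#' @return Percent identity in `[0, 100]`.
#' @export
alignment_identity <- function(alignment, query_seq = NULL, target_seq = NULL) {
  stopifnot(nrow(alignment) == 1)
  ops <- cigar_ops(alignment$cigar)
  has_m <- any(ops$op == "M")
  if (!has_m) {
    matches <- sum(ops$len[ops$op == "="])
    mism <- sum(ops$len[ops$op == "X"])
  } else {
    if (is.null(query_seq) || is.null(target_seq)) {
      stop_pg("identity unresolved: CIGAR contains M ops and no sequences supplied")
    }
    segs <- cigar_to_segments(alignment)
    matches <- 0L; mism <- 0L
    for (i in seq_len(nrow(segs))) {
      tchars <- substring(target_seq, segs$tstart[i] + 1L, segs$tend[i])
      qchars <- substring(query_seq, segs$qstart[i] + 1L, segs$qend[i])
      if (alignment$strand == "-") qchars <- revcomp_chr(qchars)
      a <- strsplit(tchars, "")[[1]]; b <- strsplit(qchars, "")[[1]]
      matches <- matches + sum(a == b)
      mism <- mism + sum(a != b)
    }
  }
  if (matches + mism == 0) return(NA_real_)
  100 * matches / (matches + mism)
}

#' Pairwise average nucleotide identity matrix
#'
#' Computes per-pair ANI as the aligned-column-weighted mean identity of all
#' alignments between the two assemblies. The weighting by aligned columns
#' is this package's estimator; aligner-internal ANI formulas may differ
#' slightly. Pairs with no alignments are `NA`, the diagonal is 100 and the
#' matrix is symmetric.
#'
#' @param alignments Alignment tibble carrying `query_assembly` and
#'   `target_assembly` columns (see [run_pipeline()] / the simulator).
#' @param assemblies Character vector of assembly ids ordering the matrix.
#' @return A square numeric matrix of percent identities.
#' @export
ani_matrix <- function(alignments, assemblies) {
  mat <- matrix(NA_real_, length(assemblies), length(assemblies),
                dimnames = list(assemblies, assemblies))
  diag(mat) <- 100
  if (nrow(alignments) > 0) {
    stats <- map(seq_len(nrow(alignments)), function(i) {
      row <- alignments[i, ]
      ops <- cigar_ops(row$cigar)
      tibble(
        query_assembly = row$query_assembly,
        target_assembly = row$target_assembly,
        ident = alignment_identity(row),
        cols = sum(ops$len[ops$op %in% c("M", "=", "X")])
      )
    }) |> list_rbind()
    per <- stats |>
      group_by(.data$query_assembly, .data$target_assembly) |>
      summarise(ani = sum(.data$ident * .data$cols) / sum(.data$cols), .groups = "drop")
    for (i in seq_len(nrow(per))) {
      a <- per$query_assembly[i]; b <- per$target_assembly[i]
      if (a %in% assemblies && b %in% assemblies) {
        mat[a, b] <- per$ani[i]; mat[b, a] <- per$ani[i]
      }
    }
  }
  mat
}
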