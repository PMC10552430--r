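# Independent oracles and toy fixture builders used across the suite.

# Per-base projection oracle: walk a CIGAR one base at a time and return
# the target position of every aligned query base (forward-strand query
# coordinates). Deliberately naive and independent of cigar_to_segments.
oracle_base_map <- function(qstart, qend, tstart, strand, cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", m))
  ops <- sub("^[0-9]+", "", m)
  # expand to one op character per base, then walk cursors with cumsum
  op_b <- rep(ops, lens)
  q_consume <- op_b %in% c("M", "=", "X", "I")
  t_consume <- op_b %in% c("M", "=", "X", "D")
  step <- if (strand == "+") 1L else -1L
  q0 <- if (strand == "+") qstart else qend - 1L
  q_at <- q0 + step * (cumsum(q_consume) - 1L)
  t_at <- tstart + cumsum(t_consume) - 1L
  aligned <- op_b %in% c("M", "=", "X")
  data.frame(q = q_at[aligned], t = t_at[aligned])
}

# random CIGAR over =/X/I/D (optionally M) with consistent PAF coordinates
random_alignment <- function(max_ops = 12L, max_run = 400L, use_m = FALSE) {
  n <- sample(3:max_ops, 1)
  ops <- sample(c("=", "X", "I", "D"), n, replace = TRUE,
                prob = c(0.6, 0.2, 0.1, 0.1))
  if (use_m) ops[ops %in% c("=", "X")] <- "M"
  ops[1] <- "="; ops[n] <- "="  # alignments start/end aligned
  lens <- sample(1:max_run, n, replace = TRUE)
  qspan <- sum(lens[ops %in% c("M", "=", "X", "I")])
  tspan <- sum(lens[ops %in% c("M", "=", "X", "D")])
  strand <- sample(c("+", "-"), 1)
  qstart <- sample(0:500, 1); tstart <- sample(0:500, 1)
  tibble::tibble(
    qname = "q", qlen = qstart + qspan + sample(0:100, 1),
    qstart = qstart, qend = qstart + qspan,
    strand = strand,
    tname = "t", tlen = tstart + tspan + sample(0:100, 1),
    tstart = tstart, tend = tstart + tspan,
    nmatch = sum(lens[ops == "="]), alen = sum(lens),
    mapq = 60L,
    cigar = paste0(lens, ops, collapse = ""),
    source = "test", aln_id = 1L
  )
}

# Brute-force collinear scanner over the full cross product of projected
# and target genes, applying the either-fraction + strand rule directly.
oracle_collinear_vec <- function(proj, targets, f = 0.5) {
  g <- expand.grid(i = seq_len(nrow(proj)), j = seq_len(nrow(targets)))
  ov <- pmin(proj$end[g$i], targets$end[g$j]) -
    pmax(proj$start[g$i], targets$start[g$j])
  la <- targets$end[g$j] - targets$start[g$j]
  lb <- proj$end[g$i] - proj$start[g$i]
  keep <- proj$chrom[g$i] == targets$chrom[g$j] & ov > 0 &
    (ov >= f * la | ov >= f * lb) &
    proj$strand[g$i] == targets$strand[g$j]
  out <- data.frame(
    gene_id_A = targets$gene_id[g$j][keep],
    gene_id_B = proj$gene_id[g$i][keep],
    overlap_bp = as.integer(ov[keep])
  )
  out[order(out$gene_id_A, out$gene_id_B), , drop = FALSE]
}

# Brute-force collinear scanner: double loop over projected genes and
# target genes applying the either-fraction + strand rule directly.
oracle_collinear <- function(proj, targets, f = 0.5) {
  hits <- list()
  for (i in seq_len(nrow(proj))) {
    for (j in seq_len(nrow(targets))) {
      if (proj$chrom[i] != targets$chrom[j]) next
      ov <- min(proj$end[i], targets$end[j]) - max(proj$start[i], targets$start[j])
      if (ov <= 0) next
      la <- targets$end[j] - targets$start[j]
      lb <- proj$end[i] - proj$start[i]
      if ((ov >= f * la || ov >= f * lb) && proj$strand[i] == targets$strand[j]) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id_A = targets$gene_id[j], gene_id_B = proj$gene_id[i],
          overlap_bp = ov
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(gene_id_A = character(), gene_id_B = character(),
                      overlap_bp = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$gene_id_A, out$gene_id_B), , drop = FALSE]
}

# Write a toy assembly (one chromosome) to FASTA + GFF3 and load it.
# genes: list of lists with gene_id, start, end, strand, exons (matrix-like
# list of c(start, end), 0-based half-open), optional cds (defaults to
# exons, phase 0 on the 5'-most segment).
toy_assembly <- function(seq, genes, assembly_id = "toy", chrom = "chr1",
                         dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, paste0(assembly_id, ".fna"))
  writeLines(c(paste0(">", chrom), seq), fa)
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, sprintf("%s\tt\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              chrom, g$start + 1L, g$end, g$strand, g$gene_id))
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines, sprintf("%s\tt\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                              chrom, g$start + 1L, g$end, g$strand, tid, g$gene_id))
    cds <- if (is.null(g$cds)) g$exons else g$cds
    for (e in g$exons) {
      lines <- c(lines, sprintf("%s\tt\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                chrom, e[1] + 1L, e[2], g$strand, tid))
    }
    segs <- cds
    phases <- rep(0L, length(segs))
    ord <- if (g$strand == "-") rev(seq_along(segs)) else seq_along(segs)
    cum <- 0L
    for (i in ord) {
      phases[i] <- (3L - cum %% 3L) %% 3L
      cum <- cum + (segs[[i]][2] - segs[[i]][1])
    }
    for (i in seq_along(segs)) {
      lines <- c(lines, sprintf("%s\tt\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                                chrom, segs[[i]][1] + 1L, segs[[i]][2],
                                g$strand, phases[i], tid))
    }
  }
  gff <- file.path(dir, paste0(assembly_id, ".gff3"))
  writeLines(lines, gff)
  load_assembly(fa, gff, assembly_id)
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal gene-table builder for clustering tests (no sequences involved)
gene_table <- function(ids, chrom = "chr1", start0 = 0L, len = 100L, gap = 50L,
                       strand = "+") {
  n <- length(ids)
  starts <- start0 + (seq_len(n) - 1L) * (len + gap)
  tibble::tibble(
    gene_id = ids, chrom = chrom, start = starts, end = starts + len,
    strand = strand, has_transcript = TRUE, rank = seq_len(n) - 1L
  )
}

# wrap gene tables into a minimal assembly object for greedy_cluster
fake_assembly <- function(assembly_id, genes) {
  structure(
    list(
      assembly_id = assembly_id,
      seqs = Biostrings::DNAStringSet(),
      genes = genes,
      transcripts = tibble::tibble(transcript_id = character(), gene_id = character()),
      exons = tibble::tibble(transcript_id = character(), start = integer(), end = integer()),
      cds = tibble::tibble(transcript_id = character(), start = integer(),
                           end = integer(), phase = integer())
    ),
    class = "assembly"
  )
}

# collinear pair row builder
pair_row <- function(a, asm_a, b, asm_b, overlap = 100L, inverted = FALSE,
                     type = "gene-gene", chrom = "chr1",
                     sa = 0L, ea = 100L, sb = 0L, eb = 100L) {
  tibble::tibble(
    gene_id_A = a, assembly_A = asm_a, chrom_A = chrom,
    start_A = sa, end_A = ea, strand_A = "+",
    gene_id_B = b, assembly_B = asm_b, chrom_B = chrom,
    start_B = sb, end_B = eb, strand_B = "+",
    overlap_bp = as.integer(overlap), wga_algorithm = "test",
    inverted = inverted, pair_type = type
  )
}

expect_segments_match_oracle <- function(aln) {
  segs <- cigar_to_segments(aln)
  om <- oracle_base_map(aln$qstart, aln$qend, aln$tstart, aln$strand, aln$cigar)
  # expand segments to per-base pairs
  got <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    n <- segs$tend[i] - segs$tstart[i]
    t <- segs$tstart[i]:(segs$tend[i] - 1L)
    q <- if (aln$strand == "+") {
      segs$qstart[i]:(segs$qend[i] - 1L)
    } else {
      (segs$qend[i] - 1L):segs$qstart[i]
    }
    data.frame(q = q, t = t)
  }))
  got <- got[order(got$t), , drop = FALSE]
  om <- om[order(om$t), , drop = FALSE]
  rownames(got) <- rownames(om) <- NULL
  expect_equal(got, om)
}
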