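# PAV confirmation by lift-over: consensus isoform selection, a built-in
# seed-and-extend spliced aligner (exact k-mer seeds chained colinearly,
# introns snapped to GT..AG when possible), cluster checking and patch-GFF
# emission.

#' Select consensus and outlier isoforms of a cluster
#'
#' The mode CDS length is the most frequent length among the cluster's CDS
#' records (ties go to the longest length). Isoforms within
#' `outlier_frac * mode_length` of the mode are the consensus; the rest are
#' outliers.
#'
#' @param cds_records Sequence-record tibble (kind `cds`) of one cluster.
#' @param outlier_frac Relative deviation tolerated from the mode length
#'   (default 0.5).
#' @return List with `consensus` and `outliers` (record tibbles) and
#'   `mode_length`.
#' @export
consensus_isoforms <- function(cds_records, outlier_frac = 0.5) {
  cds <- cds_records |> filter(.data$kind == "cds")
  if (nrow(cds) == 0) stop_pg("no coding evidence: cluster has no CDS records")
  tab <- table(cds$length)
  mode_length <- max(as.integer(names(tab)[tab == max(tab)]))
  ok <- abs(cds$length - mode_length) <= outlier_frac * mode_length
  list(
    consensus = cds[ok, , drop = FALSE],
    outliers = cds[!ok, , drop = FALSE],
    mode_length = mode_length
  )
}

#' Spliced alignment of a CDS/cDNA onto a genomic segment
#'
#' A seed-and-extend spliced aligner: exact k-mer seeds are collected,
#' merged along diagonals, chained colinearly (maximizing matched bases),
#' and the gaps between chained blocks are resolved as substitution runs
#' (equal-length gaps), introns (target gap at least `min_intron`, with
#' boundaries shifted to the nearest GT..AG donor/acceptor when one is
#' compatible with the aligned bases), or small indels (scored with a
#' pairwise alignment of the gap substrings). The query is aligned to the
#' sense strand given by `strand_hint` — the segment is
#' reverse-complemented first when the hint is `-`, and reported exon
#' blocks are converted back to forward-segment coordinates.
#'
#' @param query Query sequence (character; a CDS or cDNA).
#' @param segment Genomic segment sequence (character, forward strand).
#' @param strand_hint `"+"` or `"-"`: strand of the segment on which the
#'   query is expected (sense-forced).
#' @param k Seed k-mer length (default 12).
#' @param min_intron Minimum target gap treated as an intron (default 30).
#' @return `NULL` when no seed chain is found, otherwise a list:
#'   `exon_blocks` (tibble `start`,`end`, 0-based half-open on the forward
#'   segment), `strand`, `matches`, `mismatches`, `insertions_bp`,
#'   `deletions_bp`, `query_coverage`, `query_aligned` (`qstart`,`qend`),
#'   `spliced_seq` (the segment sequence under the exon blocks, spliced in
#'   transcript orientation).
#' @export
spliced_align <- function(query, segment, strand_hint = "+", k = 12L,
                          min_intron = 30L) {
  qlen <- nchar(query); slen <- nchar(segment)
  if (qlen < k || slen < k) return(NULL)
  seg <- if (strand_hint == "-") revcomp_chr(segment) else segment

  qv <- strsplit(query, "")[[1]]
  sv <- strsplit(seg, "")[[1]]

  blocks <- seed_blocks(query, seg, k)
  if (is.null(blocks) || nrow(blocks) == 0) return(NULL)
  chain <- chain_blocks(blocks)

  # resolve gaps between chained blocks
  matches <- 0L; mism <- 0L; ins_bp <- 0L; del_bp <- 0L
  exons <- list() # working exon: c(sstart, send) on seg coords, 0-based half-open
  cur <- c(chain$sstart[1], chain$send[1])
  matches <- matches + chain$len[1]

  add_exon <- function() exons[[length(exons) + 1L]] <<- cur

  n <- nrow(chain)
  if (n > 1) {
    for (i in 2:n) {
      qgap <- chain$qstart[i] - chain$qend[i - 1]
      sgap <- chain$sstart[i] - chain$send[i - 1]
      if (sgap - qgap >= min_intron) {
        # intron: split the query-gap bases between the flanking exons by
        # best direct match, then snap boundaries to GT..AG if compatible
        left_fit <- 0L
        if (qgap > 0) {
          fits <- map_int(0:qgap, function(nl) {
            nr <- qgap - nl
            lq <- qv[seq_len(nl) + chain$qend[i - 1]]
            ls <- sv[seq_len(nl) + chain$send[i - 1]]
            rq <- if (nr > 0) qv[chain$qstart[i] - nr + seq_len(nr)] else character()
            rs <- if (nr > 0) sv[chain$sstart[i] - nr + seq_len(nr)] else character()
            sum(lq == ls) + sum(rq == rs)
          })
          left_fit <- which.max(fits) - 1L
          matches <- matches + fits[left_fit + 1L]
          mism <- mism + qgap - fits[left_fit + 1L]
        }
        don <- cur[2] + left_fit            # intron start (0-based)
        acc <- chain$sstart[i] - (qgap - left_fit) # intron end (exclusive)
        snapped <- snap_intron(sv, qv, don, acc,
                               chain$qend[i - 1] + left_fit)
        cur[2] <- snapped$don
        add_exon()
        cur <- c(snapped$acc, chain$send[i])
        matches <- matches + chain$len[i]
      } else if (qgap == sgap) {
        # substitution run
        if (qgap > 0) {
          a <- qv[chain$qend[i - 1] + seq_len(qgap)]
          b <- sv[chain$send[i - 1] + seq_len(qgap)]
          matches <- matches + sum(a == b)
          mism <- mism + sum(a != b)
        }
        cur[2] <- chain$send[i]
        matches <- matches + chain$len[i]
      } else {
        # small indel: align the gap substrings
        if (qgap > 0 && sgap > 0) {
          sub <- gap_align(
            paste(qv[chain$qend[i - 1] + seq_len(qgap)], collapse = ""),
            paste(sv[chain$send[i - 1] + seq_len(sgap)], collapse = "")
          )
          matches <- matches + sub$matches
          mism <- mism + sub$mismatches
          ins_bp <- ins_bp + sub$insertions_bp
          del_bp <- del_bp + sub$deletions_bp
        } else if (qgap > 0) {
          ins_bp <- ins_bp + qgap
        } else {
          del_bp <- del_bp + sgap
        }
        cur[2] <- chain$send[i]
        matches <- matches + chain$len[i]
      }
    }
  }
  add_exon()

  # extend the outer ends of the terminal exons along the diagonal, keeping
  # only the best-scoring extension (match +1, mismatch -2) so a partially
  # present query is reported with honest coverage
  best_ext <- function(a, b) {
    sc <- cumsum(ifelse(a == b, 1L, -2L))
    if (max(sc) <= 0) return(0L)
    which.max(sc)
  }
  qhead <- chain$qstart[1]
  if (qhead > 0) {
    room <- min(qhead, exons[[1]][1])
    if (room > 0) {
      a <- rev(qv[qhead - seq_len(room) + 1L])
      b <- rev(sv[exons[[1]][1] - seq_len(room) + 1L])
      ext <- best_ext(a, b)
      if (ext > 0) {
        matches <- matches + sum(a[1:ext] == b[1:ext])
        mism <- mism + sum(a[1:ext] != b[1:ext])
        exons[[1]][1] <- exons[[1]][1] - ext
        qhead <- qhead - ext
      }
    }
  }
  qtail <- qlen - chain$qend[nrow(chain)]
  last <- length(exons)
  if (qtail > 0) {
    room <- min(qtail, slen - exons[[last]][2])
    if (room > 0) {
      a <- qv[chain$qend[nrow(chain)] + seq_len(room)]
      b <- sv[exons[[last]][2] + seq_len(room)]
      ext <- best_ext(a, b)
      if (ext > 0) {
        matches <- matches + sum(a[1:ext] == b[1:ext])
        mism <- mism + sum(a[1:ext] != b[1:ext])
        exons[[last]][2] <- exons[[last]][2] + ext
        qtail <- qtail - ext
      }
    }
  }

  qstart_aln <- qhead
  qend_aln <- qlen - qtail
  spliced <- paste(map_chr(exons, function(e) {
    paste(sv[(e[1] + 1):e[2]], collapse = "")
  }), collapse = "")

  # convert exon blocks back to forward-segment coordinates
  exon_tbl <- tibble(
    start = map_int(exons, function(e) as.integer(e[1])),
    end = map_int(exons, function(e) as.integer(e[2]))
  )
  if (strand_hint == "-") {
    exon_tbl <- tibble(
      start = slen - exon_tbl$end,
      end = slen - exon_tbl$start
    ) |> arrange(.data$start)
  }

  list(
    exon_blocks = exon_tbl,
    strand = strand_hint,
    matches = as.integer(matches),
    mismatches = as.integer(mism),
    insertions_bp = as.integer(ins_bp),
    deletions_bp = as.integer(del_bp),
    query_coverage = (qend_aln - qstart_aln) / qlen,
    query_aligned = c(qstart = qstart_aln, qend = qend_aln),
    spliced_seq = spliced
  )
}

# exact k-mer seed matches merged along diagonals into maximal blocks;
# coordinates 0-based half-open (qstart,qend,sstart,send,len)
seed_blocks <- function(query, seg, k) {
  qlen <- nchar(query); slen <- nchar(seg)
  qk <- substring(query, 1:(qlen - k + 1), k:qlen)
  sk <- substring(seg, 1:(slen - k + 1), k:slen)
  pos <- split(seq_along(sk) - 1L, sk)
  hits <- list()
  for (i in seq_along(qk)) {
    p <- pos[[qk[i]]]
    if (!is.null(p)) hits[[length(hits) + 1L]] <- cbind(q = i - 1L, s = p)
  }
  if (length(hits) == 0) return(NULL)
  m <- do.call(rbind, hits)
  d <- m[, "s"] - m[, "q"]
  df <- tibble(q = m[, "q"], s = m[, "s"], d = d) |> arrange(.data$d, .data$q)
  # merge overlapping/contiguous seeds on the same diagonal
  brk <- c(TRUE, diff(df$d) != 0 | diff(df$q) > k)
  grp <- cumsum(brk)
  df |>
    mutate(grp = grp) |>
    group_by(.data$grp) |>
    summarise(
      qstart = min(.data$q), qend = max(.data$q) + k,
      sstart = min(.data$s), send = max(.data$s) + k,
      .groups = "drop"
    ) |>
    mutate(len = .data$qend - .data$qstart) |>
    select(-"grp")
}

# Colinear chain maximizing total matched bases (quadratic DP over blocks).
# Blocks may overlap by a few bases where an intron head coincidentally
# matches the next exon's start; such overlaps are allowed up to `slack`
# and trimmed off the later block so the emitted chain is strictly
# colinear.
chain_blocks <- function(blocks, slack = 16L) {
  b <- blocks |> arrange(.data$qstart, .data$sstart)
  n <- nrow(b)
  score <- b$len
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (b$qstart[j] < b$qstart[i] && b$sstart[j] < b$sstart[i] &&
          b$qend[j] < b$qend[i] && b$send[j] < b$send[i] &&
          b$qend[j] <= b$qstart[i] + slack && b$send[j] <= b$sstart[i] + slack) {
        ov <- max(0L, b$qend[j] - b$qstart[i], b$send[j] - b$sstart[i])
        cand <- score[j] + b$len[i] - ov
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
  }
  i <- which.max(score)
  path <- integer()
  while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
  ch <- b[path, , drop = FALSE]
  for (pass in 1:5) {
    if (nrow(ch) < 2) break
    changed <- FALSE
    for (i in 2:nrow(ch)) {
      ov <- max(0L, ch$qend[i - 1] - ch$qstart[i], ch$send[i - 1] - ch$sstart[i])
      if (ov > 0L) {
        ch$qstart[i] <- ch$qstart[i] + ov
        ch$sstart[i] <- ch$sstart[i] + ov
        ch$len[i] <- ch$qend[i] - ch$qstart[i]
        changed <- TRUE
      }
    }
    ch <- ch |> filter(.data$len > 0)
    if (!changed) break
  }
  ch
}

# shift an intron within a small window to land on GT..AG while keeping the
# reassigned exon bases identical to the query
snap_intron <- function(sv, qv, don, acc, q_at_don, window = 12L) {
  is_gtag <- function(d, a) {
    d + 2 <= length(sv) && a >= 2 &&
      sv[d + 1] == "G" && sv[d + 2] == "T" && sv[a - 1] == "A" && sv[a] == "G"
  }
  if (is_gtag(don, acc)) return(list(don = don, acc = acc))
  for (sh in order(abs(seq(-window, window)))) {
    delta <- seq(-window, window)[sh]
    if (delta == 0) next
    d2 <- don + delta; a2 <- acc + delta
    if (d2 < 0 || a2 > length(sv)) next
    # moving the boundary by delta reassigns |delta| bases across the
    # intron; they must still match the query on both sides
    ok <- if (delta > 0) {
      all(sv[don + seq_len(delta)] == qv[q_at_don + seq_len(delta)]) &&
        all(sv[acc + seq_len(delta)] == sv[don + seq_len(delta)])
    } else {
      dd <- -delta
      all(sv[don - dd + seq_len(dd)] == sv[acc - dd + seq_len(dd)])
    }
    if (ok && is_gtag(d2, a2)) return(list(don = d2, acc = a2))
  }
  list(don = don, acc = acc)
}

# global alignment of two short gap substrings, for small-indel resolution
gap_align <- function(a, b) {
  if (nchar(a) == 0) return(list(matches = 0L, mismatches = 0L, insertions_bp = 0L, deletions_bp = nchar(b)))
  if (nchar(b) == 0) return(list(matches = 0L, mismatches = 0L, insertions_bp = nchar(a), deletions_bp = 0L))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", gapOpening = 4, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- pa != "-" & pb != "-"
  list(
    matches = sum(both & pa == pb),
    mismatches = sum(both & pa != pb),
    insertions_bp = sum(pb == "-"),
    deletions_bp = sum(pa == "-")
  )
}

# ORF classification of a spliced CDS candidate
orf_status <- function(spliced_seq, query_coverage, min_coverage = 1.0) {
  if (is.null(spliced_seq) || nchar(spliced_seq) == 0) return("no_alignment")
  if (query_coverage < min_coverage) return("partial")
  n <- nchar(spliced_seq)
  if (n %% 3L != 0L) return("not_multiple_of_3")
  if (substring(spliced_seq, 1, 3) != "ATG") return("partial")
  pep <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(spliced_seq), if.fuzzy.codon = "solve"
  )))
  if (substring(pep, nchar(pep), nchar(pep)) != "*") return("partial")
  if (grepl("\\*", substring(pep, 1, nchar(pep) - 1))) return("premature_stop")
  "intact"
}

#' Check a pangene cluster by lift-over
#'
#' Projects consensus CDS sequences of a cluster onto candidate genomic
#' regions and classifies the outcome.
#'
#' * `mode = "missing"`: each genomic-segment member (padded by `flank` on
#'   both sides) of an assembly lacking a gene member is probed with every
#'   consensus CDS; the best alignment decides. Verdict
#'   `missing_gene_confirmed` requires an intact ORF and full query
#'   coverage (`>= min_coverage`, default 1). Assemblies absent from the
#'   cluster with no candidate segment are reported `rejected` with
#'   `orf_status = "no_alignment"`.
#' * `mode = "split"`: the locus spanning an assembly's multiple members is
#'   probed with the consensus full-length CDS; an intact full-coverage ORF
#'   yields `split_fix`.
#' * `mode = "merged"`: the consensus CDS of this cluster and of
#'   `other_cds` are both aligned within the locus of the long member;
#'   disjoint intact ORFs yield `merged_fix` on both results.
#'
#' @param ps A named `pangene_set` with attached sequences.
#' @param cluster_id Cluster to check.
#' @param assemblies Named list of `assembly` objects keyed by id.
#' @param mode One of `"missing"`, `"split"`, `"merged"`.
#' @param flank Padding in bp around candidate segments (default 1000).
#' @param min_coverage Query coverage required to confirm (default 1.0).
#' @param outlier_frac Passed to [consensus_isoforms()].
#' @param other_cds For `mode = "merged"`: CDS records of the second
#'   cluster.
#' @return Tibble of lift-over results: `cluster_id`, `target_assembly`,
#'   `chrom`, `seg_start`, `seg_end`, `strand`, `matches`, `mismatches`,
#'   `insertions_bp`, `deletions_bp`, `query_coverage`, `orf_status`,
#'   `verdict`, `source_seq_id`, `exon_blocks` (list column, segment-local
#'   converted to chromosome coordinates).
#' @export
check_cluster <- function(ps, cluster_id, assemblies, mode = "missing",
                          flank = 1000L, min_coverage = 1.0,
                          outlier_frac = 0.5, other_cds = NULL) {
  stopifnot(inherits(ps, "pangene_set"), !is.null(ps$sequences))
  mode <- match.arg(mode, c("missing", "split", "merged"))
  if (is.null(names(assemblies))) {
    names(assemblies) <- map_chr(assemblies, "assembly_id")
  }
  cl <- ps$clusters |> filter(.data$cluster_id == !!cluster_id)
  if (nrow(cl) == 0) stop_pg("unknown cluster '%s'", cluster_id)
  cds <- ps$sequences |>
    filter(.data$cluster_id == !!cluster_id, .data$kind == "cds")
  cons <- consensus_isoforms(cds, outlier_frac)

  if (mode == "missing") {
    res <- check_missing(ps, cluster_id, cl, cons, assemblies, flank, min_coverage)
  } else if (mode == "split") {
    res <- check_split(cluster_id, cl, cons, assemblies, flank, min_coverage)
  } else {
    if (is.null(other_cds)) stop_pg("mode 'merged' needs other_cds")
    res <- check_merged(cluster_id, cl, cons, other_cds, assemblies, flank,
                        min_coverage, outlier_frac)
  }
  if (is.null(res) || nrow(res) == 0) {
    inform(sprintf("check_cluster: no candidates for cluster '%s' in mode '%s'",
                   cluster_id, mode))
    return(empty_liftover())
  }
  res
}

empty_liftover <- function() {
  tibble(
    cluster_id = character(), target_assembly = character(),
    chrom = character(), seg_start = integer(), seg_end = integer(),
    strand = character(), matches = integer(), mismatches = integer(),
    insertions_bp = integer(), deletions_bp = integer(),
    query_coverage = double(), orf_status = character(),
    verdict = character(), source_seq_id = character(),
    exon_blocks = list()
  )
}

liftover_row <- function(cluster_id, target_assembly, chrom, seg_start, seg_end,
                         aln, status, verdict, source_seq_id) {
  tibble(
    cluster_id = cluster_id, target_assembly = target_assembly,
    chrom = chrom, seg_start = as.integer(seg_start), seg_end = as.integer(seg_end),
    strand = if (is.null(aln)) NA_character_ else aln$strand,
    matches = if (is.null(aln)) 0L else aln$matches,
    mismatches = if (is.null(aln)) 0L else aln$mismatches,
    insertions_bp = if (is.null(aln)) 0L else aln$insertions_bp,
    deletions_bp = if (is.null(aln)) 0L else aln$deletions_bp,
    query_coverage = if (is.null(aln)) 0 else aln$query_coverage,
    orf_status = status, verdict = verdict,
    source_seq_id = source_seq_id,
    exon_blocks = list(if (is.null(aln)) tibble(start = integer(), end = integer())
                       else aln$exon_blocks)
  )
}

# best consensus CDS alignment on one padded segment
probe_segment <- function(cons, assembly, chrom, start, end, strand, flank,
                          min_coverage) {
  len <- nchar(asm_seq(assembly, chrom))
  lo <- max(0L, start - flank); hi <- min(len, end + flank)
  segseq <- substring(asm_seq(assembly, chrom), lo + 1L, hi)
  best <- NULL; best_id <- NA_character_
  for (i in seq_len(nrow(cons$consensus))) {
    q <- cons$consensus$sequence[i]
    aln <- spliced_align(q, segseq, strand_hint = strand)
    if (is.null(aln)) next
    better <- is.null(best) ||
      aln$matches > best$matches ||
      (aln$matches == best$matches && aln$mismatches < best$mismatches)
    if (better) { best <- aln; best_id <- cons$consensus$seq_id[i] }
  }
  if (!is.null(best)) {
    best$exon_blocks <- best$exon_blocks |>
      mutate(start = .data$start + lo, end = .data$end + lo)
  }
  list(aln = best, seq_id = best_id, lo = lo, hi = hi)
}

check_missing <- function(ps, cluster_id, cl, cons, assemblies, flank, min_coverage) {
  present <- unique(cl$assembly[cl$type == "gene"])
  absent <- setdiff(ps$assemblies, present)
  segs <- cl |> filter(.data$type == "segment")
  out <- list()
  for (asm in absent) {
    s <- segs |> filter(.data$assembly == asm)
    if (nrow(s) == 0) {
      out[[length(out) + 1L]] <- liftover_row(
        cluster_id, asm, NA_character_, NA_integer_, NA_integer_,
        NULL, "no_alignment", "rejected", NA_character_
      )
      next
    }
    for (i in seq_len(nrow(s))) {
      pr <- probe_segment(cons, assemblies[[asm]], s$chrom[i], s$start[i],
                          s$end[i], s$strand[i], flank, min_coverage)
      if (is.null(pr$aln)) {
        out[[length(out) + 1L]] <- liftover_row(
          cluster_id, asm, s$chrom[i], s$start[i], s$end[i],
          NULL, "no_alignment", "rejected", NA_character_
        )
        next
      }
      status <- orf_status(pr$aln$spliced_seq, pr$aln$query_coverage, min_coverage)
      verdict <- if (status == "intact" && pr$aln$query_coverage >= min_coverage) {
        "missing_gene_confirmed"
      } else "rejected"
      out[[length(out) + 1L]] <- liftover_row(
        cluster_id, asm, s$chrom[i], s$start[i], s$end[i],
        pr$aln, status, verdict, pr$seq_id
      )
    }
  }
  list_rbind(out)
}

check_split <- function(cluster_id, cl, cons, assemblies, flank, min_coverage) {
  multi <- cl |>
    filter(.data$type == "gene") |>
    group_by(.data$assembly) |>
    filter(dplyr::n() > 1) |>
    ungroup()
  if (nrow(multi) == 0) return(NULL)
  out <- list()
  for (asm in unique(multi$assembly)) {
    m <- multi |> filter(.data$assembly == asm)
    if (length(unique(m$chrom)) > 1) next
    pr <- probe_segment(cons, assemblies[[asm]], m$chrom[1], min(m$start),
                        max(m$end), m$strand[1], flank, min_coverage)
    if (is.null(pr$aln)) {
      out[[length(out) + 1L]] <- liftover_row(
        cluster_id, asm, m$chrom[1], min(m$start), max(m$end),
        NULL, "no_alignment", "rejected", NA_character_
      )
      next
    }
    status <- orf_status(pr$aln$spliced_seq, pr$aln$query_coverage, min_coverage)
    verdict <- if (status == "intact" && pr$aln$query_coverage >= min_coverage) {
      "split_fix"
    } else "rejected"
    out[[length(out) + 1L]] <- liftover_row(
      cluster_id, asm, m$chrom[1], min(m$start), max(m$end),
      pr$aln, status, verdict, pr$seq_id
    )
  }
  list_rbind(out)
}

check_merged <- function(cluster_id, cl, cons, other_cds, assemblies, flank,
                         min_coverage, outlier_frac) {
  cons2 <- consensus_isoforms(other_cds, outlier_frac)
  # candidate loci: the longest gene member of this cluster per assembly
  loci <- cl |> filter(.data$type == "gene") |>
    mutate(len = .data$end - .data$start) |>
    group_by(.data$assembly) |>
    arrange(dplyr::desc(.data$len), .by_group = TRUE) |>
    slice(1) |> ungroup()
  out <- list()
  for (i in seq_len(nrow(loci))) {
    asm <- loci$assembly[i]
    pr1 <- probe_segment(cons, assemblies[[asm]], loci$chrom[i], loci$start[i],
                         loci$end[i], loci$strand[i], flank, min_coverage)
    pr2 <- probe_segment(cons2, assemblies[[asm]], loci$chrom[i], loci$start[i],
                         loci$end[i], loci$strand[i], flank, min_coverage)
    if (is.null(pr1$aln) || is.null(pr2$aln)) next
    s1 <- orf_status(pr1$aln$spliced_seq, pr1$aln$query_coverage, min_coverage)
    s2 <- orf_status(pr2$aln$spliced_seq, pr2$aln$query_coverage, min_coverage)
    r1 <- range(unlist(pr1$aln$exon_blocks))
    r2 <- range(unlist(pr2$aln$exon_blocks))
    disjoint <- r1[2] <= r2[1] || r2[2] <= r1[1]
    verdict <- if (s1 == "intact" && s2 == "intact" && disjoint) "merged_fix" else "rejected"
    out[[length(out) + 1L]] <- liftover_row(
      cluster_id, asm, loci$chrom[i], loci$start[i], loci$end[i],
      pr1$aln, s1, verdict, pr1$seq_id
    )
    out[[length(out) + 1L]] <- liftover_row(
      cluster_id, asm, loci$chrom[i], loci$start[i], loci$end[i],
      pr2$aln, s2, verdict, pr2$seq_id
    )
  }
  list_rbind(out)
}

#' Emit a patch GFF3 file from lift-over results
#'
#' Writes one gene/mRNA/exon/CDS block per confirming result
#' (`missing_gene_confirmed`, `split_fix` or `merged_fix`), with 1-based
#' inclusive coordinates, strand from the alignment, and attributes that
#' carry the source sequence and cluster id. Rejected results never
#' produce records. Overlapping same-strand patch models are all written
#' with a warning.
#'
#' @param results Lift-over tibble from [check_cluster()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
emit_patch_gff <- function(results, path) {
  conf <- results |>
    filter(.data$verdict %in% c("missing_gene_confirmed", "split_fix", "merged_fix")) |>
    arrange(.data$chrom, map_int(.data$exon_blocks, function(b) {
      if (nrow(b) == 0) NA_integer_ else min(b$start)
    }))
  lines <- "##gff-version 3"
  if (nrow(conf) > 0) {
    spans <- map(conf$exon_blocks, function(b) c(min(b$start), max(b$end)))
    # warn on overlapping same-strand patches
    for (i in seq_len(nrow(conf))) {
      for (j in seq_len(i - 1)) {
        if (identical(conf$chrom[i], conf$chrom[j]) &&
            identical(conf$strand[i], conf$strand[j]) &&
            spans[[i]][1] < spans[[j]][2] && spans[[j]][1] < spans[[i]][2]) {
          warn("emit_patch_gff: overlapping patch models on the same strand")
        }
      }
    }
    for (i in seq_len(nrow(conf))) {
      b <- conf$exon_blocks[[i]] |> arrange(.data$start)
      gid <- sprintf("patch_%s_%s", sanitize_id(conf$cluster_id[i]),
                     conf$target_assembly[i])
      span <- spans[[i]]
      attrs <- sprintf("ID=%s;source_gene=%s;cluster=%s",
                       gid, conf$source_seq_id[i], conf$cluster_id[i])
      lines <- c(lines,
        sprintf("%s\tpangenes\tgene\t%d\t%d\t.\t%s\t.\t%s",
                conf$chrom[i], span[1] + 1L, span[2], conf$strand[i], attrs),
        sprintf("%s\tpangenes\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                conf$chrom[i], span[1] + 1L, span[2], conf$strand[i], gid, gid)
      )
      phase <- 0L
      ord <- if (conf$strand[i] == "-") rev(seq_len(nrow(b))) else seq_len(nrow(b))
      cds_phase <- integer(nrow(b))
      for (kidx in seq_along(ord)) {
        e <- ord[kidx]
        cds_phase[e] <- phase
        phase <- (3L - ((b$end[e] - b$start[e]) - phase) %% 3L) %% 3L
      }
      for (e in seq_len(nrow(b))) {
        lines <- c(lines,
          sprintf("%s\tpangenes\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
                  conf$chrom[i], b$start[e] + 1L, b$end[e], conf$strand[i], gid, e, gid),
          sprintf("%s\tpangenes\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.t1.cds;Parent=%s.t1",
                  conf$chrom[i], b$start[e] + 1L, b$end[e], conf$strand[i],
                  cds_phase[e], gid, gid)
        )
      }
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}
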