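# Synthetic pangenome simulator: an ancestor genome with multi-exon genes,
# derived assemblies with seeded SNPs/indels and planted structural events
# (gene deletions, a partial deletion, inversions, split annotations,
# hidden-but-present genes, tandem duplications), and the exact pairwise
# PAF alignments implied by the edit history. Event gene bodies are
# protected from SNPs/indels in every assembly so planted events stay
# cleanly interpretable; SNPs are additionally excluded from CDS bases and
# splice-site dinucleotides so untouched genes remain intact ORFs.

#' Simulator configuration
#'
#' Defaults describe a family of closely related genotypes: ~50 multi-exon
#' genes on one chromosome across 4 assemblies, with a per-eligible-base
#' SNP rate chosen so that genome-wide identity sits near 97% (SNPs fall
#' only outside CDS, splice dinucleotides and planted-event regions), plus
#' a handful of planted structural events of each kind.
#'
#' @param seed Integer RNG seed (all randomness derives from it).
#' @param n_assemblies,n_chromosomes,n_genes Sizes.
#' @param mean_gene_len Informative only; gene length emerges from
#'   `exons_per_gene` and per-exon lengths (90-240 bp exons, 60-120 bp
#'   introns).
#' @param mean_intergenic_len Mean intergenic spacer (bp).
#' @param exons_per_gene Integer range `c(lo, hi)`.
#' @param snp_rate Per-assembly, per-eligible-base substitution probability;
#'   pairwise divergence is roughly twice this, so the default 0.03 yields
#'   pairwise identities near 97% over aligned columns.
#' @param indel_rate Per-eligible-base small indel probability (intergenic
#'   only, lengths 1-8).
#' @param n_deletions Whole-gene presence-absence deletions.
#' @param n_inversions Inversions, each spanning two adjacent genes.
#' @param n_split_annotations Genes annotated as two partial models (the
#'   sequence stays intact).
#' @param n_hidden_genes Genes with intact sequence but no annotation
#'   record.
#' @param n_tandem_duplications Genes duplicated in tandem (extra annotated
#'   copy).
#' @param n_partial_deletions Genes with all exons but the last deleted
#'   (the last exon is built long so the locus still projects); the
#'   annotation record is removed.
#' @param p_second_isoform Probability that a non-event gene carries a
#'   second isoform skipping its first exon.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_assemblies = 4L, n_chromosomes = 1L,
                       n_genes = 50L, mean_gene_len = 650L,
                       mean_intergenic_len = 400L, exons_per_gene = c(2L, 4L),
                       snp_rate = 0.03, indel_rate = 0.002,
                       n_deletions = 5L, n_inversions = 1L,
                       n_split_annotations = 1L, n_hidden_genes = 1L,
                       n_tandem_duplications = 1L, n_partial_deletions = 0L,
                       p_second_isoform = 0.2) {
  cfg <- as.list(environment())
  stopifnot(cfg$snp_rate >= 0, cfg$snp_rate <= 1, cfg$indel_rate >= 0,
            cfg$indel_rate <= 1, cfg$n_assemblies >= 2, cfg$n_genes >= 1)
  n_events <- n_deletions + n_hidden_genes + n_split_annotations +
    n_tandem_duplications + n_partial_deletions + 2L * n_inversions
  if (n_events > n_genes / 2) {
    stop_pg("too many planted events (%d) for %d genes", n_events, n_genes)
  }
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

comp_chars <- function(ch) chartr("ACGTN", "TGCAN", ch)

rand_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(matrix(sample(BASES, len - 6, replace = TRUE), nrow = 3), 2, paste, collapse = "")
  # resample any stop codon drawn mid-ORF
  while (any(codons %in% STOPS)) {
    i <- which(codons %in% STOPS)
    codons[i] <- map_chr(i, function(x) paste(sample(BASES, 3, replace = TRUE), collapse = ""))
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOPS, 1))
}

# one ancestor gene: exon/intron structure plus genomic sequence
make_gene <- function(n_ex, exon_lens = NULL, intron_lens = NULL) {
  if (is.null(exon_lens)) exon_lens <- sample(90:240, n_ex, replace = TRUE)
  tot <- sum(exon_lens)
  exon_lens[1] <- exon_lens[1] + (3L - tot %% 3L) %% 3L
  tot <- sum(exon_lens)
  if (is.null(intron_lens)) {
    intron_lens <- if (n_ex > 1) sample(60:120, n_ex - 1, replace = TRUE) else integer()
  }
  orf <- rand_orf(tot)
  exon_seqs <- substring(orf, cumsum(c(0, head(exon_lens, -1))) + 1,
                         cumsum(exon_lens))
  introns <- map_chr(intron_lens, function(l) {
    paste0("GT", rand_dna(l - 4L), "AG")
  })
  tx <- exon_seqs[1]
  for (i in seq_along(introns)) tx <- paste0(tx, introns[i], exon_seqs[i + 1])
  strand <- sample(c("+", "-"), 1)
  gseq <- if (strand == "-") revcomp_chr(tx) else tx
  # exon offsets within the gene, in genomic orientation
  tx_starts <- cumsum(c(0, exon_lens[-n_ex] + intron_lens))
  tx_ends <- tx_starts + exon_lens
  if (strand == "-") {
    glen <- nchar(gseq)
    g_starts <- glen - tx_ends
    g_ends <- glen - tx_starts
    o <- order(g_starts)
    exon_off <- tibble(start = g_starts[o], end = g_ends[o])
  } else {
    exon_off <- tibble(start = tx_starts, end = tx_ends)
  }
  list(seq = gseq, strand = strand, exons = exon_off, cds_len = tot,
       n_ex = n_ex, exon_lens = exon_lens)
}

# CDS phases for segments given in genomic order
cds_phases <- function(starts, ends, strand) {
  n <- length(starts)
  ord <- if (strand == "-") rev(seq_len(n)) else seq_len(n)
  phase <- integer(n); cum <- 0L
  for (i in ord) {
    phase[i] <- (3L - cum %% 3L) %% 3L
    cum <- cum + (ends[i] - starts[i])
  }
  phase
}

build_ancestor <- function(cfg) {
  per_chr <- rep(cfg$n_genes %/% cfg$n_chromosomes, cfg$n_chromosomes)
  if (cfg$n_chromosomes > 0) {
    per_chr[1] <- per_chr[1] + cfg$n_genes %% cfg$n_chromosomes
  }
  gene_no <- 0L
  chroms <- list()
  genes <- list()
  spacer_len <- function() {
    max(150L, as.integer(round(runif(1, 0.6, 1.4) * cfg$mean_intergenic_len)))
  }
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- sprintf("chr%d", ci)
    pieces <- character(); pos <- 0L
    sp <- spacer_len(); pieces <- c(pieces, rand_dna(sp)); pos <- pos + sp
    for (gi in seq_len(per_chr[ci])) {
      gene_no <- gene_no + 1L
      g <- make_gene(sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1))
      glen <- nchar(g$seq)
      genes[[gene_no]] <- tibble(
        anc_id = sprintf("g%03d", gene_no), chrom = chrom,
        start = pos, end = pos + glen, strand = g$strand,
        exons = list(g$exons |> mutate(start = .data$start + pos, end = .data$end + pos)),
        cds_len = g$cds_len, n_ex = g$n_ex
      )
      pieces <- c(pieces, g$seq); pos <- pos + glen
      sp <- spacer_len(); pieces <- c(pieces, rand_dna(sp)); pos <- pos + sp
    }
    chroms[[chrom]] <- paste(pieces, collapse = "")
  }
  list(chroms = chroms, genes = list_rbind(genes))
}

# rebuild one ancestor gene with a long final exon so that a partial
# deletion of the earlier exons leaves a projectable locus
rebuild_partial_target <- function(anc, anc_id) {
  i <- which(anc$genes$anc_id == anc_id)
  old <- anc$genes[i, ]
  g <- make_gene(4L, exon_lens = c(90L, 90L, 90L, 600L),
                 intron_lens = c(70L, 70L, 70L))
  chrom <- old$chrom
  seq <- anc$chroms[[chrom]]
  new_seq <- paste0(substring(seq, 1, old$start),
                    g$seq,
                    substring(seq, old$end + 1))
  delta <- nchar(g$seq) - (old$end - old$start)
  anc$chroms[[chrom]] <- new_seq
  # shift downstream genes on the same chromosome
  down <- which(anc$genes$chrom == chrom & anc$genes$start > old$start &
                  seq_len(nrow(anc$genes)) != i)
  anc$genes$start[down] <- anc$genes$start[down] + delta
  anc$genes$end[down] <- anc$genes$end[down] + delta
  anc$genes$exons[down] <- map(anc$genes$exons[down], function(e) {
    e |> mutate(start = .data$start + delta, end = .data$end + delta)
  })
  anc$genes$start[i] <- old$start
  anc$genes$end[i] <- old$start + nchar(g$seq)
  anc$genes$strand[i] <- g$strand
  anc$genes$exons[[i]] <- g$exons |>
    mutate(start = .data$start + old$start, end = .data$end + old$start)
  anc$genes$cds_len[i] <- g$cds_len
  anc$genes$n_ex[i] <- g$n_ex
  anc
}

plan_events <- function(cfg, anc, reserved = character()) {
  genes <- anc$genes
  asm_pool <- sprintf("asm%d", 2:cfg$n_assemblies)
  take_asm <- local({
    k <- 0L
    function() {
      k <<- k + 1L
      asm_pool[(k - 1L) %% length(asm_pool) + 1L]
    }
  })
  free <- !(genes$anc_id %in% reserved)
  events <- list()
  # inversions first: two adjacent free genes on one chromosome
  for (e in seq_len(cfg$n_inversions)) {
    found <- FALSE
    cand <- sample(seq_len(nrow(genes) - 1L))
    for (i in cand) {
      if (free[i] && free[i + 1] && genes$chrom[i] == genes$chrom[i + 1]) {
        free[c(i, i + 1)] <- FALSE
        # breakpoints at spacer midpoints flanking the two genes
        prev_end <- if (i > 1 && genes$chrom[i - 1] == genes$chrom[i]) genes$end[i - 1] else 0L
        nxt <- i + 2L
        chrom_len <- nchar(anc$chroms[[genes$chrom[i]]])
        next_start <- if (nxt <= nrow(genes) && genes$chrom[nxt] == genes$chrom[i]) {
          genes$start[nxt]
        } else chrom_len
        s <- (prev_end + genes$start[i]) %/% 2L
        e2 <- (genes$end[i + 1] + next_start) %/% 2L
        events[[length(events) + 1L]] <- tibble(
          event = "inversion", assembly = take_asm(),
          anc_id = paste(genes$anc_id[c(i, i + 1)], collapse = ","),
          chrom = genes$chrom[i], start = s, end = e2
        )
        found <- TRUE
        break
      }
    }
    if (!found) stop_pg("could not place inversion %d: no free adjacent gene pair", e)
  }
  pick_free <- function(n, need_exons = 1L) {
    ok <- which(free & anc$genes$n_ex >= need_exons)
    if (length(ok) < n) stop_pg("not enough free genes for planted events")
    sel <- sample(ok, n)
    free[sel] <<- FALSE
    sel
  }
  single <- function(type, n, need_exons = 1L) {
    for (i in pick_free(n, need_exons)) {
      events[[length(events) + 1L]] <<- tibble(
        event = type, assembly = take_asm(), anc_id = genes$anc_id[i],
        chrom = genes$chrom[i], start = genes$start[i], end = genes$end[i]
      )
    }
  }
  single("deletion", cfg$n_deletions)
  single("hidden", cfg$n_hidden_genes)
  single("split", cfg$n_split_annotations, need_exons = 2L)
  single("tandem", cfg$n_tandem_duplications)
  for (rid in reserved) {
    i <- which(genes$anc_id == rid)
    events[[length(events) + 1L]] <- tibble(
      event = "partial_deletion", assembly = take_asm(), anc_id = rid,
      chrom = genes$chrom[i], start = genes$start[i], end = genes$end[i]
    )
  }
  out <- list_rbind(events)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(event = character(), assembly = character(),
                  anc_id = character(), chrom = character(),
                  start = integer(), end = integer())
  }
  out
}

#' Simulate a family of annotated assemblies with ground truth
#'
#' Generates an ancestor genome, derives `n_assemblies` assemblies by
#' applying seeded SNPs, small intergenic indels and the configured
#' structural events, writes per-assembly FASTA + GFF3 and per-pair PAF
#' files (alignments computed from the tracked edit history, not by
#' running an aligner — they are exact), and returns the ground truth.
#' `asm1` carries no structural events; events are spread round-robin over
#' the other assemblies. Same seed, same bytes.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created).
#' @return List: `config`, `dir`, `assemblies` (ids), `fasta`, `gff`,
#'   `paf` (named paths), `alignments` (tibble with `query_assembly` /
#'   `target_assembly`), `truth` (list: `genes`, `members`, `events`,
#'   `expected_occupancy`, `inverted_genes`, `split_clusters`,
#'   `tandem_clusters`, `hidden`, `deleted`).
#' @export
simulate_pangenome <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(cfg$seed, simulate_impl(cfg, outdir))
}

simulate_impl <- function(cfg, outdir) {
  anc <- build_ancestor(cfg)
  # partial-deletion targets are rebuilt (long last exon) before any event
  # coordinates are fixed, so every planned interval is final
  partial_ids <- character()
  if (cfg$n_partial_deletions > 0) {
    cand <- which(anc$genes$n_ex >= 2)
    sel <- sample(cand, cfg$n_partial_deletions)
    partial_ids <- anc$genes$anc_id[sel]
    for (pid in partial_ids) anc <- rebuild_partial_target(anc, pid)
  }
  events <- plan_events(cfg, anc, reserved = partial_ids)

  asm_ids <- sprintf("asm%d", seq_len(cfg$n_assemblies))

  # second isoforms on non-event genes
  event_genes <- unique(unlist(strsplit(events$anc_id, ",")))
  iso2 <- anc$genes$anc_id[
    !(anc$genes$anc_id %in% event_genes) &
      anc$genes$n_ex >= 2 &
      runif(nrow(anc$genes)) < cfg$p_second_isoform
  ]

  # per-chromosome protected / eligibility masks (ancestor coordinates)
  masks <- map(names(anc$chroms), function(chrom) {
    L <- nchar(anc$chroms[[chrom]])
    protect <- rep(FALSE, L) # no SNPs and no indels here, any assembly
    cdsmask <- rep(FALSE, L)
    genemask <- rep(FALSE, L)
    g <- anc$genes |> filter(.data$chrom == !!chrom)
    for (i in seq_len(nrow(g))) {
      genemask[(g$start[i] + 1):g$end[i]] <- TRUE
      ex <- g$exons[[i]]
      for (j in seq_len(nrow(ex))) cdsmask[(ex$start[j] + 1):ex$end[j]] <- TRUE
      # splice dinucleotides: 2 bases flanking each internal exon boundary
      if (nrow(ex) > 1) {
        for (j in seq_len(nrow(ex) - 1)) {
          protect[(ex$end[j] + 1):min(L, ex$end[j] + 2)] <- TRUE
          protect[max(1, ex$start[j + 1] - 1):ex$start[j + 1]] <- TRUE
        }
      }
    }
    ev <- events |> filter(.data$chrom == !!chrom)
    for (i in seq_len(nrow(ev))) {
      lo <- max(1L, ev$start[i] - 10L)
      hi <- min(L, ev$end[i] + 60L) # margin covers tandem insertion anchors
      protect[lo:hi] <- TRUE
    }
    list(protect = protect, cds = cdsmask, gene = genemask, L = L)
  })
  names(masks) <- names(anc$chroms)

  # per-assembly edits, ancestor coordinates
  edits <- map(asm_ids, function(asm) {
    per_chr <- map(names(anc$chroms), function(chrom) {
      m <- masks[[chrom]]
      chars <- strsplit(anc$chroms[[chrom]], "")[[1]]
      snp_ok <- !m$protect & !m$cds
      snp_pos <- which(snp_ok & rbinom(m$L, 1, cfg$snp_rate) == 1L)
      alt <- map_chr(snp_pos, function(p) sample(setdiff(BASES, chars[p]), 1))
      ind_ok <- !m$protect & !m$gene
      # keep indels clear of gene boundaries
      ind_pos <- sort(which(ind_ok & rbinom(m$L, 1, cfg$indel_rate) == 1L))
      ins <- list(); dels <- list()
      blocked <- rep(FALSE, m$L) # bases removed by an earlier small deletion
      for (p in ind_pos) {
        len <- sample(1:8, 1)
        if (runif(1) < 0.5) {
          if (!blocked[p]) {
            # anchored on the (kept) base at 0-based position p - 1
            ins[[length(ins) + 1L]] <- tibble(anchor = p - 1L, seq = rand_dna(len),
                                              kind = "indel", anc_gene = NA_character_)
          }
        } else {
          hi <- min(p + len - 1L, m$L)
          if (all(ind_ok[p:hi]) && !any(blocked[p:hi])) {
            dels[[length(dels) + 1L]] <- tibble(start = p - 1L, end = hi)
            blocked[p:hi] <- TRUE
          }
        }
      }
      ev <- events |> filter(.data$assembly == asm, .data$chrom == !!chrom)
      del_iv <- ev |> filter(.data$event == "deletion") |> select("start", "end")
      pd <- ev |> filter(.data$event == "partial_deletion")
      if (nrow(pd) > 0) {
        # delete everything up to the start of the last exon
        for (i in seq_len(nrow(pd))) {
          ex <- anc$genes$exons[[which(anc$genes$anc_id == pd$anc_id[i])]]
          gstrand <- anc$genes$strand[anc$genes$anc_id == pd$anc_id[i]]
          # exons 1..(n-1) in transcription order; genomic interval to cut
          if (gstrand == "+") {
            cut <- tibble(start = pd$start[i], end = ex$start[nrow(ex)] - 5L)
          } else {
            cut <- tibble(start = ex$end[1] + 5L, end = pd$end[i])
          }
          del_iv <- bind_rows(del_iv, cut)
        }
      }
      inv <- ev |> filter(.data$event == "inversion") |> select("start", "end")
      tan <- ev |> filter(.data$event == "tandem")
      if (nrow(tan) > 0) {
        for (i in seq_len(nrow(tan))) {
          ins[[length(ins) + 1L]] <- tibble(
            anchor = tan$end[i] + 20L,
            seq = substring(anc$chroms[[chrom]], tan$start[i] + 1L, tan$end[i]),
            kind = "tandem", anc_gene = tan$anc_id[i]
          )
        }
      }
      list(
        snp = tibble(pos = snp_pos - 1L, alt = alt),
        ins = list_rbind(ins) %||% tibble(anchor = integer(), seq = character(),
                                          kind = character(), anc_gene = character()),
        dels_small = list_rbind(dels) %||% tibble(start = integer(), end = integer()),
        del_iv = bind_rows(del_iv) |> as_tibble(),
        inv = inv
      )
    })
    names(per_chr) <- names(anc$chroms)
    per_chr
  })
  names(edits) <- asm_ids

  # materialize each derived assembly: sequence + ancestor->derived map
  derived <- map(asm_ids, function(asm) {
    per_chr <- map(names(anc$chroms), function(chrom) {
      build_derived_chrom(anc$chroms[[chrom]], edits[[asm]][[chrom]])
    })
    names(per_chr) <- names(anc$chroms)
    per_chr
  })
  names(derived) <- asm_ids

  # annotations + files
  fasta <- setNames(file.path(outdir, paste0(asm_ids, ".fna")), asm_ids)
  gff <- setNames(file.path(outdir, paste0(asm_ids, ".gff3")), asm_ids)
  members <- list()
  for (asm in asm_ids) {
    seqs <- Biostrings::DNAStringSet(map_chr(derived[[asm]], "seq"))
    names(seqs) <- names(anc$chroms)
    Biostrings::writeXStringSet(seqs, fasta[[asm]], width = 60L)
    ann <- annotate_assembly(asm, anc, events, derived[[asm]], iso2)
    members[[asm]] <- ann$members
    write_gff3(ann$records, gff[[asm]])
  }
  members <- list_rbind(members)

  # pairwise PAF from the edit history
  paf <- character(); aln_rows <- list()
  for (i in seq_along(asm_ids)) {
    for (j in seq_along(asm_ids)) {
      if (j <= i) next
      a <- asm_ids[i]; b <- asm_ids[j]
      recs <- compose_pair_paf(anc, events, derived, edits, target = a, query = b)
      path <- file.path(outdir, sprintf("%s__%s.paf", a, b))
      write_paf(recs, path)
      paf[sprintf("%s__%s", a, b)] <- path
      aln_rows[[length(aln_rows) + 1L]] <- recs |>
        mutate(target_assembly = a, query_assembly = b, source = "simulated")
    }
  }
  alignments <- list_rbind(aln_rows) |> mutate(aln_id = dplyr::row_number())

  truth <- build_truth(cfg, anc, events, members, asm_ids)
  # planted coordinates of hidden genes in their (unannotated) assembly
  hid_ev <- events |> filter(.data$event == "hidden")
  truth$hidden_coords <- map(seq_len(nrow(hid_ev)), function(i) {
    g <- anc$genes[anc$genes$anc_id == hid_ev$anc_id[i], ]
    m <- derived[[hid_ev$assembly[i]]][[g$chrom]]$anc2der
    ex <- g$exons[[1]]
    tibble(
      anc_id = g$anc_id, assembly = hid_ev$assembly[i], chrom = g$chrom,
      start = m[g$start + 1L], end = m[(g$end - 1L) + 1L] + 1L,
      strand = g$strand,
      exons = list(tibble(start = m[ex$start + 1L],
                          end = m[(ex$end - 1L) + 1L] + 1L))
    )
  }) |> list_rbind()
  jsonlite::write_json(
    truth[c("events", "expected_occupancy", "inverted_genes", "hidden", "deleted")],
    file.path(outdir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(members, file.path(outdir, "truth_members.tsv"), progress = FALSE)

  list(
    config = cfg, dir = outdir, assemblies = asm_ids,
    fasta = fasta, gff = gff, paf = paf,
    alignments = alignments, truth = truth
  )
}

# apply one assembly's edits to one ancestor chromosome
build_derived_chrom <- function(anc_seq, ed) {
  L <- nchar(anc_seq)
  chars <- strsplit(anc_seq, "")[[1]]
  if (nrow(ed$snp) > 0) chars[ed$snp$pos + 1L] <- ed$snp$alt

  keep <- rep(TRUE, L)
  for (iv in list(ed$del_iv, ed$dels_small)) {
    for (i in seq_len(nrow(iv))) keep[(iv$start[i] + 1):iv$end[i]] <- FALSE
  }

  # derived order of ancestor positions (inversions reverse-complement)
  bnd <- sort(unique(c(0L, L, ed$inv$start, ed$inv$end)))
  anc_order <- integer(0); inv_flag <- logical(0)
  for (r in seq_len(length(bnd) - 1)) {
    s <- bnd[r]; e <- bnd[r + 1]
    inv_here <- any(ed$inv$start == s & ed$inv$end == e)
    idx <- if (inv_here) rev(s:(e - 1L)) else s:(e - 1L)
    anc_order <- c(anc_order, idx)
    inv_flag <- c(inv_flag, rep(inv_here, e - s))
  }
  ch <- chars[anc_order + 1L]
  ch[inv_flag] <- comp_chars(ch[inv_flag])
  kept <- keep[anc_order + 1L]
  d0_full <- cumsum(kept) - 1L
  anc2der0 <- rep(NA_integer_, L)
  anc2der0[anc_order[kept] + 1L] <- d0_full[kept]
  der0 <- ch[kept]

  ins <- ed$ins
  if (nrow(ins) > 0) {
    ins <- ins |>
      mutate(p = anc2der0[.data$anchor + 1L] + 1L, len = nchar(.data$seq)) |>
      arrange(.data$p, .data$kind)
    if (any(is.na(ins$p))) stop_pg("insertion anchored on a deleted base")
    cumlen <- cumsum(ins$len)
    shift_before <- c(0L, cumlen[-length(cumlen)])
    ins$final_start <- ins$p + shift_before
    # ancestor->derived map including insertion shifts
    fi <- findInterval(anc2der0, ins$p)
    shifts <- rep(0L, length(anc2der0))
    nz <- !is.na(fi) & fi > 0
    shifts[nz] <- cumlen[fi[nz]]
    anc2der <- anc2der0 + shifts
    # splice inserted sequences into the derived string
    pieces <- character(); prev <- 0L
    for (k in seq_len(nrow(ins))) {
      pieces <- c(pieces, paste(der0[seq_len(ins$p[k] - prev) + prev], collapse = ""),
                  ins$seq[k])
      prev <- ins$p[k]
    }
    pieces <- c(pieces, paste(der0[seq_len(length(der0) - prev) + prev], collapse = ""))
    seq <- paste(pieces, collapse = "")
  } else {
    ins <- tibble(anchor = integer(), seq = character(), kind = character(),
                  anc_gene = character(), p = integer(), len = integer(),
                  final_start = integer())
    anc2der <- anc2der0
    seq <- paste(der0, collapse = "")
  }
  list(seq = seq, anc2der = anc2der, keep = keep, chars = chars,
       inv = ed$inv, ins = ins, len = nchar(seq))
}

# derive an assembly's annotation records (for GFF) and truth membership
annotate_assembly <- function(asm, anc, events, der, iso2) {
  ev_here <- events |> filter(.data$assembly == asm)
  records <- list(); members <- list()
  add_rec <- function(gene_id, chrom, start, end, strand, transcripts, anc_id) {
    records[[length(records) + 1L]] <<- tibble(
      gene_id = gene_id, chrom = chrom, start = start, end = end,
      strand = strand, transcripts = list(transcripts)
    )
    members[[length(members) + 1L]] <<- tibble(
      anc_id = anc_id, assembly = asm, gene_id = gene_id
    )
  }
  for (i in seq_len(nrow(anc$genes))) {
    g <- anc$genes[i, ]
    chrom <- g$chrom
    m <- der[[chrom]]$anc2der
    inv_iv <- der[[chrom]]$inv
    in_inv <- nrow(inv_iv) > 0 &&
      any(inv_iv$start <= g$start & g$end <= inv_iv$end)
    status_row <- ev_here |> filter(.data$anc_id == g$anc_id, .data$event != "inversion")
    status <- if (nrow(status_row) > 0) status_row$event[1] else "none"
    if (status %in% c("deletion", "hidden", "partial_deletion")) next

    lift_iv <- function(s, e) {
      if (in_inv) c(m[(e - 1L) + 1L], m[s + 1L] + 1L) else c(m[s + 1L], m[(e - 1L) + 1L] + 1L)
    }
    strand_out <- if (in_inv) flip_strand(g$strand) else g$strand
    giv <- lift_iv(g$start, g$end)
    ex <- g$exons[[1]]
    ex_l <- map(seq_len(nrow(ex)), function(k) lift_iv(ex$start[k], ex$end[k]))
    ex_tbl <- tibble(
      start = map_int(ex_l, 1), end = map_int(ex_l, 2)
    ) |> arrange(.data$start)

    base_id <- paste0(asm, "_", g$anc_id)
    mk_tx <- function(tid, ex_sub) {
      ph <- cds_phases(ex_sub$start, ex_sub$end, strand_out)
      tibble(
        transcript_id = tid,
        exons = list(ex_sub),
        cds = list(ex_sub |> mutate(phase = ph))
      )
    }
    if (status == "split") {
      n <- nrow(ex_tbl)
      k <- max(1L, n %/% 2L) # transcription-order exons in part 1
      if (strand_out == "+") {
        idx1 <- seq_len(k); idx2 <- (k + 1L):n
      } else {
        idx1 <- (n - k + 1L):n; idx2 <- seq_len(n - k)
      }
      parts <- list(p1 = sort(idx1), p2 = sort(idx2))
      # part 2 CDS phase continues from part 1's coding length
      len1 <- sum(ex_tbl$end[parts$p1] - ex_tbl$start[parts$p1])
      for (pn in names(parts)) {
        sub <- ex_tbl[parts[[pn]], , drop = FALSE]
        ph <- cds_phases(sub$start, sub$end, strand_out)
        if (pn == "p2") {
          ph <- (ph + (3L - len1 %% 3L) %% 3L) %% 3L
        }
        tx <- tibble(
          transcript_id = paste0(base_id, "_", pn, ".t1"),
          exons = list(sub), cds = list(sub |> mutate(phase = ph))
        )
        add_rec(paste0(base_id, "_", pn), chrom,
                min(sub$start), max(sub$end), strand_out, tx, g$anc_id)
      }
    } else {
      txs <- mk_tx(paste0(base_id, ".t1"), ex_tbl)
      if (g$anc_id %in% iso2 && nrow(ex_tbl) >= 2) {
        drop_idx <- if (strand_out == "+") 1L else nrow(ex_tbl)
        sub <- ex_tbl[-drop_idx, , drop = FALSE]
        txs <- bind_rows(txs, mk_tx(paste0(base_id, ".t2"), sub))
      }
      add_rec(base_id, chrom, giv[1], giv[2], strand_out, txs, g$anc_id)
      if (status == "tandem") {
        ins <- der[[chrom]]$ins |> filter(.data$kind == "tandem", .data$anc_gene == g$anc_id)
        for (ti in seq_len(nrow(ins))) {
          cstart <- ins$final_start[ti]
          ex_c <- g$exons[[1]] |>
            mutate(start = .data$start - g$start + cstart,
                   end = .data$end - g$start + cstart)
          cid <- paste0(base_id, "_c2")
          tx <- mk_tx(paste0(cid, ".t1"), ex_c)
          add_rec(cid, chrom, cstart, cstart + (g$end - g$start), g$strand, tx, g$anc_id)
        }
      }
    }
  }
  list(records = list_rbind(records), members = list_rbind(members))
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# write hierarchical gene/mRNA/exon/CDS GFF3 (1-based inclusive on disk)
write_gff3 <- function(records, path) {
  lines <- "##gff-version 3"
  records <- records |> arrange(.data$chrom, .data$start, .data$gene_id)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    lines <- c(lines, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      r$chrom, r$start + 1L, r$end, r$strand, r$gene_id
    ))
    txs <- r$transcripts[[1]]
    for (t in seq_len(nrow(txs))) {
      ex <- txs$exons[[t]]; cd <- txs$cds[[t]]
      lines <- c(lines, sprintf(
        "%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        r$chrom, min(ex$start) + 1L, max(ex$end), r$strand,
        txs$transcript_id[t], r$gene_id
      ))
      for (e in seq_len(nrow(ex))) {
        lines <- c(lines, sprintf(
          "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
          r$chrom, ex$start[e] + 1L, ex$end[e], r$strand, txs$transcript_id[t]
        ))
      }
      for (e in seq_len(nrow(cd))) {
        lines <- c(lines, sprintf(
          "%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
          r$chrom, cd$start[e] + 1L, cd$end[e], r$strand, cd$phase[e],
          txs$transcript_id[t]
        ))
      }
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

# compose the exact pairwise alignment (target <- query) from edit history
compose_pair_paf <- function(anc, events, derived, edits, target, query) {
  out <- list()
  for (chrom in names(anc$chroms)) {
    L <- nchar(anc$chroms[[chrom]])
    dt <- derived[[target]][[chrom]]; dq <- derived[[query]][[chrom]]
    inv_t <- dt$inv; inv_q <- dq$inv
    inv_both <- bind_rows(inv_t, inv_q) |> distinct()
    bnd <- sort(unique(c(0L, L, inv_both$start, inv_both$end)))
    for (r in seq_len(length(bnd) - 1)) {
      s <- bnd[r]; e <- bnd[r + 1]
      t_inv <- nrow(inv_t) > 0 && any(inv_t$start == s & inv_t$end == e)
      q_inv <- nrow(inv_q) > 0 && any(inv_q$start == s & inv_q$end == e)
      if (t_inv || q_inv) {
        # protected region: identical in both, pure '=' record, '-' strand
        len <- e - s
        if (t_inv) {
          t_lo <- dt$anc2der[(e - 1L) + 1L]; t_hi <- dt$anc2der[s + 1L] + 1L
        } else {
          t_lo <- dt$anc2der[s + 1L]; t_hi <- dt$anc2der[(e - 1L) + 1L] + 1L
        }
        if (q_inv) {
          q_lo <- dq$anc2der[(e - 1L) + 1L]; q_hi <- dq$anc2der[s + 1L] + 1L
        } else {
          q_lo <- dq$anc2der[s + 1L]; q_hi <- dq$anc2der[(e - 1L) + 1L] + 1L
        }
        out[[length(out) + 1L]] <- tibble(
          qname = chrom, qlen = dq$len, qstart = q_lo, qend = q_hi,
          strand = "-", tname = chrom, tlen = dt$len,
          tstart = t_lo, tend = t_hi, nmatch = len, alen = len,
          mapq = 255L, cigar = paste0(len, "="), source = "simulated"
        )
      } else {
        rec <- compose_region(chrom, s, e, dt, dq)
        if (!is.null(rec)) out[[length(out) + 1L]] <- rec
      }
    }
    # extra records for tandem copies (copy aligned to the partner's locus)
    for (asml in c(target, query)) {
      d_this <- derived[[asml]][[chrom]]
      tn <- d_this$ins |> filter(.data$kind == "tandem")
      for (ti in seq_len(nrow(tn))) {
        g <- anc$genes[anc$genes$anc_id == tn$anc_gene[ti], ]
        glen <- g$end - g$start
        other <- if (asml == target) query else target
        d_other <- derived[[other]][[chrom]]
        o_lo <- d_other$anc2der[g$start + 1L]
        if (asml == target) {
          out[[length(out) + 1L]] <- tibble(
            qname = chrom, qlen = dq$len, qstart = o_lo, qend = o_lo + glen,
            strand = "+", tname = chrom, tlen = dt$len,
            tstart = tn$final_start[ti], tend = tn$final_start[ti] + glen,
            nmatch = glen, alen = glen, mapq = 255L,
            cigar = paste0(glen, "="), source = "simulated"
          )
        } else {
          out[[length(out) + 1L]] <- tibble(
            qname = chrom, qlen = dq$len,
            qstart = tn$final_start[ti], qend = tn$final_start[ti] + glen,
            strand = "+", tname = chrom, tlen = dt$len,
            tstart = o_lo, tend = o_lo + glen,
            nmatch = glen, alen = glen, mapq = 255L,
            cigar = paste0(glen, "="), source = "simulated"
          )
        }
      }
    }
  }
  list_rbind(out) |> arrange(.data$tname, .data$tstart) |>
    mutate(aln_id = dplyr::row_number())
}

# one '+' region: per-base walk between two derived assemblies
compose_region <- function(chrom, s, e, dt, dq) {
  idx <- s:(e - 1L)
  kt <- dt$keep[idx + 1L]; kq <- dq$keep[idx + 1L]
  cht <- dt$chars[idx + 1L]; chq <- dq$chars[idx + 1L]
  op <- rep(NA_character_, length(idx))
  both <- kt & kq
  op[both] <- ifelse(cht[both] == chq[both], "=", "X")
  op[kt & !kq] <- "D"
  op[!kt & kq] <- "I"
  rows <- tibble(
    key = as.numeric(idx), op = op, len = 1L,
    tcoord = ifelse(kt, dt$anc2der[idx + 1L], NA_integer_),
    qcoord = ifelse(kq, dq$anc2der[idx + 1L], NA_integer_)
  ) |> filter(!is.na(.data$op))
  ins_rows <- function(d, opchar, off) {
    sel <- d$ins |> filter(.data$anchor >= s, .data$anchor < e)
    if (nrow(sel) == 0) return(NULL)
    tibble(
      key = sel$anchor + off, op = opchar, len = sel$len,
      tcoord = if (opchar == "D") sel$final_start else NA_integer_,
      qcoord = if (opchar == "I") sel$final_start else NA_integer_
    )
  }
  rows <- bind_rows(rows, ins_rows(dt, "D", 0.4), ins_rows(dq, "I", 0.6)) |>
    arrange(.data$key)
  if (nrow(rows) == 0) return(NULL)
  # trim leading/trailing indel ops
  first_mx <- which(rows$op %in% c("=", "X"))
  if (length(first_mx) == 0) return(NULL)
  rows <- rows[first_mx[1]:first_mx[length(first_mx)], , drop = FALSE]
  t_rows <- rows |> filter(.data$op %in% c("=", "X", "D"))
  q_rows <- rows |> filter(.data$op %in% c("=", "X", "I"))
  t_lo <- t_rows$tcoord[1]; q_lo <- q_rows$qcoord[1]
  t_hi <- t_lo + sum(t_rows$len); q_hi <- q_lo + sum(q_rows$len)
  cigar <- {
    grp <- cumsum(c(TRUE, rows$op[-1] != rows$op[-nrow(rows)]))
    agg <- rows |> mutate(grp = grp) |> group_by(grp) |>
      summarise(len = sum(.data$len), op = dplyr::first(.data$op), .groups = "drop")
    paste0(agg$len, agg$op, collapse = "")
  }
  tibble(
    qname = chrom, qlen = dq$len, qstart = q_lo, qend = q_hi,
    strand = "+", tname = chrom, tlen = dt$len, tstart = t_lo, tend = t_hi,
    nmatch = sum(rows$len[rows$op == "="]), alen = sum(rows$len),
    mapq = 255L, cigar = cigar, source = "simulated"
  )
}

build_truth <- function(cfg, anc, events, members, asm_ids) {
  n <- length(asm_ids)
  ev_by_gene <- events |>
    filter(.data$event != "inversion") |>
    select(anc_id2 = "anc_id", "event", ev_assembly = "assembly")
  inv_genes <- events |> filter(.data$event == "inversion")
  inv_members <- list()
  for (i in seq_len(nrow(inv_genes))) {
    for (gid in strsplit(inv_genes$anc_id[i], ",")[[1]]) {
      inv_members[[length(inv_members) + 1L]] <- tibble(
        anc_id = gid, assembly = inv_genes$assembly[i],
        gene_id = paste0(inv_genes$assembly[i], "_", gid)
      )
    }
  }
  inv_members <- list_rbind(inv_members) %||%
    tibble(anc_id = character(), assembly = character(), gene_id = character())

  genes <- anc$genes |>
    left_join(ev_by_gene, by = c(anc_id = "anc_id2")) |>
    mutate(event = coalesce(.data$event, "none")) |>
    select("anc_id", "chrom", "start", "end", "strand", "cds_len", "n_ex",
           "event", "ev_assembly")
  expected_occupancy <- genes |>
    mutate(expected_occupancy = ifelse(
      .data$event %in% c("deletion", "hidden", "partial_deletion"), n - 1L, n
    )) |>
    select("anc_id", "event", "expected_occupancy")
  list(
    genes = genes,
    members = members,
    events = events,
    expected_occupancy = expected_occupancy,
    inverted_genes = inv_members,
    split_clusters = genes$anc_id[genes$event == "split"],
    tandem_clusters = genes$anc_id[genes$event == "tandem"],
    hidden = genes |> filter(.data$event == "hidden") |>
      transmute(.data$anc_id, assembly = .data$ev_assembly),
    deleted = genes |> filter(.data$event %in% c("deletion", "partial_deletion")) |>
      transmute(.data$anc_id, assembly = .data$ev_assembly, .data$event)
  )
}
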