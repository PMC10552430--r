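# Consensus isoform selection, the built-in spliced aligner, cluster
# checking and patch GFF emission.

cds_rec <- function(id, len, seq = NULL) {
  tibble::tibble(
    seq_id = id, kind = "cds", gene_id = sub(":.*", "", id),
    transcript_id = id, assembly = "A", chrom = "chr1",
    start = 0L, end = len, strand = "+", length = len,
    sequence = seq %||% strrep("A", len),
    internal_stop = FALSE, len_not_multiple3 = FALSE
  )
}

test_that("consensus selection keys on the mode length with tie to longest", {
  recs <- dplyr::bind_rows(
    cds_rec("x1", 300L), cds_rec("x2", 300L), cds_rec("x3", 300L),
    cds_rec("x4", 150L)
  )
  cs <- consensus_isoforms(recs, outlier_frac = 0.5)
  expect_equal(cs$mode_length, 300L)
  expect_equal(nrow(cs$consensus), 4) # |150-300| = 150 <= 0.5*300
  cs2 <- consensus_isoforms(recs, outlier_frac = 0.4)
  expect_equal(nrow(cs2$outliers), 1) # 150 now outside 0.4*300

  same <- dplyr::bind_rows(cds_rec("y1", 300L), cds_rec("y2", 300L))
  expect_equal(nrow(consensus_isoforms(same)$outliers), 0)

  tie <- dplyr::bind_rows(cds_rec("z1", 300L), cds_rec("z2", 300L),
                          cds_rec("z3", 600L), cds_rec("z4", 600L))
  expect_equal(consensus_isoforms(tie)$mode_length, 600L)

  expect_error(consensus_isoforms(cds_rec("w", 10L)[0, ]), "no coding evidence")
})

# plant a 3-exon CDS in a segment with GT..AG introns
plant_query <- function(exon_lens = c(120L, 90L, 120L), intron_lens = c(80L, 70L)) {
  total <- sum(exon_lens)
  total <- total + (3L - total %% 3L) %% 3L
  exon_lens[1] <- exon_lens[1] + (total - sum(exon_lens))
  ncod <- total / 3
  codons <- replicate(ncod - 2, {
    repeat {
      c3 <- random_dna(3)
      if (!c3 %in% c("TAA", "TAG", "TGA")) break
    }
    c3
  })
  orf <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  exons <- substring(orf, cumsum(c(0, exon_lens[-3])) + 1, cumsum(exon_lens))
  introns <- vapply(intron_lens, function(l) paste0("GT", random_dna(l - 4), "AG"), "")
  seg <- paste0(random_dna(300), exons[1], introns[1], exons[2], introns[2],
                exons[3], random_dna(300))
  exon_starts <- c(300L,
                   300L + exon_lens[1] + intron_lens[1],
                   300L + exon_lens[1] + intron_lens[1] + exon_lens[2] + intron_lens[2])
  list(query = orf, segment = seg,
       exon_blocks = tibble::tibble(start = exon_starts,
                                    end = exon_starts + exon_lens))
}

test_that("a planted multi-exon query aligns perfectly with exact exons", {
  withr::local_seed(31)
  pl <- plant_query()
  aln <- spliced_align(pl$query, pl$segment, "+")
  expect_equal(nrow(aln$exon_blocks), 3)
  expect_equal(aln$exon_blocks, pl$exon_blocks)
  expect_equal(aln$mismatches, 0L)
  expect_equal(aln$insertions_bp + aln$deletions_bp, 0L)
  expect_equal(aln$query_coverage, 1)
  expect_equal(aln$matches, nchar(pl$query))
  expect_equal(aln$spliced_seq, pl$query)
})

test_that("a query on the reverse strand is recovered through the hint", {
  withr::local_seed(32)
  pl <- plant_query()
  seg_rc <- revcomp_str(pl$segment)
  aln <- spliced_align(pl$query, seg_rc, "-")
  expect_equal(aln$strand, "-")
  expect_equal(aln$mismatches, 0L)
  expect_equal(aln$query_coverage, 1)
  # exon blocks reported in forward-segment coordinates, ascending
  slen <- nchar(seg_rc)
  want <- tibble::tibble(
    start = slen - rev(pl$exon_blocks$end),
    end = slen - rev(pl$exon_blocks$start)
  )
  expect_equal(aln$exon_blocks, want)
})

test_that("absent queries and substitutions behave as contracted", {
  withr::local_seed(33)
  pl <- plant_query()
  expect_null(spliced_align(random_dna(200), random_dna(2000), "+"))
  # one substituted base in the middle exon
  qv <- strsplit(pl$query, "")[[1]]
  pos <- 160L
  qv[pos] <- setdiff(c("A", "C", "G", "T"), qv[pos])[1]
  q2 <- paste(qv, collapse = "")
  aln <- spliced_align(q2, pl$segment, "+")
  expect_equal(aln$matches, nchar(q2) - 1L)
  expect_equal(aln$mismatches, 1L)
})

test_that("orf classification agrees with a direct translation oracle", {
  withr::local_seed(34)
  for (i in 1:20) {
    pl <- plant_query(exon_lens = c(90L + 3L * i, 90L, 99L))
    aln <- spliced_align(pl$query, pl$segment, "+")
    status <- pangenes:::orf_status(aln$spliced_seq, aln$query_coverage)
    # oracle: translate the spliced sequence directly
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(aln$spliced_seq)))
    ok <- nchar(aln$spliced_seq) %% 3 == 0 &&
      startsWith(aln$spliced_seq, "ATG") &&
      endsWith(pep, "*") &&
      !grepl("\\*", substr(pep, 1, nchar(pep) - 1))
    expect_equal(status == "intact", ok)
    expect_equal(status, "intact") # planted ORFs are intact by construction
  }
})

test_that("premature stops and frame breaks are classified", {
  withr::local_seed(35)
  pl <- plant_query()
  # knock a stop codon into the middle of the query and the segment copy
  q <- pl$query
  substr(q, 61, 63) <- "TAA"
  seg <- pl$segment
  substr(seg, 361, 363) <- "TAA"
  aln <- spliced_align(q, seg, "+")
  expect_equal(pangenes:::orf_status(aln$spliced_seq, aln$query_coverage),
               "premature_stop")
  expect_equal(pangenes:::orf_status("ATGGCTTA", 1), "not_multiple_of_3")
  expect_equal(pangenes:::orf_status("", 0), "no_alignment")
  expect_equal(pangenes:::orf_status("ATGGCTTAA", 0.5), "partial")
})

test_that("patch GFF blocks are hierarchical, sorted and only for confirmations", {
  res <- tibble::tibble(
    cluster_id = "clX", target_assembly = "B", chrom = "chr1",
    seg_start = 100L, seg_end = 700L, strand = "+",
    matches = 300L, mismatches = 0L, insertions_bp = 0L, deletions_bp = 0L,
    query_coverage = 1, orf_status = "intact",
    verdict = "missing_gene_confirmed", source_seq_id = "gA:t1:A",
    exon_blocks = list(tibble::tibble(start = c(100L, 300L, 500L),
                                      end = c(200L, 400L, 620L)))
  )
  p <- withr::local_tempfile()
  emit_patch_gff(res, p)
  lines <- readLines(p)
  types <- vapply(strsplit(lines[-1], "\t"), `[`, "", 3)
  expect_equal(sum(types == "gene"), 1)
  expect_equal(sum(types == "mRNA"), 1)
  expect_equal(sum(types == "exon"), 3)
  expect_equal(sum(types == "CDS"), 3)
  # 1-based inclusive conversion of the first exon
  exon1 <- strsplit(lines[-1][types == "exon"][1], "\t")[[1]]
  expect_equal(as.integer(exon1[4:5]), c(101L, 200L))

  # '-' strand: ascending coordinates, strand column '-'
  res_m <- res; res_m$strand <- "-"
  emit_patch_gff(res_m, p)
  lines_m <- readLines(p)
  ex <- lines_m[vapply(strsplit(lines_m, "\t"), function(x) length(x) >= 3 && x[3] == "exon", TRUE)]
  starts <- as.integer(vapply(strsplit(ex, "\t"), `[`, "", 4))
  expect_equal(starts, sort(starts))
  expect_true(all(vapply(strsplit(ex, "\t"), `[`, "", 7) == "-"))

  # rejected results produce no records
  res_r <- res; res_r$verdict <- "rejected"
  emit_patch_gff(res_r, p)
  expect_equal(readLines(p), "##gff-version 3")
})
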