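# Gene projection through mapped segments and collinear pair calling.

mk_aln <- function(cigar, qs, qe, ts, te, strand = "+") {
  a <- random_alignment()
  a$cigar <- cigar; a$qstart <- qs; a$qend <- qe
  a$tstart <- ts; a$tend <- te; a$strand <- strand
  a$qlen <- qe + 50L; a$tlen <- te + 50L
  a$qname <- "chr1"; a$tname <- "chr1"
  a
}

test_that("identity alignment projects a gene unchanged", {
  segs <- cigar_to_segments(mk_aln("10000M", 0L, 10000L, 0L, 10000L))
  g <- gene_table("g1")[1, ]
  g$start <- 100L; g$end <- 600L
  pr <- project_genes(g, segs)
  expect_equal(c(pr$start, pr$end), c(100, 600))
  expect_equal(pr$coverage, 1)
  expect_equal(pr$strand, "+")
  expect_false(pr$inverted)
})

test_that("target gaps split coverage but keep the projected span", {
  segs <- cigar_to_segments(mk_aln("40M10D60M", 0L, 100L, 0L, 110L))
  g <- gene_table("g1")[1, ]
  g$start <- 30L; g$end <- 50L
  pr <- project_genes(g, segs, min_coverage = 0.5)
  expect_equal(c(pr$start, pr$end), c(30, 60))
  expect_equal(pr$covered_bp, 20L)
  expect_equal(pr$coverage, 1)
})

test_that("reverse-strand projection flips strand and matches the oracle", {
  a <- mk_aln("200M", 0L, 200L, 0L, 200L, strand = "-")
  segs <- cigar_to_segments(a)
  g <- gene_table("g1")[1, ]
  g$start <- 20L; g$end <- 80L; g$strand <- "+"
  pr <- project_genes(g, segs)
  expect_equal(pr$strand, "-")
  expect_true(pr$inverted)
  expect_equal(pr$coverage, 1)
  om <- oracle_base_map(a$qstart, a$qend, a$tstart, a$strand, a$cigar)
  t_of_gene <- om$t[om$q >= 20 & om$q < 80]
  expect_equal(c(pr$start, pr$end), c(min(t_of_gene), max(t_of_gene) + 1))
})

test_that("coverage below threshold yields no projection", {
  segs <- cigar_to_segments(mk_aln("100M", 0L, 100L, 0L, 100L))
  g <- gene_table("g1")[1, ]
  g$start <- 80L; g$end <- 380L # only 20 of 300 bp covered
  expect_equal(nrow(project_genes(g, segs, min_coverage = 0.5)), 0)
})

test_that("the either-fraction rule with strandedness matches spec cases", {
  targets <- tibble::tibble(
    gene_id = "a1", chrom = "chr1", start = 0L, end = 1000L, strand = "+",
    has_transcript = TRUE, rank = 0L
  )
  proj <- tibble::tibble(
    gene_id = "b1", source_assembly = "B", target_assembly = "A",
    aln_id = 1L, chrom = "chr1", start = 500L, end = 2167L, strand = "+",
    covered_bp = 1667L, coverage = 1, gene_len = 1667L, gene_strand = "+",
    inverted = FALSE, ambiguous = FALSE
  )
  # overlap 500 = 50% of a, 30% of b -> pair
  pairs <- call_collinear_pairs(proj, targets, "A")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$overlap_bp, 500L)
  # opposite strand, same geometry -> no pair
  proj2 <- proj; proj2$strand <- "-"
  expect_equal(nrow(call_collinear_pairs(proj2, targets, "A")), 0)
  # overlap exactly half the smaller feature -> emitted (>= semantics)
  proj3 <- proj
  proj3$start <- 900L; proj3$end <- 1100L # len 200, overlap 100 = 0.5*200
  proj3$gene_len <- 200L; proj3$covered_bp <- 200L
  expect_equal(nrow(call_collinear_pairs(proj3, targets, "A")), 1)
})

test_that("one long projected gene can pair with two consecutive targets", {
  targets <- tibble::tibble(
    gene_id = c("a1", "a2"), chrom = "chr1",
    start = c(0L, 600L), end = c(500L, 1100L), strand = "+",
    has_transcript = TRUE, rank = 0:1
  )
  proj <- tibble::tibble(
    gene_id = "b1", source_assembly = "B", target_assembly = "A",
    aln_id = 1L, chrom = "chr1", start = 0L, end = 1100L, strand = "+",
    covered_bp = 1100L, coverage = 1, gene_len = 1100L, gene_strand = "+",
    inverted = FALSE, ambiguous = FALSE
  )
  pairs <- call_collinear_pairs(proj, targets, "A")
  expect_equal(sort(pairs$gene_id_A), c("a1", "a2"))
})

test_that("pair calling equals the brute-force scanner on random fixtures", {
  withr::local_seed(99)
  for (rep in 1:10) {
    n <- sample(20:80, 1); m <- sample(20:80, 1)
    targets <- tibble::tibble(
      gene_id = sprintf("a%03d", 1:n), chrom = "chr1",
      start = sort(sample(0:20000, n)), strand = sample(c("+", "-"), n, TRUE),
      has_transcript = TRUE, rank = 0:(n - 1)
    ) |> dplyr::mutate(end = start + sample(50:800, n, TRUE))
    proj <- tibble::tibble(
      gene_id = sprintf("b%03d", 1:m), source_assembly = "B",
      target_assembly = "A", aln_id = 1L, chrom = "chr1",
      start = sort(sample(0:20000, m)), strand = sample(c("+", "-"), m, TRUE),
      coverage = 1, gene_strand = "+", inverted = FALSE, ambiguous = FALSE
    ) |> dplyr::mutate(end = start + sample(50:800, m, TRUE),
                       gene_len = end - start, covered_bp = end - start)
    got <- call_collinear_pairs(proj, targets, "A") |>
      dplyr::select(gene_id_A, gene_id_B, overlap_bp) |>
      as.data.frame()
    want <- oracle_collinear(proj, targets)
    rownames(got) <- rownames(want) <- NULL
    want$overlap_bp <- as.integer(want$overlap_bp)
    expect_equal(got, want)
  }
})

test_that("unpaired projections become gene-gdna matches, paired ones do not", {
  targets <- tibble::tibble(
    gene_id = "a1", chrom = "chr1", start = 0L, end = 1000L, strand = "+",
    has_transcript = TRUE, rank = 0L
  )
  proj <- tibble::tibble(
    gene_id = c("b1", "b2"), source_assembly = "B", target_assembly = "A",
    aln_id = 1L, chrom = "chr1", start = c(100L, 5000L), end = c(900L, 5800L),
    strand = "+", covered_bp = 800L, coverage = 1, gene_len = 800L,
    gene_strand = "+", inverted = FALSE, ambiguous = FALSE
  )
  pairs <- call_collinear_pairs(proj, targets, "A")
  gd <- call_gdna_matches(proj, pairs, "A")
  expect_equal(gd$gene_id_A, "b2") # b1 paired with a1, suppressed
  expect_equal(gd$gene_id_B, "segment:chr1:5000-5800")
  expect_equal(gd$pair_type, "gene-gdna")
  # below-coverage projections never reach this stage by contract
  proj_low <- proj[2, ]; proj_low$coverage <- 0.3
  gd2 <- call_gdna_matches(proj_low |> dplyr::filter(coverage >= 0.5), pairs, "A")
  expect_equal(nrow(gd2), 0)
})

test_that("homologous-chromosome restriction keys on the regex match", {
  a <- dplyr::bind_rows(
    mk_aln("100M", 0L, 100L, 0L, 100L),
    mk_aln("100M", 0L, 100L, 0L, 100L),
    mk_aln("100M", 0L, 100L, 0L, 100L)
  )
  a$qname <- c("chr1H", "chr1H", "chrUn")
  a$tname <- c("chr1H", "chr2H", "chr1H")
  kept <- restrict_homologous(a, "^chr\\d+H")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$qname, "chr1H")
  expect_warning(restrict_homologous(a, "^scaffold\\d+"), "matched no")
})

test_that("reciprocal evidence is symmetric on identity-like alignments", {
  dir <- withr::local_tempdir()
  sim <- simulate_pangenome(sim_config(
    seed = 3, n_assemblies = 2, n_genes = 8, snp_rate = 0, indel_rate = 0,
    n_deletions = 0, n_inversions = 0, n_split_annotations = 0,
    n_hidden_genes = 0, n_tandem_duplications = 0, p_second_isoform = 0
  ), dir)
  asms <- lapply(1:2, function(i) load_assembly(sim$fasta[i], sim$gff[i], sim$assemblies[i]))
  res <- run_pipeline(asms, sim$alignments, file.path(dir, "out"), seed = 3)
  gg <- res$pairs |> dplyr::filter(pair_type == "gene-gene")
  key_fwd <- paste(gg$gene_id_A, gg$gene_id_B)
  key_rev <- paste(gg$gene_id_B, gg$gene_id_A)
  expect_setequal(key_fwd, key_rev)
})
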