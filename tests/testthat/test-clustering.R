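# Greedy clustering under the neighbor-distance constraint, cluster naming,
# sequence attachment and structural flags.

test_that("a single collinear pair forms one cluster of occupancy 2", {
  asms <- list(
    fake_assembly("A", gene_table("a1")),
    fake_assembly("B", gene_table("b1"))
  )
  ps <- greedy_cluster(pair_row("a1", "A", "b1", "B"), asms)
  expect_equal(length(unique(ps$clusters$cluster)), 1)
  occ <- pangenes:::cluster_occupancy(ps)
  expect_equal(occ$occupancy, 2L)
})

test_that("the neighbor-distance constraint excludes distant same-assembly genes", {
  # sp2 genes b0..b8; candidate b7 is 7 ranks from b0 (6 intervening)
  sp1 <- fake_assembly("sp1", gene_table("a1"))
  sp2 <- fake_assembly("sp2", gene_table(sprintf("b%d", 0:8)))
  pairs <- dplyr::bind_rows(
    pair_row("a1", "sp1", "b0", "sp2", overlap = 900L),
    pair_row("a1", "sp1", "b7", "sp2", overlap = 100L)
  )
  ps5 <- greedy_cluster(pairs, list(sp1, sp2), max_neighbors = 5L)
  cl5 <- ps5$clusters |> dplyr::filter(type == "gene")
  grp <- function(ps, m) ps$clusters$cluster[ps$clusters$member == m]
  expect_false(grp(ps5, "b7") == grp(ps5, "b0")) # excluded at N=5
  expect_true(grp(ps5, "a1") == grp(ps5, "b0"))

  ps7 <- greedy_cluster(pairs, list(sp1, sp2), max_neighbors = 7L)
  expect_true(grp(ps7, "b7") == grp(ps7, "b0")) # included at N=7
})

test_that("adjacent tandem copies join the same cluster", {
  A <- fake_assembly("A", gene_table(c("a1", "a2")))
  B <- fake_assembly("B", gene_table("b1"))
  pairs <- dplyr::bind_rows(
    pair_row("a1", "A", "b1", "B", overlap = 500L),
    pair_row("a2", "A", "b1", "B", overlap = 400L)
  )
  ps <- greedy_cluster(pairs, list(A, B))
  expect_equal(length(unique(ps$clusters$cluster)), 1)
})

test_that("cross-chromosome same-assembly merges are refused", {
  A <- fake_assembly("A", dplyr::bind_rows(
    gene_table("a1", chrom = "chr1"),
    gene_table("a2", chrom = "chr2")
  ))
  B <- fake_assembly("B", gene_table("b1"))
  pairs <- dplyr::bind_rows(
    pair_row("a1", "A", "b1", "B", overlap = 900L),
    pair_row("a2", "A", "b1", "B", overlap = 100L)
  )
  ps <- greedy_cluster(pairs, list(A, B))
  cl <- ps$clusters
  expect_false(
    cl$cluster[cl$member == "a1"] == cl$cluster[cl$member == "a2"]
  )
  # a2 seeds its own cluster; partition property holds
  expect_equal(nrow(cl |> dplyr::filter(type == "gene")), 3)
  expect_equal(anyDuplicated(paste(cl$assembly, cl$member)), 0)
})

test_that("unknown gene references are a hard error", {
  A <- fake_assembly("A", gene_table("a1"))
  B <- fake_assembly("B", gene_table("b1"))
  expect_error(
    greedy_cluster(pair_row("aX", "A", "b1", "B"), list(A, B)),
    "unknown gene 'aX'"
  )
})

test_that("clustering is invariant to pair input order and constraint-clean", {
  withr::local_seed(21)
  A <- fake_assembly("A", gene_table(sprintf("a%02d", 1:20)))
  B <- fake_assembly("B", gene_table(sprintf("b%02d", 1:20)))
  C <- fake_assembly("C", gene_table(sprintf("c%02d", 1:20)))
  pairs <- dplyr::bind_rows(lapply(1:20, function(i) {
    dplyr::bind_rows(
      pair_row(sprintf("a%02d", i), "A", sprintf("b%02d", i), "B",
               overlap = sample(100:999, 1)),
      pair_row(sprintf("b%02d", i), "B", sprintf("c%02d", i), "C",
               overlap = sample(100:999, 1))
    )
  }))
  ps1 <- greedy_cluster(pairs, list(A, B, C)) |> name_clusters()
  ps2 <- greedy_cluster(pairs[sample(nrow(pairs)), ], list(A, B, C)) |>
    name_clusters()
  norm <- function(ps) {
    ps$clusters |> dplyr::arrange(cluster_id, assembly, member) |>
      dplyr::select(cluster_id, assembly, member)
  }
  expect_equal(norm(ps1), norm(ps2))
  # post-hoc constraint audit over every cluster
  audit <- ps1$clusters |>
    dplyr::filter(type == "gene") |>
    dplyr::group_by(cluster, assembly) |>
    dplyr::summarise(
      ok = dplyr::n_distinct(chrom) == 1 &
        (dplyr::n() == 1 | max(rank) - min(rank) - 1 <= 5),
      .groups = "drop"
    )
  expect_true(all(audit$ok))
  # every input gene in exactly one cluster
  expect_equal(sum(ps1$clusters$type == "gene"), 60)
})

test_that("cluster naming prefers the reference member and dedupes", {
  A <- fake_assembly("A", gene_table(c("R1", "R2")))
  B <- fake_assembly("B", gene_table(c("zz9", "aa1")))
  pairs <- pair_row("R1", "A", "zz9", "B")
  ps <- greedy_cluster(pairs, list(A, B)) |> name_clusters("A")
  cl <- ps$clusters
  expect_equal(unique(cl$cluster_id[cl$member %in% c("R1", "zz9")]), "R1")
  # cluster without a reference member: lexicographically smallest gene id
  expect_equal(unique(cl$cluster_id[cl$member == "aa1"]), "aa1")

  # forced name collision gets a numeric suffix
  A2 <- fake_assembly("A", gene_table("x1"))
  B2 <- fake_assembly("B", gene_table(c("x1", "other"), chrom = "chr2"))
  ps2 <- greedy_cluster(pair_row("x1", "A", "other", "B"), list(A2, B2)) |>
    name_clusters("A")
  ids <- sort(unique(ps2$clusters$cluster_id))
  expect_equal(ids, c("x1", "x1_2"))
})

test_that("all isoforms are attached and written to cluster FASTA files", {
  seq <- random_dna(4000)
  orf1 <- paste0("ATG", strrep("GCA", 60), "TAA")  # 186 bp
  seq <- paste0(substr(seq, 1, 500), orf1, substr(seq, 687, 4000))
  mk <- function(id) {
    toy_assembly(seq, list(
      list(gene_id = paste0(id, "_g1"), start = 500L, end = 686L, strand = "+",
           exons = list(c(500L, 686L)))
    ), assembly_id = id)
  }
  A <- mk("A"); B <- mk("B")
  # add a second transcript to A's gene by rewriting its tibbles
  A$transcripts <- dplyr::bind_rows(
    A$transcripts, tibble::tibble(transcript_id = "A_g1.t2", gene_id = "A_g1")
  )
  A$exons <- dplyr::bind_rows(
    A$exons, tibble::tibble(transcript_id = "A_g1.t2", start = 500L, end = 650L)
  )
  A$cds <- dplyr::bind_rows(
    A$cds, tibble::tibble(transcript_id = "A_g1.t2", start = 500L, end = 650L,
                          phase = 0L)
  )
  recs <- dplyr::bind_rows(cut_sequences(A), cut_sequences(B))
  ps <- greedy_cluster(pair_row("A_g1", "A", "B_g1", "B"), list(A, B)) |>
    name_clusters() |>
    attach_sequences(recs, list(A, B))
  cdna <- ps$sequences |> dplyr::filter(kind == "cdna")
  expect_equal(nrow(cdna), 3) # two isoforms in A + one in B
  out <- withr::local_tempdir()
  files <- write_cluster_fastas(ps, out)
  fa <- Biostrings::readDNAStringSet(
    file.path(out, paste0(ps$clusters$cluster_id[1], ".cdna.fna"))
  )
  expect_equal(length(fa), 3)
})

test_that("split and tandem structure is flagged against the mode model", {
  # three assemblies: B carries two adjacent half-length models (split),
  # C carries two full-length copies (tandem)
  len_full <- 300L
  mkrec <- function(asm, gene, cdslen) {
    tibble::tibble(
      seq_id = paste0(gene, ":t1:", asm), kind = "cds", gene_id = gene,
      transcript_id = paste0(gene, ".t1"), assembly = asm, chrom = "chr1",
      start = 0L, end = cdslen, strand = "+", length = cdslen,
      sequence = strrep("A", cdslen), internal_stop = FALSE,
      len_not_multiple3 = FALSE
    )
  }
  A <- fake_assembly("A", gene_table("a1"))
  B <- fake_assembly("B", gene_table(c("b1a", "b1b")))
  C <- fake_assembly("C", gene_table(c("c1", "c2")))
  pairs <- dplyr::bind_rows(
    pair_row("a1", "A", "b1a", "B", overlap = 500L),
    pair_row("a1", "A", "b1b", "B", overlap = 400L),
    pair_row("a1", "A", "c1", "C", overlap = 600L),
    pair_row("a1", "A", "c2", "C", overlap = 300L)
  )
  recs <- dplyr::bind_rows(
    mkrec("A", "a1", len_full),
    mkrec("B", "b1a", 150L), mkrec("B", "b1b", 150L),
    mkrec("C", "c1", len_full), mkrec("C", "c2", len_full)
  )
  ps <- greedy_cluster(pairs, list(A, B, C)) |> name_clusters("A") |>
    attach_sequences(recs)
  flags <- flag_structure(ps)
  f <- flags[flags$cluster_id == "a1", ]
  expect_equal(f$split_count, 1L)  # B's halves sum to the mode length
  expect_equal(f$tandem_count, 1L) # C's two full copies do not
})

test_that("inverted members are flagged from minority strand plus evidence", {
  A <- fake_assembly("A", gene_table("a1"))
  B <- fake_assembly("B", gene_table("b1"))
  C <- fake_assembly("C", gene_table("c1") |> dplyr::mutate(strand = "-"))
  pairs <- dplyr::bind_rows(
    pair_row("a1", "A", "b1", "B", overlap = 500L),
    pair_row("a1", "A", "c1", "C", overlap = 500L, inverted = TRUE) |>
      dplyr::mutate(strand_B = "-")
  )
  recs <- tibble::tibble(
    seq_id = character(), kind = character(), gene_id = character(),
    transcript_id = character(), assembly = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    length = integer(), sequence = character(), internal_stop = logical(),
    len_not_multiple3 = logical()
  )
  ps <- greedy_cluster(pairs, list(A, B, C)) |> name_clusters("A") |>
    attach_sequences(recs)
  flags <- flag_structure(ps)
  expect_equal(flags$inverted_count, 1L)
  expect_equal(flags$inverted_members[[1]], "c1")
})
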