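# Assembly loading, sequence cutting, masking and gDNA extraction.

test_that("load_assembly converts coordinates and assigns ranks", {
  seq <- random_dna(2000)
  asm <- toy_assembly(seq, list(
    list(gene_id = "gB", start = 500L, end = 700L, strand = "+",
         exons = list(c(500L, 700L))),
    list(gene_id = "gA", start = 100L, end = 200L, strand = "+",
         exons = list(c(100L, 200L))),
    list(gene_id = "gC", start = 900L, end = 1100L, strand = "-",
         exons = list(c(900L, 1100L)))
  ))
  expect_equal(asm$genes$gene_id, c("gA", "gB", "gC")) # sorted by start
  expect_equal(asm$genes$rank, 0:2)
  # GFF 1-based 101..200 -> internal (100, 200)
  expect_equal(asm$genes$start[asm$genes$gene_id == "gA"], 100L)
  expect_equal(asm$genes$end[asm$genes$gene_id == "gA"], 200L)
})

test_that("load_assembly reports missing chromosomes and malformed lines", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "a.fna")
  writeLines(c(">chr1", random_dna(300)), fa)
  gff <- file.path(dir, "a.gff3")
  writeLines(c("##gff-version 3",
               "chrZ\tt\tgene\t10\t50\t.\t+\t.\tID=g1"), gff)
  expect_error(load_assembly(fa, gff, "a"), "chrZ")

  gff2 <- file.path(dir, "b.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t10\t50\t.\t+\t.\tID=g1",
               "chr1\tgene\t10\t50"), gff2)
  expect_error(load_assembly(fa, gff2, "a"), "line 3")

  gff3 <- file.path(dir, "c.gff3")
  writeLines("chr1\tt\tgene\t10\t50\t.\t+\t.\tID=g1", gff3)
  expect_error(load_assembly(fa, gff3, "a"), "gff-version")
})

test_that("cut_sequences applies the strict length filter per record kind", {
  # CDS lengths 99..102 on a ladder of single-exon genes
  lens <- 99:102
  seq <- random_dna(3000)
  genes <- lapply(seq_along(lens), function(i) {
    s <- 200L * i
    list(gene_id = sprintf("g%03d", lens[i]), start = s, end = s + lens[i],
         strand = "+", exons = list(c(s, s + lens[i])))
  })
  asm <- toy_assembly(seq, genes)
  recs <- cut_sequences(asm, min_len = 100L)
  kept <- unique(recs$gene_id[recs$kind == "cds"])
  # strict > 100: 99 and 100 excluded, 101 and 102 kept
  expect_setequal(kept, c("g101", "g102"))
  # brute-force filter over the ladder agrees
  expect_identical(sort(kept), sort(sprintf("g%03d", lens[lens > 100])))
  # peptides only for surviving CDS
  expect_setequal(unique(recs$gene_id[recs$kind == "pep"]), kept)
})

test_that("cutting respects strand and translates CDS", {
  orf <- paste0("ATG", strrep("GCT", 32), "TAA") # 102 bp clean ORF
  flank1 <- random_dna(150); flank2 <- random_dna(150)
  seq_plus <- paste0(flank1, orf, flank2)
  seq_minus <- paste0(flank1, revcomp_str(orf), flank2)
  asm_p <- toy_assembly(seq_plus, list(
    list(gene_id = "gp", start = 150L, end = 252L, strand = "+",
         exons = list(c(150L, 252L)))
  ), assembly_id = "plus")
  asm_m <- toy_assembly(seq_minus, list(
    list(gene_id = "gm", start = 150L, end = 252L, strand = "-",
         exons = list(c(150L, 252L)))
  ), assembly_id = "minus")
  rp <- cut_sequences(asm_p); rm_ <- cut_sequences(asm_m)
  expect_equal(rp$sequence[rp$kind == "cds"], orf)
  # '-' strand CDS equals reverse complement of the genomic slice
  expect_equal(rm_$sequence[rm_$kind == "cds"], orf)
  pep <- rp$sequence[rp$kind == "pep"]
  expect_equal(nchar(pep), 102 / 3)
  expect_equal(substr(pep, 1, 2), "MA")
  expect_false(rp$internal_stop[rp$kind == "pep"])
})

test_that("internal stops and frame problems are flagged, not dropped", {
  orf <- paste0("ATG", "TAA", strrep("GCT", 32), "TAA") # internal stop at codon 2
  seq <- paste0(random_dna(120), orf, random_dna(120))
  asm <- toy_assembly(seq, list(
    list(gene_id = "g1", start = 120L, end = 120L + nchar(orf), strand = "+",
         exons = list(c(120L, 120L + nchar(orf))))
  ))
  recs <- cut_sequences(asm)
  pep <- recs[recs$kind == "pep", ]
  expect_true(pep$internal_stop)
  expect_true(grepl("\\*", pep$sequence))
})

test_that("gdna round trip: a '+' single-exon gene equals its cdna", {
  seq <- random_dna(1000)
  asm <- toy_assembly(seq, list(
    list(gene_id = "g1", start = 300L, end = 531L, strand = "+",
         exons = list(c(300L, 531L)))
  ))
  recs <- cut_sequences(asm)
  gd <- cut_gdna(asm, "chr1", 300L, 531L, "+")
  expect_equal(gd$sequence, recs$sequence[recs$kind == "cdna"])
})

test_that("cut_gdna handles strand and bounds", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "a.fna"); writeLines(c(">chr1", "ACGTAACGTA"), fa)
  gff <- file.path(dir, "a.gff3"); writeLines("##gff-version 3", gff)
  asm <- load_assembly(fa, gff, "a")
  expect_equal(cut_gdna(asm, "chr1", 0L, 5L, "+")$sequence, "ACGTA")
  expect_equal(cut_gdna(asm, "chr1", 0L, 5L, "-")$sequence, "TACGT")
  expect_error(cut_gdna(asm, "chr1", 5L, 20L), "out of bounds")
})

test_that("mask_geneless masks only long geneless tracts", {
  # two genes separated by a 1.5 Mb gene-free gap
  gap <- 1500000L
  seq <- paste0(random_dna(300), strrep("A", gap), random_dna(300))
  total <- nchar(seq)
  asm <- toy_assembly(seq, list(
    list(gene_id = "g1", start = 50L, end = 250L, strand = "+",
         exons = list(c(50L, 250L))),
    list(gene_id = "g2", start = 300L + gap + 50L, end = 300L + gap + 250L,
         strand = "+", exons = list(c(300L + gap + 50L, 300L + gap + 250L)))
  ))
  masked <- as.character(mask_geneless(asm)[[1]])
  expect_equal(nchar(masked), total) # length conserved
  mid <- substring(masked, 300 + 1000, 300 + 2000)
  expect_true(grepl("^N+$", mid))
  # gene bases untouched
  expect_equal(substring(masked, 51, 250), substring(seq, 51, 250))
})

test_that("masking thresholds are strict and tiled chromosomes untouched", {
  small_gap <- 900000L
  seq <- paste0(random_dna(200), strrep("C", small_gap), random_dna(200))
  asm <- toy_assembly(seq, list(
    list(gene_id = "g1", start = 10L, end = 150L, strand = "+",
         exons = list(c(10L, 150L))),
    list(gene_id = "g2", start = 200L + small_gap + 10L,
         end = 200L + small_gap + 150L, strand = "+",
         exons = list(c(200L + small_gap + 10L, 200L + small_gap + 150L)))
  ))
  expect_equal(as.character(mask_geneless(asm)[[1]]), seq) # 0.9 Mb untouched

  tiled <- random_dna(500)
  asm2 <- toy_assembly(tiled, list(
    list(gene_id = "g1", start = 0L, end = 500L, strand = "+",
         exons = list(c(0L, 500L)))
  ))
  expect_equal(as.character(mask_geneless(asm2)[[1]]), tiled)
})

test_that("sequence cutting is independent of GFF gene order", {
  seq <- random_dna(2000)
  genes <- list(
    list(gene_id = "gA", start = 100L, end = 301L, strand = "+",
         exons = list(c(100L, 301L))),
    list(gene_id = "gB", start = 500L, end = 704L, strand = "-",
         exons = list(c(500L, 704L)))
  )
  a1 <- toy_assembly(seq, genes, assembly_id = "o1")
  a2 <- toy_assembly(seq, rev(genes), assembly_id = "o2")
  r1 <- cut_sequences(a1) |> dplyr::mutate(seq_id = sub(":o1$", "", seq_id))
  r2 <- cut_sequences(a2) |> dplyr::mutate(seq_id = sub(":o2$", "", seq_id))
  expect_equal(r1 |> dplyr::select(-assembly), r2 |> dplyr::select(-assembly))
})
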