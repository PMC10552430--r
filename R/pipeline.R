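# End-to-end pipeline: cut -> import alignments -> project -> collinear
# pairs -> greedy clusters -> matrices/reports. Deterministic given a seed:
# all outputs are sorted and no stage depends on filesystem iteration
# order.

# swap query/target roles of mapped segments so one alignment can be used
# to project genes in both directions
swap_segments <- function(segments) {
  tibble(
    aln_id = segments$aln_id,
    qname = segments$tname, qstart = segments$tstart, qend = segments$tend,
    tname = segments$qname, tstart = segments$qstart, tend = segments$qend,
    strand = segments$strand
  )
}

# collinear evidence (both directions) for one aligned assembly pair
pair_evidence <- function(alignments, target_asm, query_asm, assemblies,
                          f = 0.5, min_coverage = 0.5,
                          wga_algorithm = "simulated") {
  byid <- setNames(assemblies, map_chr(assemblies, "assembly_id"))
  segs <- cigar_to_segments(alignments)
  proj_q <- project_genes(byid[[query_asm]]$genes, segs, min_coverage,
                          source_assembly = query_asm,
                          target_assembly = target_asm)
  p1 <- call_collinear_pairs(proj_q, byid[[target_asm]]$genes, target_asm,
                             f = f, wga_algorithm = wga_algorithm)
  proj_t <- project_genes(byid[[target_asm]]$genes, swap_segments(segs),
                          min_coverage,
                          source_assembly = target_asm,
                          target_assembly = query_asm)
  p2 <- call_collinear_pairs(proj_t, byid[[query_asm]]$genes, query_asm,
                             f = f, wga_algorithm = wga_algorithm)
  both <- bind_rows(p1, p2)
  g1 <- call_gdna_matches(proj_q, both, target_asm, wga_algorithm)
  g2 <- call_gdna_matches(proj_t, both, query_asm, wga_algorithm)
  bind_rows(both, g1, g2)
}

#' Run the whole pangene pipeline
#'
#' Stages, in order: load assemblies, cut sequences, import PAF alignments
#' (or take them from a simulation), restrict to homologous chromosomes
#' when requested, project genes and call collinear pairs in both
#' directions of every aligned pair, greedily cluster, name clusters,
#' attach sequences, flag structure, and write the collinear TSV, cluster
#' report, pangene matrix, POCS and ANI matrices and growth curves to
#' `outdir`. Rerunning with the same inputs and seed is byte-identical.
#'
#' @param assemblies Either a list of `assembly` objects or a tibble with
#'   columns `assembly_id`, `fasta`, `gff` to load.
#' @param alignments Alignment tibble carrying `query_assembly` and
#'   `target_assembly` columns, or a tibble with columns `target_assembly`,
#'   `query_assembly`, `paf` naming files to parse.
#' @param outdir Output directory.
#' @param f Either-fraction overlap threshold (default 0.5).
#' @param max_neighbors Neighbor-distance constraint (default 5).
#' @param min_len Sequence length filter in bp (default 100).
#' @param min_coverage Projection coverage threshold (default 0.5).
#' @param softcore_frac Soft-core fraction (default 0.95).
#' @param homologous_regex Optional chromosome-pairing regex
#'   ([restrict_homologous()]); `NULL` compares all against all.
#' @param reference_assembly Naming reference; default first assembly.
#' @param seed Seed for the growth-curve permutations.
#' @param n_perm Growth-curve permutations (default 10).
#' @param wga_algorithm Label recorded in the evidence.
#' @return A list: `pangene_set`, `pairs`, `flags`, `matrix`, `pocs`,
#'   `ani`, `growth`, `assemblies` (loaded objects), `files` (paths).
#' @export
run_pipeline <- function(assemblies, alignments, outdir,
                         f = 0.5, max_neighbors = 5L, min_len = 100L,
                         min_coverage = 0.5, softcore_frac = 0.95,
                         homologous_regex = NULL, reference_assembly = NULL,
                         seed = 1L, n_perm = 10L,
                         wga_algorithm = "simulated") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (is.data.frame(assemblies)) {
    for (col in c("assembly_id", "fasta", "gff")) {
      if (!col %in% names(assemblies)) stop_pg("assembly table lacks column '%s'", col)
    }
    missing <- assemblies$fasta[!file.exists(assemblies$fasta)]
    missing <- c(missing, assemblies$gff[!file.exists(assemblies$gff)])
    if (length(missing) > 0) stop_pg("input file not found: %s", missing[1])
    assemblies <- pmap(assemblies, function(assembly_id, fasta, gff, ...) {
      load_assembly(fasta, gff, assembly_id)
    })
  }
  if (length(assemblies) < 2) stop_pg("clustering needs at least 2 assemblies")
  asm_ids <- map_chr(assemblies, "assembly_id")

  if (is.data.frame(alignments) && "paf" %in% names(alignments)) {
    alignments <- pmap(alignments, function(target_assembly, query_assembly, paf, ...) {
      parse_paf(paf, source_algorithm = wga_algorithm) |>
        mutate(target_assembly = target_assembly, query_assembly = query_assembly)
    }) |> list_rbind() |>
      mutate(aln_id = dplyr::row_number())
  }
  if (!is.null(homologous_regex)) {
    alignments <- restrict_homologous(alignments, homologous_regex)
  }

  # collinear evidence per aligned pair
  pair_keys <- alignments |> distinct(.data$target_assembly, .data$query_assembly)
  pairs <- map(seq_len(nrow(pair_keys)), function(i) {
    a <- pair_keys$target_assembly[i]; b <- pair_keys$query_assembly[i]
    alns <- alignments |>
      filter(.data$target_assembly == a, .data$query_assembly == b)
    pair_evidence(alns, a, b, assemblies, f = f, min_coverage = min_coverage,
                  wga_algorithm = wga_algorithm)
  }) |> list_rbind()
  if (is.null(pairs) || nrow(pairs) == 0) pairs <- empty_pairs()
  pairs <- pairs |>
    arrange(.data$pair_type, .data$assembly_A, .data$gene_id_A,
            .data$assembly_B, .data$gene_id_B)
  write_collinear_tsv(pairs, file.path(outdir, "collinear.tsv"))

  records <- map(assemblies, cut_sequences, min_len = min_len) |> list_rbind()

  ps <- greedy_cluster(pairs, assemblies, max_neighbors = max_neighbors) |>
    name_clusters(reference_assembly) |>
    attach_sequences(records, assemblies)
  flags <- flag_structure(ps)

  occ <- cluster_occupancy(ps) |>
    left_join(ps$clusters |> distinct(.data$cluster, .data$cluster_id), by = "cluster") |>
    mutate(class = classify_occupancy(.data$occupancy, length(asm_ids), softcore_frac))
  report <- occ |>
    left_join(flags |> select(-"inverted_members"), by = "cluster_id") |>
    mutate(across(c("split_count", "tandem_count", "inverted_count"),
                  ~ coalesce(.x, 0L))) |>
    select("cluster_id", "occupancy", "class", "split_count", "tandem_count",
           "inverted_count") |>
    arrange(.data$cluster_id)
  readr::write_tsv(report, file.path(outdir, "cluster_report.tsv"), progress = FALSE)

  mat <- build_pangene_matrix(ps)
  write_pangene_matrix(mat, file.path(outdir, "pangene_matrix.tsv"))
  pocs <- pocs_matrix(ps)
  write_matrix_tsv(pocs, file.path(outdir, "pocs_matrix.tsv"))
  ani <- ani_matrix(alignments, asm_ids)
  write_matrix_tsv(ani, file.path(outdir, "ani_matrix.tsv"))
  growth <- growth_curves(ps, n_perm = n_perm, seed = seed,
                          softcore_frac = softcore_frac)
  readr::write_tsv(growth, file.path(outdir, "growth_curves.tsv"), progress = FALSE)

  manifest <- list(
    assemblies = asm_ids,
    parameters = list(
      f = f, max_neighbors = max_neighbors, min_len = min_len,
      min_coverage = min_coverage, softcore_frac = softcore_frac,
      homologous_regex = homologous_regex, seed = seed, n_perm = n_perm,
      wga_algorithm = wga_algorithm
    ),
    n_clusters = length(unique(ps$clusters$cluster)),
    outputs = c("collinear.tsv", "cluster_report.tsv", "pangene_matrix.tsv",
                "pocs_matrix.tsv", "ani_matrix.tsv", "growth_curves.tsv")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(
    pangene_set = ps, pairs = pairs, flags = flags, matrix = mat,
    pocs = pocs, ani = ani, growth = growth, report = report,
    assemblies = assemblies,
    files = file.path(outdir, manifest$outputs)
  )
}

write_matrix_tsv <- function(mat, path) {
  df <- as_tibble(mat, rownames = "assembly")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Tidy a pangene set into one row per cluster member
#'
#' @param x A `pangene_set`.
#' @param ... Unused.
#' @return Tibble with `cluster_id`, `assembly`, `member`, `type`, `chrom`,
#'   `start`, `end`, `strand`, `occupancy`, `class`.
#' @export
tidy.pangene_set <- function(x, ...) {
  occ <- cluster_occupancy(x) |>
    mutate(class = classify_occupancy(.data$occupancy, length(x$assemblies)))
  x$clusters |>
    left_join(occ, by = "cluster") |>
    select(dplyr::any_of(c("cluster_id")), "assembly", "member", "type",
           "chrom", "start", "end", "strand", "occupancy", "class") |>
    as_tibble()
}

#' One-row summary of a pangene set
#'
#' Reports total clusters and occupancy-class counts. `n_softcore_total`
#' is the soft-core count including core clusters, the superset
#' conventionally reported as "(soft) core".
#'
#' @param x A `pangene_set`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.pangene_set <- function(x, ...) {
  occ <- cluster_occupancy(x) |>
    mutate(class = classify_occupancy(.data$occupancy, length(x$assemblies)))
  tibble(
    n_assemblies = length(x$assemblies),
    n_clusters = nrow(occ),
    n_core = sum(occ$class == "core"),
    n_softcore = sum(occ$class == "softcore"),
    n_softcore_total = sum(occ$class %in% c("core", "softcore")),
    n_shell = sum(occ$class == "shell"),
    n_singleton = sum(occ$class == "singleton"),
    n_gene_members = sum(x$clusters$type == "gene"),
    n_gdna_members = sum(x$clusters$type == "segment")
  )
}
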