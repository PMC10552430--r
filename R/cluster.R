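# Greedy clustering of collinear pairs into pangene clusters, cluster
# naming, sequence attachment and structural flags (split/tandem/inverted).

#' Greedily merge collinear pairs into pangene clusters
#'
#' Processes gene-gene pairs in a deterministic order (descending overlap,
#' then lexicographic member keys) and unions the two members' clusters
#' unless the merged cluster would violate the same-assembly neighbor
#' constraint for any assembly: within one assembly all members of a
#' cluster must lie on the same chromosome with at most `max_neighbors`
#' annotated genes between any two of them. When a merge is refused, both
#' clusters simply stay as they are — the incoming gene remains available
#' for other merges. Afterwards, gene-gdna pairs attach their segment to
#' the cluster of the gene member, and every unclustered annotated gene
#' becomes a singleton cluster, so the gene members of the result partition
#' the input gene set.
#'
#' @param pairs Collinear-pair tibble (gene-gene and gene-gdna rows).
#' @param assemblies List of `assembly` objects covering every gene
#'   referenced by the pairs.
#' @param max_neighbors Maximum number of intervening genes between two
#'   same-assembly members of one cluster (default 5).
#' @return A `pangene_set` object: list with `clusters` (tibble of
#'   `cluster`, `assembly`, `member`, `type`, `chrom`, `start`, `end`,
#'   `strand`, `rank`), `assemblies` (ids), `inverted_evidence`,
#'   `max_neighbors`. Clusters are unnamed until [name_clusters()].
#' @export
greedy_cluster <- function(pairs, assemblies, max_neighbors = 5L) {
  catalog <- map(assemblies, function(a) {
    a$genes |> mutate(assembly = a$assembly_id)
  }) |> list_rbind() |>
    mutate(key = paste(.data$assembly, .data$gene_id, sep = "\r"))

  gg <- pairs |> filter(.data$pair_type == "gene-gene") |>
    mutate(
      key_a = paste(.data$assembly_A, .data$gene_id_A, sep = "\r"),
      key_b = paste(.data$assembly_B, .data$gene_id_B, sep = "\r")
    )
  unknown <- setdiff(c(gg$key_a, gg$key_b), catalog$key)
  if (length(unknown) > 0) {
    parts <- strsplit(unknown[1], "\r")[[1]]
    stop_pg("pair references unknown gene '%s' in assembly '%s'", parts[2], parts[1])
  }
  gg <- gg |>
    arrange(dplyr::desc(.data$overlap_bp), .data$key_a, .data$key_b) |>
    distinct(.data$key_a, .data$key_b, .keep_all = TRUE)

  n <- nrow(catalog)
  idx <- setNames(seq_len(n), catalog$key)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # per-root membership summary: assembly -> (chrom, min rank, max rank)
  summ <- map(seq_len(n), function(i) {
    m <- list(list(chrom = catalog$chrom[i], lo = catalog$rank[i], hi = catalog$rank[i]))
    names(m) <- catalog$assembly[i]
    m
  })

  merge_ok <- function(sa, sb) {
    for (asm in intersect(names(sa), names(sb))) {
      a <- sa[[asm]]; b <- sb[[asm]]
      if (a$chrom != b$chrom) return(FALSE)
      if (max(a$hi, b$hi) - min(a$lo, b$lo) - 1L > max_neighbors) return(FALSE)
    }
    TRUE
  }
  combine_summ <- function(sa, sb) {
    for (asm in names(sb)) {
      if (is.null(sa[[asm]])) {
        sa[[asm]] <- sb[[asm]]
      } else {
        sa[[asm]]$lo <- min(sa[[asm]]$lo, sb[[asm]]$lo)
        sa[[asm]]$hi <- max(sa[[asm]]$hi, sb[[asm]]$hi)
      }
    }
    sa
  }

  for (i in seq_len(nrow(gg))) {
    ra <- find(idx[[gg$key_a[i]]])
    rb <- find(idx[[gg$key_b[i]]])
    if (ra == rb) next
    if (merge_ok(summ[[ra]], summ[[rb]])) {
      parent[rb] <- ra
      summ[[ra]] <- combine_summ(summ[[ra]], summ[[rb]])
      summ[rb] <- list(NULL)
    }
  }

  roots <- map_int(seq_len(n), find)
  clusters <- catalog |>
    mutate(cluster = roots, type = "gene", member = .data$gene_id) |>
    select("cluster", "assembly", "member", "type", "chrom", "start", "end",
           "strand", "rank")

  # attach gene-gdna segments to the cluster of their gene member
  gd <- pairs |> filter(.data$pair_type == "gene-gdna")
  if (nrow(gd) > 0) {
    gd <- gd |>
      mutate(key_a = paste(.data$assembly_A, .data$gene_id_A, sep = "\r")) |>
      filter(.data$key_a %in% names(idx)) |>
      mutate(cluster = map_int(.data$key_a, function(k) find(idx[[k]])))
    seg <- gd |>
      transmute(
        cluster = .data$cluster, assembly = .data$assembly_B,
        member = .data$gene_id_B, type = "segment",
        chrom = .data$chrom_B, start = .data$start_B, end = .data$end_B,
        strand = .data$strand_B, rank = NA_integer_
      ) |>
      distinct(.data$cluster, .data$assembly, .data$member, .keep_all = TRUE)
    clusters <- bind_rows(clusters, seg)
  }

  inverted_evidence <- pairs |>
    filter(.data$pair_type == "gene-gene", .data$inverted) |>
    transmute(assembly = .data$assembly_A, gene_id = .data$gene_id_A) |>
    bind_rows(
      pairs |> filter(.data$pair_type == "gene-gene", .data$inverted) |>
        transmute(assembly = .data$assembly_B, gene_id = .data$gene_id_B)
    ) |>
    distinct()

  structure(
    list(
      clusters = clusters |> arrange(.data$cluster, .data$assembly, .data$member),
      assemblies = map_chr(assemblies, "assembly_id"),
      inverted_evidence = inverted_evidence,
      max_neighbors = max_neighbors
    ),
    class = "pangene_set"
  )
}

#' @export
print.pangene_set <- function(x, ...) {
  occ <- cluster_occupancy(x)
  cat(sprintf(
    "<pangene_set> %d clusters over %d assemblies (%d gene members, %d gDNA segments)\n",
    length(unique(x$clusters$cluster)), length(x$assemblies),
    sum(x$clusters$type == "gene"), sum(x$clusters$type == "segment")
  ))
  cat(sprintf("  occupancy: %s\n",
              paste(sprintf("%s=%d", names(table(occ$occupancy)), table(occ$occupancy)),
                    collapse = " ")))
  invisible(x)
}

# occupancy per cluster: number of assemblies with >=1 gene member
cluster_occupancy <- function(ps) {
  ps$clusters |>
    filter(.data$type == "gene") |>
    group_by(.data$cluster) |>
    summarise(occupancy = dplyr::n_distinct(.data$assembly), .groups = "drop") |>
    right_join(ps$clusters |> distinct(.data$cluster), by = "cluster") |>
    mutate(occupancy = coalesce(.data$occupancy, 0L))
}

#' Name pangene clusters
#'
#' Assigns each cluster the gene id of its reference-assembly member with
#' the lowest order rank; clusters without a reference member take the
#' lexicographically smallest member gene id. Duplicated names get a
#' numeric suffix (`_2`, `_3`, ...).
#'
#' @param ps A `pangene_set`.
#' @param reference_assembly Assembly id used for naming, or `NULL` to use
#'   the first assembly of the set.
#' @return The `pangene_set` with a `cluster_id` column on `clusters`.
#' @export
name_clusters <- function(ps, reference_assembly = NULL) {
  stopifnot(inherits(ps, "pangene_set"))
  ref <- reference_assembly %||% ps$assemblies[1]
  genes <- ps$clusters |> filter(.data$type == "gene")
  ids <- genes |>
    group_by(.data$cluster) |>
    summarise(
      cluster_id = {
        refm <- .data$member[.data$assembly == ref]
        refr <- .data$rank[.data$assembly == ref]
        if (length(refm) > 0) refm[order(refr, refm)][1] else sort(.data$member)[1]
      },
      .groups = "drop"
    ) |>
    arrange(.data$cluster_id, .data$cluster) |>
    group_by(.data$cluster_id) |>
    mutate(cluster_id = if (dplyr::n() > 1) {
      c(.data$cluster_id[1], paste0(.data$cluster_id[-1], "_", seq_len(dplyr::n() - 1L) + 1L))
    } else .data$cluster_id) |>
    ungroup()
  ps$clusters <- ps$clusters |>
    left_join(ids |> select("cluster", "cluster_id"), by = "cluster") |>
    mutate(cluster_id = coalesce(.data$cluster_id, paste0("segcluster_", .data$cluster)))
  ps$reference_assembly <- ref
  ps
}

#' Attach isoform sequences (and gDNA slices) to a pangene set
#'
#' Stores the cut sequence records of all member genes on the set and cuts
#' the genomic slices of gDNA segment members, so cluster FASTA files can
#' be written. Members whose sequences were all removed by the length
#' filter are listed in the `missing_sequence` report.
#'
#' @param ps A named `pangene_set`.
#' @param records Sequence-record tibble from [cut_sequences()] (all
#'   assemblies bound together).
#' @param assemblies List of `assembly` objects (needed for gDNA slices);
#'   optional when the set has no segment members.
#' @return The `pangene_set` with `sequences` and `missing_sequence`
#'   elements.
#' @export
attach_sequences <- function(ps, records, assemblies = NULL) {
  stopifnot(inherits(ps, "pangene_set"))
  genes <- ps$clusters |> filter(.data$type == "gene")
  seqs <- records |>
    inner_join(genes |> select("cluster", "cluster_id", "assembly", "member"),
               by = c(assembly = "assembly", gene_id = "member"))
  segs <- ps$clusters |> filter(.data$type == "segment")
  if (nrow(segs) > 0) {
    if (is.null(assemblies)) stop_pg("assemblies needed to cut gDNA segment members")
    byid <- setNames(assemblies, map_chr(assemblies, "assembly_id"))
    gd <- pmap(segs, function(cluster, cluster_id, assembly, member, chrom,
                              start, end, strand, ...) {
      cut_gdna(byid[[assembly]], chrom, start, end, strand) |>
        mutate(cluster = cluster, cluster_id = cluster_id)
    }) |> list_rbind()
    seqs <- bind_rows(seqs, gd)
  }
  ps$sequences <- seqs |> arrange(.data$cluster, .data$kind, .data$assembly, .data$seq_id)
  ps$missing_sequence <- genes |>
    anti_join(records |> distinct(.data$assembly, .data$gene_id),
              by = c(assembly = "assembly", member = "gene_id")) |>
    select("cluster_id", "assembly", "member")
  ps
}

#' Write per-cluster FASTA files
#'
#' One FASTA per cluster and sequence kind
#' (`<cluster_id>.<kind>.fna`/`.faa`), listing every isoform of every
#' member (plus gDNA segment slices) in deterministic order.
#'
#' @param ps A `pangene_set` with attached sequences.
#' @param outdir Output directory (created if needed).
#' @return Tibble of written files (`cluster_id`, `kind`, `path`),
#'   invisibly.
#' @export
write_cluster_fastas <- function(ps, outdir) {
  stopifnot(inherits(ps, "pangene_set"), !is.null(ps$sequences))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- ps$sequences |>
    group_by(.data$cluster_id, .data$kind) |>
    group_map(function(df, key) {
      ext <- if (key$kind == "pep") "faa" else "fna"
      path <- file.path(outdir, sprintf("%s.%s.%s", sanitize_id(key$cluster_id), key$kind, ext))
      x <- Biostrings::BStringSet(setNames(df$sequence, df$seq_id))
      Biostrings::writeXStringSet(x, path, width = 60L)
      tibble(cluster_id = key$cluster_id, kind = key$kind, path = path)
    }) |> list_rbind()
  invisible(out)
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Flag split, tandem and inverted gene models per cluster
#'
#' The mode gene model of a cluster is the most frequent representative CDS
#' length across assemblies (per gene: longest isoform CDS; ties on the
#' mode go to the longest length). An assembly contributing `k > 1` members
#' whose summed CDS length is within `tol` of the mode contributes `k - 1`
#' split models; `k > 1` members not explained as a split contribute
#' `k - 1` tandem copies. Inverted members are genes seen in `-` strand
#' alignment evidence whose strand is the minority strand of their cluster
#' (ties resolved against the naming member's strand).
#'
#' @param ps A `pangene_set` with attached sequences.
#' @param tol Relative tolerance on the summed-vs-mode CDS length for split
#'   detection (default 0.2).
#' @return Tibble: `cluster_id`, `split_count`, `tandem_count`,
#'   `inverted_count`, `inverted_members` (list column).
#' @export
flag_structure <- function(ps, tol = 0.2) {
  stopifnot(inherits(ps, "pangene_set"), !is.null(ps$sequences))
  cds_src <- ps$sequences |> filter(.data$kind == "cds")
  cds_len <- if (nrow(cds_src) == 0) {
    tibble(cluster_id = character(), assembly = character(),
           gene_id = character(), cds = integer())
  } else {
    cds_src |>
      group_by(.data$cluster_id, .data$assembly, .data$gene_id) |>
      summarise(cds = max(.data$length), .groups = "drop")
  }

  genes <- ps$clusters |> filter(.data$type == "gene")
  inv_ev <- ps$inverted_evidence %||% tibble(assembly = character(), gene_id = character())

  per_cluster <- genes |>
    distinct(.data$cluster_id) |>
    pull(.data$cluster_id)

  res <- map(per_cluster, function(cid) {
    mem <- genes |> filter(.data$cluster_id == cid)
    lens <- cds_len |> filter(.data$cluster_id == cid)
    split_count <- 0L; tandem_count <- 0L
    if (nrow(lens) > 0) {
      # mode over single-member assemblies first, falling back to all genes
      singles <- lens |> group_by(.data$assembly) |> filter(dplyr::n() == 1) |> ungroup()
      pool <- if (nrow(singles) > 0) singles$cds else lens$cds
      tab <- table(pool)
      mode_len <- max(as.integer(names(tab)[tab == max(tab)]))
      multi <- lens |> group_by(.data$assembly) |>
        summarise(k = dplyr::n(), total = sum(.data$cds), .groups = "drop") |>
        filter(.data$k > 1)
      for (i in seq_len(nrow(multi))) {
        if (abs(multi$total[i] - mode_len) <= tol * mode_len) {
          split_count <- split_count + multi$k[i] - 1L
        } else {
          tandem_count <- tandem_count + multi$k[i] - 1L
        }
      }
    }
    withev <- mem |> semi_join(inv_ev, by = c(assembly = "assembly", member = "gene_id"))
    inv_members <- character()
    if (nrow(withev) > 0) {
      strands <- table(mem$strand)
      if (length(strands) > 1) {
        if (strands[["+"]] == strands[["-"]]) {
          ref_strand <- mem$strand[mem$member == cid][1] %na% "+"
          minority <- setdiff(c("+", "-"), ref_strand)
        } else {
          minority <- names(strands)[which.min(strands)]
        }
        inv_members <- withev$member[withev$strand == minority]
      }
    }
    tibble(
      cluster_id = cid, split_count = split_count, tandem_count = tandem_count,
      inverted_count = length(inv_members), inverted_members = list(inv_members)
    )
  }) |> list_rbind()
  res |> arrange(.data$cluster_id)
}
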