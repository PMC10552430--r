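# Occupancy classification, pangene / POCS matrices and pan-core growth
# curves.

#' Classify cluster occupancy
#'
#' Occupancy is the number of genomes contributing at least one gene member
#' to a cluster (genomic-segment members do not count). Classes: `core`
#' (all `n` genomes), `softcore` (at least `ceiling(softcore_frac * n)`
#' genomes but not all), `shell` (more than one genome but below the
#' soft-core threshold), `singleton` (exactly one genome). The classes
#' partition the clusters; note that for reporting, soft-core *totals*
#' conventionally include the core (see [glance.pangene_set()]).
#'
#' @param occupancy Integer vector of cluster occupancies.
#' @param n_genomes Number of genomes analyzed.
#' @param softcore_frac Soft-core fraction (default 0.95).
#' @return Character vector of classes, same length as `occupancy`.
#' @export
classify_occupancy <- function(occupancy, n_genomes, softcore_frac = 0.95) {
  if (any(occupancy > n_genomes)) {
    stop_pg("occupancy %d exceeds number of genomes %d",
            max(occupancy), n_genomes)
  }
  thr <- ceiling(softcore_frac * n_genomes)
  dplyr::case_when(
    occupancy == n_genomes ~ "core",
    occupancy >= thr & occupancy > 1 ~ "softcore",
    occupancy > 1 ~ "shell",
    occupancy == 1 ~ "singleton",
    TRUE ~ "empty"
  )
}

#' Build the BED-like pangene matrix
#'
#' One row per cluster with leading BED-like columns (`chrom`, `start`
#' 0-based, `end`, `cluster_id`) taken from the naming member's coordinates,
#' then one column per assembly holding the comma-joined gene ids present,
#' a `segment:chrom:start-end` descriptor for genomic-segment members, or
#' `-` for absence. Rows are sorted by reference chromosome and start;
#' clusters with no locatable naming member go to an unsorted tail block.
#'
#' @param ps A named `pangene_set`.
#' @return A tibble (the pangene matrix).
#' @export
build_pangene_matrix <- function(ps) {
  stopifnot(inherits(ps, "pangene_set"), "cluster_id" %in% names(ps$clusters))
  cl <- ps$clusters
  coords <- cl |>
    filter(.data$type == "gene", .data$member == .data$cluster_id) |>
    distinct(.data$cluster_id, .keep_all = TRUE) |>
    select("cluster_id", "chrom", "start", "end")
  cells <- cl |>
    mutate(label = ifelse(.data$type == "segment",
                          sprintf("segment:%s:%d-%d", .data$chrom, .data$start, .data$end),
                          .data$member)) |>
    group_by(.data$cluster_id, .data$assembly) |>
    summarise(cell = paste(sort(.data$label), collapse = ","), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "assembly", values_from = "cell")
  for (a in setdiff(ps$assemblies, names(cells))) cells[[a]] <- NA_character_
  mat <- cells |>
    left_join(coords, by = "cluster_id") |>
    select("chrom", "start", "end", "cluster_id", dplyr::all_of(ps$assemblies)) |>
    mutate(across(dplyr::all_of(ps$assemblies), ~ coalesce(.x, "-")))
  located <- mat |> filter(!is.na(.data$chrom)) |> arrange(.data$chrom, .data$start)
  tail_blk <- mat |> filter(is.na(.data$chrom)) |> arrange(.data$cluster_id)
  bind_rows(located, tail_blk)
}

#' Write a pangene matrix as TSV
#'
#' @param mat Tibble from [build_pangene_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pangene_matrix <- function(mat, path) {
  out <- mat |> mutate(
    chrom = coalesce(.data$chrom, "-"),
    start = ifelse(is.na(.data$start), "-", as.character(.data$start)),
    end = ifelse(is.na(.data$end), "-", as.character(.data$end))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Percentage of conserved sequences (POCS) matrix
#'
#' For assemblies A and B, `POCS(A,B) = 100 * (g_A + g_B) / (T_A + T_B)`
#' where `g_X` counts genes of X in clusters containing both A and B gene
#' members, and `T_X` counts all clustered genes of X. Segment members do
#' not count. The matrix is symmetric with diagonal 100. The formula is
#' recorded in the matrix attribute `formula`.
#'
#' @param ps A `pangene_set`.
#' @return Square numeric matrix of percentages keyed by assembly id.
#' @export
pocs_matrix <- function(ps) {
  stopifnot(inherits(ps, "pangene_set"))
  genes <- ps$clusters |> filter(.data$type == "gene")
  asms <- ps$assemblies
  totals <- genes |> count(.data$assembly, name = "total")
  mat <- matrix(NA_real_, length(asms), length(asms), dimnames = list(asms, asms))
  diag(mat) <- 100
  counts <- genes |> count(.data$cluster, .data$assembly, name = "k")
  for (i in seq_along(asms)) {
    for (j in seq_along(asms)) {
      if (j <= i) next
      a <- asms[i]; b <- asms[j]
      ta <- totals$total[totals$assembly == a] %na% 0L
      tb <- totals$total[totals$assembly == b] %na% 0L
      if (ta == 0 || tb == 0) next # assembly with no genes stays missing
      shared <- intersect(
        counts$cluster[counts$assembly == a],
        counts$cluster[counts$assembly == b]
      )
      ga <- sum(counts$k[counts$assembly == a & counts$cluster %in% shared])
      gb <- sum(counts$k[counts$assembly == b & counts$cluster %in% shared])
      mat[a, b] <- mat[b, a] <- 100 * (ga + gb) / (ta + tb)
    }
  }
  attr(mat, "formula") <- "POCS(A,B) = 100*(g_A+g_B)/(T_A+T_B); g_X = genes of X in clusters shared by A and B, T_X = clustered genes of X"
  mat
}

#' Pan/core/soft-core genome growth curves
#'
#' Samples `n_perm` random orders of the assemblies; for every prefix of
#' length `k` counts pan clusters (gene members in at least one of the
#' first `k` genomes), core clusters (members in all `k`) and soft-core
#' clusters (members in at least `ceiling(softcore_frac * k)` genomes).
#' Reports per-`k` means and standard deviations over permutations.
#'
#' @param ps A `pangene_set`.
#' @param n_perm Number of permutations (default 10).
#' @param seed RNG seed.
#' @param softcore_frac Soft-core fraction (default 0.95).
#' @return Tibble: `k`, `metric` (`pan`/`softcore`/`core`), `mean`, `sd`.
#' @export
growth_curves <- function(ps, n_perm = 10L, seed = 1L, softcore_frac = 0.95) {
  stopifnot(inherits(ps, "pangene_set"))
  if (n_perm < 1) stop_pg("n_perm must be >= 1")
  asms <- ps$assemblies
  if (length(asms) < 2) stop_pg("growth curves need at least 2 assemblies")
  membership <- ps$clusters |>
    filter(.data$type == "gene") |>
    distinct(.data$cluster, .data$assembly)
  # cluster x assembly presence matrix
  pres <- table(membership$cluster, membership$assembly) > 0
  pres <- pres[, asms, drop = FALSE]

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  rows <- withr_seed({
    map(seq_len(n_perm), function(p) {
      ord <- sample(asms)
      cum <- matrix(FALSE, nrow(pres), 0)
      counts <- matrix(0L, nrow = length(asms), ncol = 3,
                       dimnames = list(NULL, c("pan", "softcore", "core")))
      hit <- matrix(0L, nrow(pres), 1)[, 1]
      for (k in seq_along(ord)) {
        hit <- hit + as.integer(pres[, ord[k]])
        thr <- ceiling(softcore_frac * k)
        counts[k, ] <- c(sum(hit >= 1), sum(hit >= thr), sum(hit == k))
      }
      as_tibble(counts) |> mutate(k = seq_along(ord), perm = p)
    }) |> list_rbind()
  })
  rows |>
    tidyr::pivot_longer(c("pan", "softcore", "core"),
                        names_to = "metric", values_to = "size") |>
    group_by(.data$k, .data$metric) |>
    summarise(mean = mean(.data$size), sd = sd(.data$size), .groups = "drop") |>
    mutate(sd = coalesce(.data$sd, 0)) |>
    arrange(.data$k, .data$metric)
}
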