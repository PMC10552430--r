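# Score pipeline output against simulator ground truth.

#' Compare pipeline results with simulator ground truth
#'
#' Scores a clustering (and optionally structural flags and lift-over
#' results) against the planted truth of [simulate_pangenome()].
#'
#' @param ps A named `pangene_set` from the pipeline.
#' @param truth The `truth` element returned by [simulate_pangenome()].
#' @param flags Optional tibble from [flag_structure()].
#' @param liftover Optional lift-over results
#'   (rows from [check_cluster()] in `missing` mode over candidate
#'   clusters).
#' @return A list: `partition_exact` (all ancestral genes, including event
#'   genes, recovered as exactly the planted member sets),
#'   `partition_exact_unperturbed` (same restricted to event-free genes),
#'   `pav_recall`, `pav_precision` (planted absent cells vs predicted
#'   absences), `inversion_flags_correct`, `split_flags_correct`,
#'   `tandem_flags_correct`, `liftover_confirmed`, `liftover_rejected`,
#'   `cluster_of` (anc gene -> cluster_id map).
#' @export
verify_against_truth <- function(ps, truth, flags = NULL, liftover = NULL) {
  stopifnot(inherits(ps, "pangene_set"))
  genes <- ps$clusters |> filter(.data$type == "gene") |>
    mutate(key = paste(.data$assembly, .data$member, sep = "\r"))
  pred_sets <- split(genes$key, genes$cluster_id)

  tm <- truth$members |>
    mutate(key = paste(.data$assembly, .data$gene_id, sep = "\r"))
  truth_sets <- split(tm$key, tm$anc_id)
  pred_index <- setNames(rep(names(pred_sets), lengths(pred_sets)),
                         unlist(pred_sets))

  match_exact <- map_lgl(truth_sets, function(s) {
    cids <- unique(pred_index[s])
    length(cids) == 1 && !any(is.na(cids)) &&
      setequal(pred_sets[[cids]], s)
  })
  ev <- truth$genes$event[match(names(truth_sets), truth$genes$anc_id)]
  partition_exact <- all(match_exact)
  partition_exact_unperturbed <- all(match_exact[ev == "none"])

  # predicted cluster of each ancestral gene: the cluster holding most of
  # its planted members
  cluster_of <- map_chr(truth_sets, function(s) {
    cids <- pred_index[s]
    cids <- cids[!is.na(cids)]
    if (length(cids) == 0) return(NA_character_)
    names(sort(table(cids), decreasing = TRUE))[1]
  })

  n <- length(ps$assemblies)
  occ <- cluster_occupancy(ps) |>
    left_join(ps$clusters |> distinct(.data$cluster, .data$cluster_id),
              by = "cluster")
  occ_of <- setNames(occ$occupancy, occ$cluster_id)

  # PAV cells: (anc gene, assembly) with no gene member
  pred_absent <- list()
  for (g in names(cluster_of)) {
    cid <- cluster_of[[g]]
    if (is.na(cid)) next
    present <- unique(genes$assembly[genes$cluster_id == cid])
    for (a in setdiff(ps$assemblies, present)) {
      pred_absent[[length(pred_absent) + 1L]] <- paste(g, a, sep = "\r")
    }
  }
  pred_absent <- unlist(pred_absent) %||% character()
  truth_absent <- truth$genes |>
    filter(.data$event %in% c("deletion", "hidden", "partial_deletion")) |>
    mutate(cell = paste(.data$anc_id, .data$ev_assembly, sep = "\r")) |>
    pull(.data$cell)
  pav_recall <- if (length(truth_absent) == 0) 1 else {
    mean(truth_absent %in% pred_absent)
  }
  pav_precision <- if (length(pred_absent) == 0) 1 else {
    mean(pred_absent %in% truth_absent)
  }

  inversion_flags_correct <- NA
  split_flags_correct <- NA
  tandem_flags_correct <- NA
  if (!is.null(flags)) {
    flagged_inv <- flags |>
      select("cluster_id", "inverted_members") |>
      tidyr::unnest("inverted_members") |>
      pull(.data$inverted_members)
    inversion_flags_correct <- setequal(flagged_inv, truth$inverted_genes$gene_id)
    split_cids <- cluster_of[truth$split_clusters]
    split_flags_correct <- length(split_cids) == 0 ||
      all(!is.na(split_cids) &
            flags$split_count[match(split_cids, flags$cluster_id)] >= 1)
    tandem_cids <- cluster_of[truth$tandem_clusters]
    tandem_flags_correct <- length(tandem_cids) == 0 ||
      all(!is.na(tandem_cids) &
            flags$tandem_count[match(tandem_cids, flags$cluster_id)] >= 1)
  }

  liftover_confirmed <- liftover_rejected <- NA_integer_
  if (!is.null(liftover) && nrow(liftover) > 0) {
    liftover_confirmed <- sum(liftover$verdict == "missing_gene_confirmed")
    liftover_rejected <- sum(liftover$verdict == "rejected")
  }

  list(
    partition_exact = partition_exact,
    partition_exact_unperturbed = partition_exact_unperturbed,
    pav_recall = pav_recall,
    pav_precision = pav_precision,
    inversion_flags_correct = inversion_flags_correct,
    split_flags_correct = split_flags_correct,
    tandem_flags_correct = tandem_flags_correct,
    liftover_confirmed = liftover_confirmed,
    liftover_rejected = liftover_rejected,
    cluster_of = cluster_of
  )
}
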