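union_find_components <- function(ids, edges_a, edges_b) {
  # ids: character vector of all records; edges: parallel vectors of matched
  # pairs (as indices into ids). Weighted quick-union with path halving.
  n <- length(ids)
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k])
    rb <- find(edges_b[k])
    if (ra != rb) {
      if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
      parent[rb] <- ra
      size[ra] <- size[ra] + size[rb]
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Deduplicate records into entity clusters
#'
#' Clusters are the connected components of the match graph (transitive
#' closure over pairs labelled `match`): a cluster may contain pairs that
#' were individually classified non-match if a chain of matches connects
#' them, mirroring standard deduplication practice. Records touching no
#' match form singleton clusters, so the clusters partition the record set.
#' Cluster ids are dense integers assigned in order of each cluster's
#' smallest record id, making the output deterministic.
#'
#' @param decisions Tibble with `record_id_a`, `record_id_b`, `label`
#'   (from [predict.hcm_match_model()]); only `label == "match"` rows form
#'   edges.
#' @param record_ids Character vector of all record ids to partition.
#' @return A tibble with `record_id`, `cluster_id`.
#' @export
deduplicate <- function(decisions, record_ids) {
  ids <- sort(unique(record_ids))
  matched <- decisions[decisions$label == "match", , drop = FALSE]
  ea <- match(matched$record_id_a, ids)
  eb <- match(matched$record_id_b, ids)
  keep <- !is.na(ea) & !is.na(eb)
  root <- union_find_components(ids, ea[keep], eb[keep])
  cluster_id <- match(root, unique(root))  # ids sorted => order of min member
  tibble::tibble(record_id = ids, cluster_id = cluster_id)
}

#' Link cancer records to deduplicated HIV clusters
#'
#' Candidate cancer-HIV record pairs come from shared blocking keys; each
#' pair is scored by the match classifier. A cancer record links to at most
#' one cluster: the cluster whose best-scoring pair is highest, provided
#' that pair is classified a match; ties go to the smaller `cluster_id`.
#' Cancer records with no matching cluster stay unlinked (absent from the
#' output).
#'
#' @param cancer_std,hiv_std Standardized record tibbles.
#' @param clusters Tibble `record_id`, `cluster_id` from [deduplicate()].
#' @param model An `hcm_match_model`.
#' @param features Optional precomputed comparison vectors for the
#'   cancer-HIV candidate pairs (`record_id_a` = cancer side); computed
#'   from blocking when `NULL`.
#' @return A tibble `cancer_record_id`, `cluster_id`, `score`.
#' @export
link_cancer <- function(cancer_std, hiv_std, clusters, model, features = NULL) {
  if (is.null(features)) {
    pairs <- candidate_pairs(cancer_std, hiv_std)
    if (nrow(pairs) == 0) {
      return(tibble::tibble(cancer_record_id = character(),
                            cluster_id = integer(), score = numeric()))
    }
    features <- compare_pairs(pairs, cancer_std, hiv_std)
  }
  if (nrow(features) == 0) {
    return(tibble::tibble(cancer_record_id = character(),
                          cluster_id = integer(), score = numeric()))
  }
  scored <- predict(model, features)
  scored |>
    dplyr::filter(.data$label == "match") |>
    dplyr::inner_join(clusters, by = c(record_id_b = "record_id")) |>
    dplyr::group_by(.data$record_id_a, .data$cluster_id) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$record_id_a, dplyr::desc(.data$score), .data$cluster_id) |>
    dplyr::distinct(.data$record_id_a, .keep_all = TRUE) |>
    dplyr::select(cancer_record_id = "record_id_a", "cluster_id", "score")
}

#' Evaluate linkage quality against ground truth
#'
#' Pairwise deduplication metrics are computed by counting, over the HIV
#' record set: truth pairs (same entity), predicted pairs (same cluster)
#' and their intersection give precision, recall and F1. Entity-level
#' agreement is the fraction of truth entities whose record set coincides
#' exactly with one predicted cluster. When `links` are supplied, link
#' precision (linked cluster contains a record of the cancer record's true
#' entity) and link recall (over cancer records whose entity has HIV
#' records) are added.
#'
#' @param clusters Tibble `record_id`, `cluster_id`.
#' @param truth Tibble `record_id`, `entity_id`; must be non-empty.
#' @param links Optional tibble from [link_cancer()].
#' @param cancer_ids Character vector of all cancer record ids; required for
#'   link recall (its denominator is the cancer records whose true entity
#'   appears among the clustered HIV records).
#' @return A one-row tibble of metrics.
#' @export
evaluate_linkage <- function(clusters, truth, links = NULL, cancer_ids = NULL) {
  if (is.null(truth) || nrow(truth) == 0) {
    stop("truth table is empty", call. = FALSE)
  }
  df <- dplyr::inner_join(clusters, truth, by = "record_id")
  choose2 <- function(m) sum(m * (m - 1) / 2)
  truth_pairs <- df |> dplyr::count(.data$entity_id) |> dplyr::pull("n") |> choose2()
  pred_pairs <- df |> dplyr::count(.data$cluster_id) |> dplyr::pull("n") |> choose2()
  tp <- df |> dplyr::count(.data$cluster_id, .data$entity_id) |>
    dplyr::pull("n") |> choose2()
  precision <- if (pred_pairs > 0) tp / pred_pairs else 1
  recall <- if (truth_pairs > 0) tp / truth_pairs else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0

  by_entity <- df |> dplyr::count(.data$entity_id, .data$cluster_id)
  entity_sizes <- df |> dplyr::count(.data$entity_id, name = "n_entity")
  cluster_sizes <- df |> dplyr::count(.data$cluster_id, name = "n_cluster")
  exact <- by_entity |>
    dplyr::inner_join(entity_sizes, by = "entity_id") |>
    dplyr::inner_join(cluster_sizes, by = "cluster_id") |>
    dplyr::filter(.data$n == .data$n_entity, .data$n == .data$n_cluster)
  entity_exact <- nrow(exact) / nrow(entity_sizes)

  out <- tibble::tibble(
    pairwise_precision = precision, pairwise_recall = recall, pairwise_f1 = f1,
    entity_exact = entity_exact,
    n_records = nrow(df), n_truth_pairs = truth_pairs, n_pred_pairs = pred_pairs
  )
  if (!is.null(links) && nrow(links) > 0) {
    cancer_entity <- truth$entity_id[match(links$cancer_record_id, truth$record_id)]
    cluster_entities <- dplyr::distinct(df, .data$cluster_id, .data$entity_id)
    hit <- dplyr::inner_join(
      tibble::tibble(cluster_id = links$cluster_id, entity_id = cancer_entity,
                     cancer_record_id = links$cancer_record_id),
      cluster_entities, by = c("cluster_id", "entity_id")
    )
    out$link_precision <- nrow(hit) / nrow(links)
    if (!is.null(cancer_ids)) {
      cancer_entities <- truth$entity_id[match(cancer_ids, truth$record_id)]
      linkable <- sum(cancer_entities %in% df$entity_id)
      out$link_recall <- if (linkable > 0) nrow(hit) / linkable else NA_real_
    }
  }
  out
}
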