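decision_row <- function(a, b, label) {
  tibble::tibble(record_id_a = a, record_id_b = b, score = ifelse(label == "match", 1, -1),
                 label = factor(label, levels = c("non-match", "match")))
}

test_that("transitive closure merges chains despite a non-match pair", {
  dec <- dplyr::bind_rows(
    decision_row("A", "B", "match"),
    decision_row("B", "C", "match"),
    decision_row("A", "C", "non-match")
  )
  cl <- deduplicate(dec, c("A", "B", "C"))
  expect_identical(dplyr::n_distinct(cl$cluster_id), 1L)
})

test_that("no matches yields all-singleton clusters partitioning the records", {
  dec <- decision_row("A", "B", "non-match")
  cl <- deduplicate(dec, c("A", "B", "C"))
  expect_identical(nrow(cl), 3L)
  expect_identical(dplyr::n_distinct(cl$cluster_id), 3L)
  expect_setequal(cl$record_id, c("A", "B", "C"))
})

test_that("union-find components equal brute-force traversal on random instances", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    ids <- sprintf("R%03d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    ea <- sample.int(n, m, replace = TRUE)
    eb <- sample.int(n, m, replace = TRUE)
    keep <- ea != eb
    uf <- hivcanmatch:::union_find_components(ids, ea[keep], eb[keep])
    bf <- bfs_components(ids, ea[keep], eb[keep])
    # same partition up to relabelling
    expect_identical(as.integer(factor(uf, levels = unique(uf))),
                     as.integer(factor(bf, levels = unique(bf))))
  }
})

test_that("zero-corruption deduplication recovers the truth partition exactly", {
  sim <- simulate_records(small_config(n = 1000, seed = 25,
                                       corruption = zero_corruption()))
  set.seed(25)
  linked <- run_linkage(sim$hiv, sim$cancer, sim$truth, n_train = 2000)
  joined <- dplyr::inner_join(linked$clusters, sim$truth, by = "record_id")
  # one cluster per entity and vice versa
  expect_identical(
    dplyr::n_distinct(paste(joined$cluster_id, joined$entity_id)),
    dplyr::n_distinct(joined$cluster_id)
  )
  expect_identical(dplyr::n_distinct(joined$cluster_id),
                   dplyr::n_distinct(joined$entity_id))

  # idempotence: re-linking one representative per cluster causes no merges
  reps <- linked$hiv_std[!duplicated(linked$clusters$cluster_id[
    match(linked$hiv_std$record_id, linked$clusters$record_id)]), ]
  rep_pairs <- candidate_pairs(reps)
  rep_feats <- compare_pairs(rep_pairs, reps)
  rep_dec <- predict(linked$model, rep_feats)
  rep_cl <- deduplicate(rep_dec, reps$record_id)
  expect_identical(dplyr::n_distinct(rep_cl$cluster_id), nrow(reps))
})

test_that("evaluate_linkage counts pairwise metrics correctly", {
  truth <- tibble::tibble(record_id = c("a", "b", "c", "d", "e", "f"),
                          entity_id = c(1, 1, 2, 2, 3, 4))
  perfect <- tibble::tibble(record_id = truth$record_id,
                            cluster_id = c(1, 1, 2, 2, 3, 4))
  ev <- evaluate_linkage(perfect, truth)
  expect_identical(ev$pairwise_precision, 1)
  expect_identical(ev$pairwise_recall, 1)

  singletons <- tibble::tibble(record_id = truth$record_id, cluster_id = 1:6)
  ev0 <- evaluate_linkage(singletons, truth)
  expect_identical(ev0$pairwise_recall, 0)

  # one spurious pair on top of a perfect prediction: precision n/(n+1)
  spurious <- tibble::tibble(record_id = truth$record_id,
                             cluster_id = c(1, 1, 2, 2, 3, 3))
  ev1 <- evaluate_linkage(spurious, truth)
  expect_equal(ev1$pairwise_precision, 2 / 3)
  expect_identical(ev1$pairwise_recall, 1)

  expect_error(evaluate_linkage(perfect, truth[0, ]), "empty")
})

test_that("cancer records link to the matching cluster or stay unlinked", {
  hiv <- standardize_records(dplyr::bind_rows(
    raw_hiv("H1", first = "THABO", sur = "NKOSI", episode = "E1", folder = "F1"),
    raw_hiv("H2", first = "THABO", sur = "NKOSI", episode = "E1", folder = "F1"),
    raw_hiv("H3", first = "WILLEM", sur = "PRETORIUS",
            dob = as.Date("1988-06-15"), episode = "E2", folder = "F2")
  ))
  clusters <- tibble::tibble(record_id = c("H1", "H2", "H3"),
                             cluster_id = c(1L, 1L, 2L))
  model <- fit_match_classifier(toy_train())
  same <- standardize_records(raw_cancer("C1", first = "THABO", sur = "NKOSI"))
  links <- link_cancer(same, hiv, clusters, model)
  expect_identical(links$cluster_id, 1L)

  stranger <- standardize_records(raw_cancer("C2", first = "GRACE", sur = "MOYO",
                                             dob = as.Date("1960-10-10")))
  links2 <- link_cancer(stranger, hiv, clusters, model)
  expect_identical(nrow(links2), 0L)
})
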