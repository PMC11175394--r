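test_that("only positive HIV results survive the result filter", {
  recs <- dplyr::bind_rows(
    raw_hiv("H1", result = "positive"),
    raw_hiv("H2", result = "negative"),
    raw_hiv("H3", result = "unknown")
  )
  expect_identical(filter_hiv_positive(recs)$record_id, "H1")
  all_pos <- dplyr::bind_rows(raw_hiv("H4"), raw_hiv("H5"))
  expect_identical(filter_hiv_positive(all_pos), all_pos)
})

test_that("the positive fraction of generated records matches its weights", {
  cfg <- small_config(n = 2600, seed = 12)
  sim <- simulate_records(cfg)
  n <- nrow(sim$hiv)
  expect_gte(n, 10000)
  kept <- nrow(filter_hiv_positive(sim$hiv)) / n
  expect_lt(abs(kept - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("incident cancer selection takes the earliest report, ties by record id", {
  two <- dplyr::bind_rows(
    raw_cancer("C2", date = as.Date("2012-03-01")),
    raw_cancer("C1", date = as.Date("2010-05-01"))
  )
  expect_identical(incident_cancer(two)$record_id, "C1")
  one <- raw_cancer("C9")
  expect_identical(incident_cancer(one)$record_id, "C9")
  tie <- dplyr::bind_rows(
    raw_cancer("C5", date = as.Date("2010-05-01")),
    raw_cancer("C4", date = as.Date("2010-05-01"))
  )
  expect_identical(incident_cancer(tie)$record_id, "C4")
})

test_that("temporal eligibility keeps same-day and later cancers only", {
  expect_true(temporal_filter(as.Date("2009-01-01"), as.Date("2011-06-01")))
  expect_false(temporal_filter(as.Date("2012-01-01"), as.Date("2011-06-01")))
  expect_true(temporal_filter(as.Date("2011-06-01"), as.Date("2011-06-01")))
  expect_false(temporal_filter(as.Date(NA), as.Date("2011-06-01")))
})

test_that("home province is the modal province with the stated tie-breaks", {
  recs <- dplyr::bind_rows(
    raw_hiv("H1", province = "GAU"),
    raw_hiv("H2", province = "GAU"),
    raw_hiv("H3", province = "KZN")
  )
  expect_identical(home_province(recs), "GAU")
  expect_identical(home_province(raw_hiv("H4", province = "KZN")), "KZN")
  tie <- dplyr::bind_rows(
    raw_hiv("H5", province = "GAU", date = as.Date("2006-01-01")),
    raw_hiv("H6", province = "KZN", date = as.Date("2005-01-01"))
  )
  expect_identical(home_province(tie), "KZN")
})

test_that("a handcrafted six-cluster fixture yields three cases and attrition (1,1,1)", {
  mk_person <- function(id, first, result = "positive",
                        hiv_date = as.Date("2006-01-01")) {
    raw_hiv(paste0("H", id), first = first, result = result, date = hiv_date)
  }
  hiv <- standardize_records(dplyr::bind_rows(
    mk_person(1, "THABO"),
    mk_person(2, "LERATO", result = "negative"),        # negative-only
    mk_person(3, "SIPHO", hiv_date = as.Date("2012-01-01")),  # HIV after cancer
    mk_person(4, "NOMSA"),                               # missing province
    mk_person(5, "KAGISO"),
    mk_person(6, "PALESA")
  ))
  cancer <- standardize_records(dplyr::bind_rows(
    raw_cancer("C1", first = "THABO"),
    raw_cancer("C2", first = "LERATO"),
    raw_cancer("C3", first = "SIPHO", date = as.Date("2011-06-01")),
    raw_cancer("C4", first = "NOMSA", diag_province = NA),
    raw_cancer("C5", first = "KAGISO"),
    raw_cancer("C6", first = "PALESA")
  ))
  clusters <- tibble::tibble(record_id = paste0("H", 1:6), cluster_id = 1:6)
  links <- tibble::tibble(cancer_record_id = paste0("C", 1:6),
                          cluster_id = 1:6, score = 1)
  cohort <- build_cases(hiv, clusters, links, cancer)
  expect_identical(nrow(cohort$cases), 3L)
  expect_identical(unname(cohort$attrition),
                   c(6L, 1L, 1L, 1L, 3L))
  expect_identical(sum(cohort$attrition[2:4]) + cohort$attrition[["final_cases"]],
                   cohort$attrition[["input_clusters"]])
  # filter order invariance: missing-province drop before the temporal filter
  # yields the same final case set
  cancer2 <- cancer[!is.na(cancer$diagnosis_province), ]
  links2 <- links[links$cancer_record_id != "C4", ]
  cohort2 <- build_cases(hiv, clusters, links2, cancer2)
  expect_setequal(cohort2$cases$cluster_id, cohort$cases$cluster_id)
})

test_that("zero-corruption cases match the truth-side cohort definition exactly", {
  cfg <- small_config(n = 1500, seed = 27, corruption = zero_corruption(),
                      cancer_fraction = 0.4)
  sim <- simulate_records(cfg)
  set.seed(27)
  linked <- run_linkage(sim$hiv, sim$cancer, sim$truth, n_train = 2000)
  cohort <- build_cases(linked$hiv_std, linked$clusters, linked$links,
                        linked$cancer_std)

  # truth-side: entities with a positive HIV record, whose earliest positive
  # test is on or before their incident diagnosis, with a known province
  pos <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(sim$hiv, result_label == "positive"), entity_id),
    first_pos = min(test_date)
  )
  inc <- dplyr::distinct(
    dplyr::arrange(sim$cancer, diagnosis_date, record_id), entity_id,
    .keep_all = TRUE
  )
  truth_cases <- dplyr::inner_join(pos, inc, by = "entity_id")
  truth_n <- sum(truth_cases$first_pos <= truth_cases$diagnosis_date &
                   !is.na(truth_cases$diagnosis_province))
  expect_identical(nrow(cohort$cases), as.integer(truth_n))
})

test_that("identity mobility produces no out-of-province cases", {
  cfg <- small_config(n = 800, seed = 35, cancer_fraction = 0.5,
                      mobility = mobility_identity(), away_record_rate = 0)
  run <- run_pipeline(cfg, n_train = 2000)
  expect_true(all(!run$cohort$cases$out_of_province))
})
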