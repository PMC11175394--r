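# Shared helpers: small configurations, a zero-noise corruption model, a
# brute-force connected-components oracle, and raw-record constructors for
# handcrafted cohort fixtures.

zero_corruption <- function() {
  corruption_model(typo_rate = 0, nickname_swap_rate = 0, dob_error_rate = 0,
                   dob_missing_rate = 0, identifier_missing_rate = 0)
}

small_config <- function(n = 1000, seed = 42, ...) {
  sim_config(n_entities = n, seed = seed, ...)
}

# independent components oracle: breadth-first traversal over the match graph
bfs_components <- function(ids, edges_a, edges_b) {
  adj <- split(c(edges_b, edges_a), c(edges_a, edges_b))
  comp <- rep(NA_integer_, length(ids))
  cur <- 0L
  for (s in seq_along(ids)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[as.character(v)]]) {
        if (is.na(comp[w])) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# perfectly separable labelled comparison vectors for classifier tests
toy_train <- function(n = 40) {
  ones <- tibble::tibble(record_id_a = paste0("A", 1:n), record_id_b = paste0("B", 1:n),
                         sim_first_name = 1, sim_surname = 1, age_agreement = 1,
                         dob_exact = 1, episode_match = 1, folder_match = 1,
                         label = factor("match", levels = c("non-match", "match")))
  zeros <- dplyr::mutate(ones, dplyr::across(sim_first_name:folder_match, ~0),
                         label = factor("non-match", levels = c("non-match", "match")))
  dplyr::bind_rows(ones, zeros)
}

# raw HIV record rows for handcrafted cohort fixtures
raw_hiv <- function(record_id, first = "THABO", sur = "NKOSI",
                    dob = as.Date("1975-03-04"), province = "GAU",
                    date = as.Date("2008-01-01"), result = "positive",
                    episode = NA_character_, folder = NA_character_) {
  tibble::tibble(
    record_id = record_id, first_name = first, surname = sur,
    sex = "F", race = "Black", dob = dob,
    age = floor(as.numeric(date - dob) / 365.25),
    episode_number = episode, folder_number = folder,
    test_type = "CD4 count", result_label = result,
    facility_id = paste0(province, "-01"), province = province,
    test_date = date
  )
}

raw_cancer <- function(record_id, first = "THABO", sur = "NKOSI",
                       dob = as.Date("1975-03-04"), diag_province = "GAU",
                       date = as.Date("2010-01-01"), type = "cervix") {
  tibble::tibble(
    record_id = record_id, first_name = first, surname = sur,
    sex = "F", race = "Black", dob = dob,
    age = floor(as.numeric(date - dob) / 365.25),
    episode_number = NA_character_, folder_number = NA_character_,
    cancer_type = type, basis = "histology",
    facility_id = paste0(ifelse(is.na(diag_province), "GAU", diag_province), "-01"),
    diagnosis_province = diag_province, diagnosis_date = date
  )
}
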