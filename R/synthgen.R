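#' Simulate a ground-truth population
#'
#' Draws `n_entities` synthetic persons: names from the packaged name banks
#' with heavy-tailed (Zipf-type) rank weights, sex, race and home province
#' from the configured margins, and date of birth from a log-normal age
#' distribution anchored at the study-window midpoint. Each person is also
#' assigned a home facility within the home province. Identities are made
#' unique on the (first name, surname, date of birth) tuple by redrawing
#' collided entities, so the uncorrupted world is perfectly linkable and
#' the ground-truth partition is recoverable exactly; residual identity
#' collisions of real populations are reintroduced only through the
#' corruption model.
#'
#' @param config An [sim_config()] object.
#' @return A tibble with one row per person: `entity_id`, `first_name`,
#'   `surname`, `sex`, `race`, `dob`, `home_province`, `home_facility`.
#' @export
simulate_population <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  generate_population_(config)
}

zipf_weights <- function(n, s = 0.7) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

generate_population_ <- function(config) {
  n <- config$n_entities
  first_bank <- load_name_bank("first")
  sur_bank <- load_name_bank("surname")
  mid <- study_window()[1] + floor(diff(as.numeric(study_window())) / 2)
  age <- rlnorm(n, config$age_meanlog, config$age_sdlog)
  tibble::tibble(
    entity_id = seq_len(n),
    first_name = first_bank[sample.int(length(first_bank), n, replace = TRUE,
                                       prob = zipf_weights(length(first_bank)))],
    surname = sur_bank[sample.int(length(sur_bank), n, replace = TRUE,
                                  prob = zipf_weights(length(sur_bank)))],
    sex = ifelse(runif(n) < config$female_fraction, "F", "M"),
    race = race_labels()[sample.int(4, n, replace = TRUE, prob = config$race_weights)],
    dob = mid - round(age * 365.25),
    home_province = province_codes()[sample.int(9, n, replace = TRUE,
                                                prob = config$province_weights)],
    home_facility = NA_character_
  ) |>
    dplyr::mutate(home_facility = sprintf(
      "%s-%02d", .data$home_province,
      sample.int(config$facilities_per_province, n, replace = TRUE)
    )) |>
    dedupe_identities_(first_bank, sur_bank)
}

dedupe_identities_ <- function(entities, first_bank, sur_bank) {
  repeat {
    key <- paste(entities$first_name, entities$surname, entities$dob)
    clash <- union(which(duplicated(key)), near_twin_clashes_(entities))
    if (length(clash) == 0) return(entities)
    m <- length(clash)
    entities$first_name[clash] <- first_bank[sample.int(
      length(first_bank), m, replace = TRUE,
      prob = zipf_weights(length(first_bank))
    )]
    entities$surname[clash] <- sur_bank[sample.int(
      length(sur_bank), m, replace = TRUE,
      prob = zipf_weights(length(sur_bank))
    )]
    entities$dob[clash] <- entities$dob[clash] +
      sample.int(730, m, replace = TRUE) - 365L
  }
}

# Distinct persons sharing a date of birth whose names are also
# near-identical (both Jaro-Winkler similarities >= 0.85) produce
# comparison vectors the six-feature classifier cannot tell from true
# duplicates; like exact identity collisions, they are excluded from the
# ground truth so the zero-noise world stays exactly linkable.
near_twin_clashes_ <- function(entities) {
  groups <- split(seq_len(nrow(entities)), as.character(entities$dob))
  groups <- groups[lengths(groups) > 1]
  out <- integer(0)
  for (g in groups) {
    for (i in seq_len(length(g) - 1)) {
      for (j in seq((i + 1), length(g))) {
        a <- g[i]; b <- g[j]
        if (jaro_winkler(entities$first_name[a], entities$first_name[b]) >= 0.85 &&
            jaro_winkler(entities$surname[a], entities$surname[b]) >= 0.85) {
          out <- c(out, b)
        }
      }
    }
  }
  unique(out)
}

#' Apply typographic corruption to strings
#'
#' With probability `typo_rate` each string receives one edit drawn from the
#' configured operation weights: substitution of one character, adjacent
#' transposition, deletion, or insertion. Uses the current RNG stream, so
#' results are reproducible under `set.seed()`. A `typo_rate` of zero
#' returns the input unchanged.
#'
#' @param value Character vector (non-empty strings).
#' @param model A [corruption_model()].
#' @return Character vector of the same length.
#' @export
corrupt_string <- function(value, model) {
  stopifnot(inherits(model, "hcm_corruption"))
  if (model$typo_rate == 0 || length(value) == 0) return(value)
  hit <- !is.na(value) & runif(length(value)) < model$typo_rate
  if (!any(hit)) return(value)
  ops <- names(model$typo_ops)[sample.int(4, sum(hit), replace = TRUE,
                                          prob = model$typo_ops)]
  value[hit] <- vapply(seq_along(ops), function(i) {
    apply_typo_(value[hit][i], ops[i])
  }, character(1))
  value
}

apply_typo_ <- function(s, op) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  alphabet <- LETTERS
  if (op == "transposition" && n >= 2) {
    i <- sample.int(n - 1, 1)
    ch[c(i, i + 1)] <- ch[c(i + 1, i)]
  } else if (op == "deletion" && n >= 2) {
    ch <- ch[-sample.int(n, 1)]
  } else if (op == "insertion") {
    i <- sample.int(n + 1, 1)
    ch <- append(ch, alphabet[sample.int(26, 1)], after = i - 1)
  } else {  # substitution (and fallback for degenerate lengths)
    i <- sample.int(n, 1)
    ch[i] <- alphabet[sample.int(26, 1)]
  }
  paste(ch, collapse = "")
}

perturb_dob_ <- function(dob, hit) {
  if (!any(hit)) return(dob)
  lt <- as.POSIXlt(dob[hit])
  flip_day <- runif(sum(hit)) < 0.5
  lt$mday[flip_day] <- sample.int(28, sum(flip_day), replace = TRUE)
  lt$mon[!flip_day] <- sample.int(12, sum(!flip_day), replace = TRUE) - 1L
  lt$mday <- pmin(lt$mday, 28L)  # keep day valid for any month
  dob[hit] <- as.Date(lt)
  dob
}

corrupt_identity_ <- function(df, config, name_bank) {
  cm <- config$corruption
  n <- nrow(df)
  df$first_name <- corrupt_string(df$first_name, cm)
  df$surname <- corrupt_string(df$surname, cm)
  swap <- runif(n) < cm$nickname_swap_rate
  if (any(swap)) {
    df$first_name[swap] <- name_bank[sample.int(length(name_bank), sum(swap),
                                                replace = TRUE)]
  }
  df$dob <- perturb_dob_(df$dob, runif(n) < cm$dob_error_rate)
  df$dob[runif(n) < cm$dob_missing_rate] <- as.Date(NA)
  df$episode_number[runif(n) < cm$identifier_missing_rate] <- NA_character_
  df$folder_number[runif(n) < cm$identifier_missing_rate] <- NA_character_
  df
}

#' Simulate linked HIV and cancer laboratory record sets
#'
#' Emits the full synthetic study inputs with ground truth. Each person
#' makes one or more HIV-care visits (visits = 1 + Poisson, each visit
#' yielding one or two test records that share a date, facility and episode
#' number); most visits are at the home facility, a configurable minority
#' at a facility in another province. A `cancer_fraction` of persons
#' receive one (occasionally two) pathology reports whose diagnosis
#' province is drawn from the mobility-matrix row of the home province.
#' Identifiers on every emitted record are then corrupted per the
#' configured [corruption_model()].
#'
#' @param config An [sim_config()] object.
#' @return An object of class `hcm_simulation`: a list with tibbles
#'   `entities`, `hiv`, `cancer`, and `truth` (`record_id`, `entity_id`).
#' @export
simulate_records <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  entities <- generate_population_(config)
  window <- study_window()
  span <- as.numeric(diff(window))
  n <- nrow(entities)

  ## ---- HIV visits and records ----
  n_visits <- 1L + rpois(n, config$hiv_records_extra_mean)
  visit <- entities[rep.int(seq_len(n), n_visits), ]
  nv <- nrow(visit)
  visit$test_date <- window[1] + round(runif(nv) * span)
  away <- runif(nv) < config$away_record_rate
  away_prov <- vapply(visit$home_province[away], function(p) {
    sample(setdiff(province_codes(), p), 1)
  }, character(1))
  visit$province <- visit$home_province
  visit$province[away] <- away_prov
  visit$facility_id <- visit$home_facility
  visit$facility_id[away] <- sprintf(
    "%s-%02d", away_prov,
    sample.int(config$facilities_per_province, sum(away), replace = TRUE)
  )
  # one or two test records per visit
  n_tests <- 1L + (runif(nv) < 0.3)
  hiv <- visit[rep.int(seq_len(nv), n_tests), ]
  hiv$visit_idx <- rep.int(seq_len(nv), n_tests)
  second <- duplicated(hiv$visit_idx)
  nh <- nrow(hiv)
  test_types <- c("CD4 count", "CD4 percentage", "rapid test", "qualitative PCR",
                  "antibody", "antigen")
  hiv$test_type <- test_types[sample.int(6, nh, replace = TRUE,
                                         prob = c(0.50, 0.05, 0.25, 0.08, 0.08, 0.04))]
  hiv$test_type[second] <- "CD4 percentage"
  hiv$result_label <- hiv_result_labels()[sample.int(3, nh, replace = TRUE,
                                                     prob = config$hiv_result_label_weights)]

  ## ---- cancer reports ----
  has_cancer <- runif(n) < config$cancer_fraction
  cn <- entities[has_cancer, ]
  nc <- nrow(cn)
  cancer <- NULL
  if (nc > 0) {
    cn$cancer_type <- cancer_type_labels()[sample.int(
      length(cancer_type_labels()), nc, replace = TRUE,
      prob = config$cancer_type_weights
    )]
    two <- runif(nc) < config$second_report_rate
    cancer <- cn[rep.int(seq_len(nc), 1L + two), ]
    first_rep <- !duplicated(cancer$entity_id)
    nr <- nrow(cancer)
    d1 <- window[1] + round(runif(nc) * span)
    cancer$diagnosis_date <- d1[match(cancer$entity_id, cn$entity_id)]
    cancer$diagnosis_date[!first_rep] <- pmin(
      cancer$diagnosis_date[!first_rep] + 30 + round(runif(sum(!first_rep)) * 335),
      window[2]
    )
    home_idx <- match(cancer$home_province, province_codes())
    diag_idx <- vapply(home_idx, function(i) {
      sample.int(9, 1, prob = config$mobility[i, ])
    }, integer(1))
    cancer$diagnosis_province <- province_codes()[diag_idx]
    cancer$facility_id <- sprintf(
      "%s-%02d", cancer$diagnosis_province,
      sample.int(config$facilities_per_province, nr, replace = TRUE)
    )
    # pathology at the HIV home facility when diagnosed at home, half the time
    at_home <- cancer$diagnosis_province == cancer$home_province & runif(nr) < 0.5
    cancer$facility_id[at_home] <- cancer$home_facility[at_home]
    cancer$basis <- c("histology", "cytology", "bone-marrow")[sample.int(
      3, nr, replace = TRUE, prob = c(0.85, 0.12, 0.03)
    )]
    cancer$diagnosis_province[runif(nr) < config$missing_diagnosis_province_rate] <-
      NA_character_
  }

  ## ---- facility-scoped episode and folder serials (shared registry) ----
  reg <- dplyr::bind_rows(
    tibble::tibble(src = "H", entity_id = hiv$entity_id, facility = hiv$facility_id,
                   date = hiv$test_date, visit = hiv$visit_idx),
    if (nc > 0) tibble::tibble(src = "C", entity_id = cancer$entity_id,
                               facility = cancer$facility_id,
                               date = cancer$diagnosis_date,
                               visit = -seq_len(nrow(cancer)))
  )
  fac_f <- factor(reg$facility)
  folder_key <- paste(reg$facility, reg$entity_id)
  reg$folder_number <- sprintf(
    "%s-F%04d", reg$facility,
    stats::ave(as.integer(factor(folder_key)), fac_f,
               FUN = function(x) match(x, unique(x)))
  )
  episode_key <- paste(reg$facility, reg$entity_id, reg$visit)
  reg$episode_number <- sprintf(
    "%s-E%05d", reg$facility,
    stats::ave(as.integer(factor(episode_key)), fac_f,
               FUN = function(x) match(x, unique(x)))
  )
  is_h <- reg$src == "H"
  hiv$episode_number <- reg$episode_number[is_h]
  hiv$folder_number <- reg$folder_number[is_h]
  if (nc > 0) {
    cancer$episode_number <- reg$episode_number[!is_h]
    cancer$folder_number <- reg$folder_number[!is_h]
  }

  ## ---- assemble, corrupt, finalise ----
  first_bank <- load_name_bank("first")
  hiv <- corrupt_identity_(hiv, config, first_bank)
  hiv$age <- floor(as.numeric(hiv$test_date -
                                entities$dob[hiv$entity_id]) / 365.25)
  hiv <- tibble::tibble(
    record_id = sprintf("H%07d", seq_len(nh)),
    entity_id = hiv$entity_id,
    first_name = hiv$first_name, surname = hiv$surname,
    sex = hiv$sex, race = hiv$race,
    dob = hiv$dob, age = hiv$age,
    episode_number = hiv$episode_number, folder_number = hiv$folder_number,
    test_type = hiv$test_type, result_label = hiv$result_label,
    facility_id = hiv$facility_id, province = hiv$province,
    test_date = hiv$test_date
  )

  if (nc > 0) {
    cancer <- corrupt_identity_(cancer, config, first_bank)
    cancer$age <- floor(as.numeric(cancer$diagnosis_date -
                                     entities$dob[cancer$entity_id]) / 365.25)
    cancer <- tibble::tibble(
      record_id = sprintf("C%07d", seq_len(nrow(cancer))),
      entity_id = cancer$entity_id,
      first_name = cancer$first_name, surname = cancer$surname,
      sex = cancer$sex, race = cancer$race,
      dob = cancer$dob, age = cancer$age,
      episode_number = cancer$episode_number, folder_number = cancer$folder_number,
      cancer_type = cancer$cancer_type, basis = cancer$basis,
      facility_id = cancer$facility_id,
      diagnosis_province = cancer$diagnosis_province,
      diagnosis_date = cancer$diagnosis_date
    )
  } else {
    cancer <- tibble::tibble(
      record_id = character(), entity_id = integer(),
      first_name = character(), surname = character(),
      sex = character(), race = character(),
      dob = as.Date(character()), age = integer(),
      episode_number = character(), folder_number = character(),
      cancer_type = character(), basis = character(),
      facility_id = character(), diagnosis_province = character(),
      diagnosis_date = as.Date(character())
    )
  }

  truth <- dplyr::bind_rows(
    dplyr::select(hiv, "record_id", "entity_id"),
    dplyr::select(cancer, "record_id", "entity_id")
  )
  structure(
    list(entities = entities, hiv = hiv, cancer = cancer, truth = truth,
         config = config),
    class = "hcm_simulation"
  )
}

#' @export
print.hcm_simulation <- function(x, ...) {
  cat("<hcm_simulation>\n")
  cat("  entities:", nrow(x$entities), "\n")
  cat("  HIV records:", nrow(x$hiv), "\n")
  cat("  cancer records:", nrow(x$cancer), "\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes `hiv_records.csv`, `cancer_records.csv`, `truth.csv` (RFC 4180,
#' header rows; the ground-truth `entity_id` column is withheld from the
#' record files and only present in `truth.csv`) plus a JSON run manifest
#' with the configuration hash, seed and record counts.
#'
#' @param sim An `hcm_simulation`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "hcm_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::select(sim$hiv, -"entity_id"),
                   file.path(dir, "hiv_records.csv"), na = "")
  readr::write_csv(dplyr::select(sim$cancer, -"entity_id"),
                   file.path(dir, "cancer_records.csv"), na = "")
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "")
  manifest <- list(
    config_hash = config_hash(sim$config),
    seed = sim$config$seed,
    n_entities = nrow(sim$entities),
    n_hiv_records = nrow(sim$hiv),
    n_cancer_records = nrow(sim$cancer)
  )
  jsonlite::write_json(manifest, file.path(dir, "simulation_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
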