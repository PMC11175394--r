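#' Identifier corruption model
#'
#' Controls how person identifiers are degraded when laboratory records are
#' emitted. All rates are per-field probabilities in `[0, 1]`.
#'
#' @param typo_rate Probability that a name field receives one typographic
#'   edit.
#' @param typo_ops Named weights over the four edit operations
#'   `substitution`, `transposition`, `deletion`, `insertion`; normalised
#'   internally.
#' @param nickname_swap_rate Probability that the first name is replaced by
#'   an unrelated alias (models nickname/forename swaps that defeat string
#'   similarity entirely).
#' @param dob_error_rate Probability that the recorded date of birth has its
#'   day or month perturbed (the birth year is preserved).
#' @param dob_missing_rate Probability that the date of birth is absent and
#'   only an age at test is recorded.
#' @param identifier_missing_rate Probability that the episode or folder
#'   number is missing from a record.
#' @return An object of class `hcm_corruption` (a named list).
#' @export
corruption_model <- function(typo_rate = 0.05,
                             typo_ops = c(substitution = 0.4, transposition = 0.3,
                                          deletion = 0.15, insertion = 0.15),
                             nickname_swap_rate = 0.02,
                             dob_error_rate = 0.02,
                             dob_missing_rate = 0.02,
                             identifier_missing_rate = 0.10) {
  ops <- c("substitution", "transposition", "deletion", "insertion")
  if (!all(ops %in% names(typo_ops))) {
    stop("`typo_ops` must be named with: ", paste(ops, collapse = ", "), call. = FALSE)
  }
  typo_ops <- typo_ops[ops]
  if (any(typo_ops < 0) || sum(typo_ops) <= 0) {
    stop("`typo_ops` weights must be non-negative with positive sum", call. = FALSE)
  }
  rates <- c(typo_rate, nickname_swap_rate, dob_error_rate, dob_missing_rate,
             identifier_missing_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("corruption rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      typo_rate = typo_rate,
      typo_ops = typo_ops / sum(typo_ops),
      nickname_swap_rate = nickname_swap_rate,
      dob_error_rate = dob_error_rate,
      dob_missing_rate = dob_missing_rate,
      identifier_missing_rate = identifier_missing_rate
    ),
    class = "hcm_corruption"
  )
}

#' Mobility matrices
#'
#' A mobility matrix is a 9x9 row-stochastic matrix over the province codes:
#' row = home province (province of HIV care), column = province of cancer
#' diagnosis. `default_mobility()` is derived from the packaged printed
#' origin-destination counts (each HIV-care province's column, normalised);
#' `mobility_identity()` keeps every diagnosis in the home province;
#' `mobility_uniform_offdiag(mass)` puts `1 - mass` on the diagonal and
#' spreads `mass` evenly over the eight other provinces.
#'
#' @param mass Total off-diagonal probability mass per row, in `[0, 1]`.
#' @return A 9x9 numeric matrix with dimnames `province_codes()`.
#' @export
default_mobility <- function() {
  counts <- load_table2_counts()
  m <- t(as.matrix(counts[, -1]))  # rows become home province
  dimnames(m) <- list(province_codes(), province_codes())
  sweep(m, 1, rowSums(m), "/")
}

#' @rdname default_mobility
#' @export
mobility_identity <- function() {
  m <- diag(9)
  dimnames(m) <- list(province_codes(), province_codes())
  m
}

#' @rdname default_mobility
#' @export
mobility_uniform_offdiag <- function(mass = 0.25) {
  stopifnot(mass >= 0, mass <= 1)
  m <- matrix(mass / 8, 9, 9, dimnames = list(province_codes(), province_codes()))
  diag(m) <- 1 - mass
  m
}

default_province_weights <- function() {
  counts <- load_table2_counts()
  cs <- colSums(as.matrix(counts[, -1]))
  setNames(cs / sum(cs), province_codes())
}

default_cancer_type_weights <- function() {
  labs <- cancer_type_labels()
  w <- setNames(rep(0.25 / 15, length(labs)), labs)
  w[c("cervix", "breast", "other", "Kaposi sarcoma", "non-Hodgkin lymphoma")] <-
    c(0.28, 0.10, 0.14, 0.16, 0.07)
  w / sum(w)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic record generator. Defaults are
#' the package's standard study conditions: demographic and province
#' margins follow the printed study tables, the mobility matrix is the
#' column-normalised printed origin-destination table, and noise levels are
#' modest registry-style corruption (see the methods vignette).
#'
#' @param n_entities Number of simulated persons.
#' @param seed Integer seed; the same configuration and seed reproduce
#'   byte-identical outputs.
#' @param hiv_records_extra_mean Mean of the Poisson number of HIV records
#'   beyond the guaranteed first one (records per person = 1 + Poisson).
#' @param corruption An [corruption_model()] object.
#' @param province_weights Probability vector over the nine provinces
#'   (home-province distribution).
#' @param mobility 9x9 row-stochastic matrix, rows = home province,
#'   columns = province of cancer diagnosis.
#' @param away_record_rate Probability that an HIV record is drawn at a
#'   facility outside the home province (exercises modal home-province
#'   logic).
#' @param female_fraction Probability that an entity is female.
#' @param race_weights Probability vector over Black, Coloured, White, Asian.
#' @param age_meanlog,age_sdlog Log-normal parameters of age (years) at the
#'   window midpoint.
#' @param cancer_fraction Probability that an entity has a pathology-
#'   confirmed cancer.
#' @param second_report_rate Probability that a cancer case has a second,
#'   later pathology report (exercises incident-cancer selection).
#' @param cancer_type_weights Probability vector over [cancer_type_labels()].
#' @param hiv_result_label_weights Probability vector over positive,
#'   negative, unknown.
#' @param missing_diagnosis_province_rate Probability that a cancer record
#'   lacks its province of diagnosis.
#' @param facilities_per_province Number of synthetic facilities per
#'   province.
#' @return An object of class `hcm_config`.
#' @export
sim_config <- function(n_entities = 5000,
                       seed = 1L,
                       hiv_records_extra_mean = 2,
                       corruption = corruption_model(),
                       province_weights = default_province_weights(),
                       mobility = default_mobility(),
                       away_record_rate = 0.05,
                       female_fraction = 0.709,
                       race_weights = c(Black = 0.8964, Coloured = 0.0501,
                                        White = 0.0475, Asian = 0.0060),
                       age_meanlog = log(40),
                       age_sdlog = 0.28,
                       cancer_fraction = 0.15,
                       second_report_rate = 0.10,
                       cancer_type_weights = default_cancer_type_weights(),
                       hiv_result_label_weights = c(positive = 0.7, negative = 0.2,
                                                    unknown = 0.1),
                       missing_diagnosis_province_rate = 0.02,
                       facilities_per_province = 25) {
  cfg <- structure(
    list(
      n_entities = as.integer(n_entities),
      seed = as.integer(seed),
      hiv_records_extra_mean = hiv_records_extra_mean,
      corruption = corruption,
      province_weights = province_weights / sum(province_weights),
      mobility = mobility,
      away_record_rate = away_record_rate,
      female_fraction = female_fraction,
      race_weights = race_weights / sum(race_weights),
      age_meanlog = age_meanlog,
      age_sdlog = age_sdlog,
      cancer_fraction = cancer_fraction,
      second_report_rate = second_report_rate,
      cancer_type_weights = cancer_type_weights / sum(cancer_type_weights),
      hiv_result_label_weights = hiv_result_label_weights / sum(hiv_result_label_weights),
      missing_diagnosis_province_rate = missing_diagnosis_province_rate,
      facilities_per_province = as.integer(facilities_per_province)
    ),
    class = "hcm_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks probability vectors (sum to one within 1e-9, entries in `[0, 1]`),
#' the row-stochastic mobility matrix, and scalar rates. Called by
#' [sim_config()]; exported so externally edited YAML configurations can be
#' checked.
#'
#' @param config An `hcm_config` object.
#' @return `config`, invisibly; errors describe the first violation found.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "hcm_config"))
  check_prob_vec <- function(x, what, labels = NULL) {
    if (!is.null(labels) && !identical(names(x), labels)) {
      stop(what, " must be named ", paste(labels, collapse = ", "), call. = FALSE)
    }
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  if (config$n_entities < 1) stop("n_entities must be positive", call. = FALSE)
  if (config$hiv_records_extra_mean < 0) stop("hiv_records_extra_mean must be >= 0", call. = FALSE)
  check_prob_vec(config$province_weights, "province_weights", province_codes())
  check_prob_vec(config$race_weights, "race_weights", race_labels())
  check_prob_vec(config$cancer_type_weights, "cancer_type_weights", cancer_type_labels())
  check_prob_vec(config$hiv_result_label_weights, "hiv_result_label_weights",
                 hiv_result_labels())
  m <- config$mobility
  if (!is.matrix(m) || !identical(dim(m), c(9L, 9L))) {
    stop("mobility must be a 9x9 matrix", call. = FALSE)
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("mobility rows must be non-negative and sum to 1", call. = FALSE)
  }
  rates <- c(config$away_record_rate, config$female_fraction, config$cancer_fraction,
             config$second_report_rate, config$missing_diagnosis_province_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  invisible(config)
}

#' Read and write YAML configurations
#'
#' A configuration round-trips through YAML: vectors keep their names and
#' the mobility matrix is stored as a named list of rows. Fields absent from
#' the file fall back to the [sim_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @param config An `hcm_config` object.
#' @return `read_config()` returns an `hcm_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar_fields <- c("n_entities", "seed", "hiv_records_extra_mean",
                     "away_record_rate", "female_fraction", "age_meanlog",
                     "age_sdlog", "cancer_fraction", "second_report_rate",
                     "missing_diagnosis_province_rate", "facilities_per_province")
  for (f in scalar_fields) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  vec_fields <- c("province_weights", "race_weights", "cancer_type_weights",
                  "hiv_result_label_weights")
  for (f in vec_fields) if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  if (!is.null(raw$mobility)) {
    m <- do.call(rbind, lapply(raw$mobility, unlist))
    rownames(m) <- names(raw$mobility)
    args$mobility <- m[province_codes(), province_codes()]
  }
  if (!is.null(raw$corruption)) {
    cargs <- raw$corruption
    if (!is.null(cargs$typo_ops)) cargs$typo_ops <- unlist(cargs$typo_ops)
    args$corruption <- do.call(corruption_model, cargs)
  }
  do.call(sim_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$corruption <- unclass(config$corruption)
  out$corruption$typo_ops <- as.list(config$corruption$typo_ops)
  out$province_weights <- as.list(config$province_weights)
  out$race_weights <- as.list(config$race_weights)
  out$cancer_type_weights <- as.list(config$cancer_type_weights)
  out$hiv_result_label_weights <- as.list(config$hiv_result_label_weights)
  out$mobility <- setNames(
    lapply(seq_len(9), function(i) as.list(setNames(config$mobility[i, ], province_codes()))),
    province_codes()
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' @param config An `hcm_config` object.
#' @return A character scalar hash, recorded in run manifests.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}
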