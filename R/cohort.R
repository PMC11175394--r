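#' Keep only HIV-positive laboratory records
#'
#' Records with result labels `negative` or `unknown` are removed; the
#' study population is defined by a documented positive HIV result.
#'
#' @param records Tibble with a `result_label` column.
#' @return The filtered tibble.
#' @export
filter_hiv_positive <- function(records) {
  dplyr::filter(records, .data$result_label == "positive")
}

#' Select the incident cancer report
#'
#' Among a person's pathology reports, the first (earliest diagnosis date)
#' defines the incident cancer; ties on the date break to the smallest
#' record id.
#'
#' @param records Tibble of one person's cancer records (`record_id`,
#'   `diagnosis_date`, ...).
#' @return The single incident-report row.
#' @export
incident_cancer <- function(records) {
  stopifnot(nrow(records) >= 1)
  records |>
    dplyr::arrange(.data$diagnosis_date, .data$record_id) |>
    dplyr::slice(1)
}

#' Temporal eligibility of a linked case
#'
#' A case is kept when the first HIV record date is on or before the cancer
#' diagnosis date: prevalent-HIV persons whose cancer was diagnosed before
#' any documented HIV care are excluded, while same-day HIV and cancer
#' dates are retained. A missing date fails the filter.
#'
#' @param hiv_first_date,cancer_diagnosis_date Date vectors.
#' @return Logical vector: keep (`TRUE`) or drop.
#' @export
temporal_filter <- function(hiv_first_date, cancer_diagnosis_date) {
  !is.na(hiv_first_date) & !is.na(cancer_diagnosis_date) &
    hiv_first_date <= cancer_diagnosis_date
}

#' Home province of a person's HIV records
#'
#' The modal province across the person's (positive) HIV records, used as
#' the residence proxy. Ties break to the province of the earliest record,
#' then alphabetically.
#'
#' @param records Tibble of one person's HIV records with `province` and
#'   `test_date`.
#' @return A single province code.
#' @export
home_province <- function(records) {
  stopifnot(nrow(records) >= 1)
  records |>
    dplyr::group_by(.data$province) |>
    dplyr::summarise(n = dplyr::n(), earliest = min(.data$test_date),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$earliest, .data$province) |>
    dplyr::pull("province") |>
    head(1)
}

mode_chr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' Build the analysis cohort from linked clusters
#'
#' Applies the eligibility filters to the linked data and emits one
#' analysis row per surviving person, together with an ordered attrition
#' log. Starting from the clusters linked to at least one cancer record:
#' clusters without any HIV-positive record are dropped first; then the
#' incident cancer report is selected per cluster and clusters whose
#' incident diagnosis precedes their first positive HIV record date (or
#' with a missing date) are dropped; finally clusters whose incident report
#' lacks a province of diagnosis are dropped. The home province is the
#' modal province of the positive HIV records (ties: earliest record, then
#' alphabetical); age at diagnosis is `floor()` of the years between date
#' of birth and diagnosis, falling back to the recorded age at the HIV test
#' nearest the diagnosis when no date of birth is available.
#'
#' @param hiv_std Standardized HIV records.
#' @param clusters Tibble `record_id`, `cluster_id` from [deduplicate()].
#' @param links Tibble from [link_cancer()].
#' @param cancer_std Standardized cancer records.
#' @return A list of class `hcm_cohort`: `cases` (one row per person:
#'   `cluster_id`, `sex`, `race`, `age_at_diagnosis`, `home_province`,
#'   `diagnosis_province`, `cancer_type`, `hiv_first_date`,
#'   `cancer_diagnosis_date`, `out_of_province`) and `attrition` (named
#'   counts in filter order).
#' @export
build_cases <- function(hiv_std, clusters, links, cancer_std) {
  hiv <- dplyr::inner_join(hiv_std, clusters, by = "record_id")
  linked_clusters <- unique(links$cluster_id)
  n_input <- length(linked_clusters)

  ## filter 1: a documented positive HIV result
  pos <- dplyr::filter(hiv, .data$cluster_id %in% linked_clusters,
                       .data$result_label == "positive")
  pos_clusters <- unique(pos$cluster_id)
  n_non_positive <- n_input - length(pos_clusters)

  ## per-cluster HIV summaries from positive records
  prov <- pos |>
    dplyr::group_by(.data$cluster_id, .data$province) |>
    dplyr::summarise(n = dplyr::n(), earliest = min(.data$test_date),
                     .groups = "drop_last") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$earliest, .data$province,
                   .by_group = TRUE) |>
    dplyr::summarise(home_province = dplyr::first(.data$province), .groups = "drop")
  hiv_summary <- pos |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      hiv_first_date = min(.data$test_date),
      sex = mode_chr(.data$sex),
      race = mode_chr(.data$race),
      dob = {
        d <- .data$dob[!is.na(.data$dob)]
        if (length(d)) as.Date(mode_chr(as.character(d))) else as.Date(NA)
      },
      .groups = "drop"
    ) |>
    dplyr::inner_join(prov, by = "cluster_id")

  ## incident cancer report per linked cluster
  incident <- links |>
    dplyr::filter(.data$cluster_id %in% pos_clusters) |>
    dplyr::inner_join(cancer_std, by = c(cancer_record_id = "record_id")) |>
    dplyr::arrange(.data$diagnosis_date, .data$cancer_record_id) |>
    dplyr::distinct(.data$cluster_id, .keep_all = TRUE)

  cases <- dplyr::inner_join(hiv_summary, incident, by = "cluster_id",
                             suffix = c("", "_cancer"))

  ## filter 2: HIV care on or before the cancer diagnosis
  keep_t <- temporal_filter(cases$hiv_first_date, cases$diagnosis_date)
  n_temporal <- sum(!keep_t)
  cases <- cases[keep_t, ]

  ## filter 3: province of cancer diagnosis documented
  miss_p <- is.na(cases$diagnosis_province)
  n_missing_province <- sum(miss_p)
  cases <- cases[!miss_p, ]

  ## age at diagnosis
  age_from_dob <- floor(as.numeric(cases$diagnosis_date - cases$dob) / 365.25)
  nearest_age <- cases$age  # recorded age on the incident cancer report
  if (any(is.na(age_from_dob))) {
    need <- which(is.na(age_from_dob))
    near <- dplyr::semi_join(pos, cases[need, "cluster_id"], by = "cluster_id") |>
      dplyr::inner_join(cases[need, c("cluster_id", "diagnosis_date")],
                        by = "cluster_id") |>
      dplyr::mutate(gap = abs(as.numeric(.data$test_date - .data$diagnosis_date))) |>
      dplyr::arrange(.data$gap) |>
      dplyr::distinct(.data$cluster_id, .keep_all = TRUE)
    nearest_age[need] <- near$age[match(cases$cluster_id[need], near$cluster_id)]
  }
  age_at_diagnosis <- dplyr::coalesce(age_from_dob, as.numeric(nearest_age))

  out <- tibble::tibble(
    cluster_id = cases$cluster_id,
    sex = cases$sex,
    race = cases$race,
    age_at_diagnosis = age_at_diagnosis,
    home_province = cases$home_province,
    diagnosis_province = cases$diagnosis_province,
    cancer_type = cases$cancer_type,
    hiv_first_date = cases$hiv_first_date,
    cancer_diagnosis_date = cases$diagnosis_date,
    out_of_province = cases$home_province != cases$diagnosis_province
  )
  structure(
    list(
      cases = out,
      attrition = c(
        input_clusters = n_input,
        dropped_non_positive = n_non_positive,
        dropped_temporal = n_temporal,
        dropped_missing_province = n_missing_province,
        final_cases = nrow(out)
      )
    ),
    class = "hcm_cohort"
  )
}

#' @export
print.hcm_cohort <- function(x, ...) {
  cat("<hcm_cohort>", x$attrition[["final_cases"]], "cases from",
      x$attrition[["input_clusters"]], "linked clusters\n")
  cat("  attrition:", paste(names(x$attrition), x$attrition, sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}
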