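#' Packaged printed-table fixtures
#'
#' The package ships the printed cell counts of the study's demographics
#' table ("table1") and province-of-cancer-diagnosis by province-of-HIV-care
#' table ("table2") as plain CSV. Only cells are stored; every total and
#' percentage is recomputed from them, because some printed marginal totals
#' are internally inconsistent with the printed cells.
#'
#' @return `load_table2_counts()`: a tibble with `diagnosis_province` and one
#'   count column per HIV-care province. `load_table1_counts()`: a tibble
#'   with `characteristic`, `level`, `outside`, `within`.
#' @export
load_table2_counts <- function() {
  path <- system.file("extdata", "table2_counts.csv", package = "hivcanmatch",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    diagnosis_province = readr::col_character(),
    .default = readr::col_integer()
  ))
}

#' @rdname load_table2_counts
#' @export
load_table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.csv", package = "hivcanmatch",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "ccii")
}

#' Recompute the printed analytical tables from packaged counts
#'
#' Rebuilds, from the packaged cell counts alone, everything the printed
#' tables derive from them: the origin-destination table with recomputed
#' row totals and column percentages, the per-destination shares of
#' out-of-province diagnoses, and the demographics table with row
#' percentages. Percentages use half-away-from-zero rounding to one
#' decimal, the convention that reproduces every internally consistent
#' printed percentage exactly.
#'
#' @return A list with elements `od` (an `hcm_od_matrix`), `od_table`
#'   (formatted tibble of counts with column percentages),
#'   `destination_shares`, and `demographics` (tibble with recomputed row
#'   percentages).
#' @export
reproduce_printed_tables <- function() {
  t2 <- load_table2_counts()
  counts <- as.matrix(t2[, -1])
  rownames(counts) <- t2$diagnosis_province
  od <- new_od_matrix(counts)
  t1 <- load_table1_counts()
  demo <- dplyr::mutate(
    t1,
    total = .data$outside + .data$within,
    pct_outside = round_half_up(100 * .data$outside / .data$total, 1),
    pct_within = round_half_up(100 * .data$within / .data$total, 1)
  )
  list(
    od = od,
    od_table = od_format(od),
    destination_shares = destination_shares(od),
    demographics = demo
  )
}

load_name_bank <- function(which = c("first", "surname")) {
  which <- match.arg(which)
  file <- if (which == "first") "synthetic_first_names.txt" else "synthetic_surnames.txt"
  readLines(system.file("extdata", file, package = "hivcanmatch", mustWork = TRUE))
}
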