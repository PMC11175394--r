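#' Round half away from zero
#'
#' Registry tables round percentages half away from zero (so 26.25 prints
#' as 26.3), unlike R's banker's rounding; this rule reproduces every
#' internally consistent printed percentage in the packaged fixtures.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

new_od_matrix <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 9, ncol(counts) == 9,
            all(counts >= 0))
  dimnames(counts) <- list(diagnosis_province = province_codes(),
                           hiv_province = province_codes())
  col_sums <- colSums(counts)
  col_pct <- sweep(counts, 2, ifelse(col_sums == 0, NA, col_sums), "/") * 100
  structure(
    list(counts = counts,
         row_totals = rowSums(counts),
         col_totals = col_sums,
         col_pct = round_half_up(col_pct, 1),
         n = sum(counts)),
    class = "hcm_od_matrix"
  )
}

#' Origin-destination matrix of cancer diagnoses
#'
#' Cross-tabulates the analysis cohort as rows = province of cancer
#' diagnosis, columns = province of HIV care (the printed layout), with
#' column percentages: each cell over its column's cell sum, rounded half
#' away from zero to one decimal. A column percentage reads "of this
#' province's HIV patients, where were their cancers diagnosed". Totals are
#' always recomputed from cells.
#'
#' @param cases A case tibble (see [build_cases()]) with `home_province`
#'   and `diagnosis_province`; unknown province codes are an error.
#' @return An object of class `hcm_od_matrix` with elements `counts`,
#'   `row_totals`, `col_totals`, `col_pct`, `n`.
#' @export
od_matrix <- function(cases) {
  pcs <- province_codes()
  bad <- setdiff(unique(c(cases$home_province, cases$diagnosis_province)), pcs)
  if (length(bad) > 0) {
    stop("unknown province code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(cases$diagnosis_province, levels = pcs),
                  factor(cases$home_province, levels = pcs))
  new_od_matrix(unclass(as.matrix(counts)))
}

#' @export
print.hcm_od_matrix <- function(x, ...) {
  cat("<hcm_od_matrix>", x$n, "cases; rows = diagnosis province, columns = HIV province\n")
  print(x$counts)
  invisible(x)
}

#' Format an origin-destination matrix as a printable table
#'
#' @param od An `hcm_od_matrix`.
#' @return A tibble, one row per diagnosis province, cells formatted as
#'   `"count (pct%)"` with a recomputed `row_total` column.
#' @export
od_format <- function(od) {
  stopifnot(inherits(od, "hcm_od_matrix"))
  cells <- matrix(
    sprintf("%s (%.1f%%)", format(od$counts, trim = TRUE, big.mark = ","),
            od$col_pct),
    9, 9, dimnames = dimnames(od$counts)
  )
  out <- tibble::as_tibble(cells)
  dplyr::bind_cols(
    tibble::tibble(diagnosis_province = province_codes()),
    out,
    tibble::tibble(row_total = unname(od$row_totals))
  )
}

#' Destination shares of out-of-province diagnoses
#'
#' For each diagnosis province, the share of all out-of-province cases it
#' received: its off-diagonal row sum over the total off-diagonal count.
#' When every case is on the diagonal the shares are undefined and `NA`.
#'
#' @param od An `hcm_od_matrix`.
#' @return A tibble `diagnosis_province`, `n_received`, `share`.
#' @export
destination_shares <- function(od) {
  stopifnot(inherits(od, "hcm_od_matrix"))
  m <- od$counts
  offdiag <- m
  diag(offdiag) <- 0L
  total <- sum(offdiag)
  tibble::tibble(
    diagnosis_province = province_codes(),
    n_received = unname(rowSums(offdiag)),
    share = if (total == 0) NA_real_ else unname(rowSums(offdiag)) / total
  )
}

#' Demographics table of the analysis cohort
#'
#' Summarises the cohort by location of cancer diagnosis (outside vs within
#' the province of HIV care): counts and row percentages (one decimal,
#' half-away-from-zero) for gender, ethnicity and Black vs non-Black, plus
#' the age median and interquartile range (Tukey hinges) overall and by
#' location.
#'
#' @param cases A non-empty case tibble from [build_cases()].
#' @return An object of class `hcm_demographics`: `table` (characteristic,
#'   level, outside, within, total, pct_outside, pct_within) and `age`
#'   (median/IQR by location and overall).
#' @export
demographics_table <- function(cases) {
  stopifnot(nrow(cases) > 0)
  row_of <- function(characteristic, level, sel) {
    outside <- sum(sel & cases$out_of_province)
    within <- sum(sel & !cases$out_of_province)
    tibble::tibble(
      characteristic = characteristic, level = level,
      outside = outside, within = within, total = outside + within,
      pct_outside = round_half_up(100 * outside / (outside + within), 1),
      pct_within = round_half_up(100 * within / (outside + within), 1)
    )
  }
  tab <- dplyr::bind_rows(
    row_of("total", "All", rep(TRUE, nrow(cases))),
    row_of("gender", "Female", cases$sex == "F"),
    row_of("gender", "Male", cases$sex == "M"),
    purrr::map_dfr(race_labels(), function(r) {
      row_of("ethnicity", r, cases$race == r)
    }),
    row_of("black_vs_nonblack", "Black", cases$race == "Black"),
    row_of("black_vs_nonblack", "non-Black", cases$race != "Black")
  )
  age_summary <- function(x) {
    h <- fivenum(x)
    tibble::tibble(median = h[3], q1 = h[2], q3 = h[4])
  }
  age <- dplyr::bind_rows(
    dplyr::mutate(age_summary(cases$age_at_diagnosis), group = "all"),
    dplyr::mutate(age_summary(cases$age_at_diagnosis[cases$out_of_province]),
                  group = "outside"),
    dplyr::mutate(age_summary(cases$age_at_diagnosis[!cases$out_of_province]),
                  group = "within")
  )
  structure(list(table = tab, age = age[, c("group", "median", "q1", "q3")]),
            class = "hcm_demographics")
}

#' @export
print.hcm_demographics <- function(x, ...) {
  cat("<hcm_demographics>\n")
  print(x$table, n = Inf)
  print(x$age)
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' The Pearson statistic `sum((O - E)^2 / E)` without continuity
#' correction, `df = (r - 1)(c - 1)`, p-value from the upper chi-square
#' tail. A zero expected count is an error.
#'
#' @param contingency An r x c matrix (or table) of counts.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(contingency) {
  x <- as.matrix(contingency)
  stopifnot(all(x >= 0), nrow(x) >= 2, ncol(x) >= 2)
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  if (any(expected == 0)) {
    stop("chi-square requires all expected counts > 0", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(x, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}
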