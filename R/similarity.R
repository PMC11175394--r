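#' Jaro-Winkler string similarity
#'
#' The standard name comparator in record linkage: the Jaro similarity
#' boosted for agreeing prefixes (prefix weight `p = 0.1`, maximum prefix
#' length 4). Identical strings score 1; strings with no characters
#' matching inside the Jaro window score 0; the measure is symmetric.
#' Inputs are expected in canonical [normalize_name()] form. `NA` in either
#' position gives `NA`.
#'
#' @param x,y Character vectors of equal length (or length one, recycled).
#' @param p Prefix weight.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")  # 0.9611
#' @export
jaro_winkler <- function(x, y, p = 0.1) {
  n <- max(length(x), length(y))
  x <- rep_len(as.character(x), n)
  y <- rep_len(as.character(y), n)
  .jaro_winkler_cpp(x, y, p)
}

#' Build comparison vectors for candidate pairs
#'
#' For each candidate pair, computes the six bounded features fed to the
#' match classifier: Jaro-Winkler similarity of first names and surnames,
#' birth-year agreement `1 - min(|dy|, 5) / 5` (the "age or date of birth"
#' comparison, made on birth year so records taken years apart still
#' agree; a birth year derived from a recorded age is one of two candidate
#' years, and `dy` is the smallest discrepancy over the candidates), exact
#' date-of-birth equality, and episode- and folder-number equality. A missing name or birth year on either side encodes as the
#' uninformative midpoint 0.5, as does a missing episode/folder number;
#' a missing date of birth scores 0 on `dob_exact` (birth-year agreement
#' already carries the age signal). All features are symmetric under
#' argument swap.
#'
#' @param pairs A tibble with `record_id_a`, `record_id_b` (from
#'   [candidate_pairs()]).
#' @param a Standardized record tibble containing the `record_id_a` records.
#' @param b Standardized record tibble for `record_id_b`; defaults to `a`.
#' @return `pairs` with the six feature columns appended.
#' @export
compare_pairs <- function(pairs, a, b = NULL) {
  if (is.null(b)) b <- a
  cols <- c("record_id", "norm_first_name", "norm_surname", "dob",
            "birth_year", "episode_number", "folder_number")
  stopifnot(all(cols %in% names(a)), all(cols %in% names(b)))
  # column-at-a-time to keep peak memory low on multi-million-pair inputs
  ia <- match(pairs$record_id_a, a$record_id)
  ib <- match(pairs$record_id_b, b$record_id)

  sim_or_mid <- function(u, v) {
    s <- jaro_winkler(u, v)
    s[is.na(s)] <- 0.5
    s
  }
  eq_or_mid <- function(u, v) {
    out <- as.numeric(u == v)
    out[is.na(out)] <- 0.5
    out
  }
  ya <- a$birth_year[ia]; yb <- b$birth_year[ib]
  dy <- abs(ya - yb)
  ya_alt <- (a$birth_year_alt %||% rep(NA_integer_, nrow(a)))[ia]
  yb_alt <- (b$birth_year_alt %||% rep(NA_integer_, nrow(b)))[ib]
  dy <- pmin(dy, abs(ya_alt - yb), abs(ya - yb_alt), abs(ya_alt - yb_alt),
             na.rm = TRUE)
  dy[is.na(ya) & is.na(ya_alt) | is.na(yb) & is.na(yb_alt)] <- NA
  age_agreement <- 1 - pmin(dy, 5) / 5
  age_agreement[is.na(age_agreement)] <- 0.5
  dob_exact <- as.numeric(a$dob[ia] == b$dob[ib])
  dob_exact[is.na(dob_exact)] <- 0
  tibble::tibble(
    record_id_a = pairs$record_id_a,
    record_id_b = pairs$record_id_b,
    sim_first_name = sim_or_mid(a$norm_first_name[ia], b$norm_first_name[ib]),
    sim_surname = sim_or_mid(a$norm_surname[ia], b$norm_surname[ib]),
    age_agreement = age_agreement,
    dob_exact = dob_exact,
    episode_match = eq_or_mid(a$episode_number[ia], b$episode_number[ib]),
    folder_match = eq_or_mid(a$folder_number[ia], b$folder_number[ib])
  )
}

match_feature_names <- function() {
  c("sim_first_name", "sim_surname", "age_agreement", "dob_exact",
    "episode_match", "folder_match")
}
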