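#' Normalise a name string
#'
#' Canonical form used for all name comparisons: upper-case, diacritics
#' folded to ASCII, punctuation and digits removed, internal whitespace
#' collapsed to single spaces, leading/trailing space stripped. A string
#' that is empty after cleaning becomes `NA` (a missing-value marker, not
#' an error). The transformation is idempotent.
#'
#' @param raw Character vector.
#' @return Character vector of canonical names.
#' @export
normalize_name <- function(raw) {
  x <- toupper(as.character(raw))
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x <- stringr::str_replace_all(x, "[^A-Z ]", "")
  x <- stringr::str_squish(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' American Soundex phonetic code
#'
#' Classic four-character Soundex (letter + three digits) used to build
#' surname blocking keys: similar-sounding surnames map to the same code,
#' so a single typo rarely severs a true pair's block. Input is expected in
#' the canonical form produced by [normalize_name()]; internal spaces are
#' ignored. Missing or empty names give `NA`.
#'
#' @param name Character vector of canonical names.
#' @return Character vector of Soundex codes (e.g. `"R163"`).
#' @export
phonetic_code <- function(name) {
  x <- gsub(" ", "", name, fixed = TRUE)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  s <- x[ok]
  first <- substr(s, 1, 1)
  # H and W are transparent: codes on either side of them collapse
  body <- gsub("[HW]", "", s)
  digits <- chartr("BFPVCGJKQSXZDTLMNRAEIOUY",
                   "111122222222334556000000", body)
  digits <- gsub("(.)\\1+", "\\1", digits)   # collapse adjacent equal codes
  # the code of the (retained) first letter is dropped, unless the first
  # letter is H or W, which never enters the coded body at all
  strip <- !(first %in% c("H", "W"))
  digits[strip] <- sub("^.", "", digits[strip])
  digits <- gsub("0", "", digits)            # vowels separate but are not coded
  out[ok] <- paste0(first, substr(paste0(digits, "000"), 1, 3))
  out
}

#' Standardise a record set for linkage
#'
#' Adds the canonical-comparison columns to a laboratory record table:
#' `norm_first_name`, `norm_surname` (via [normalize_name()]),
#' `phonetic_surname` (via [phonetic_code()]), and `birth_year` (from the
#' date of birth when present, otherwise back-calculated from the recorded
#' age and the event date). An age-derived birth year is interval-censored
#' by the unknown birthday, so the alternative candidate year is kept in
#' `birth_year_alt` and also enters the blocking keys. Source columns are
#' passed through unchanged.
#'
#' @param records A tibble of HIV or cancer records (as produced by
#'   [simulate_records()] or read from CSV).
#' @param date_col Name of the event-date column used when birth year must
#'   be derived from age; defaults to `test_date` if present, else
#'   `diagnosis_date`.
#' @return The input tibble with the four added columns.
#' @export
standardize_records <- function(records, date_col = NULL) {
  if (is.null(date_col)) {
    date_col <- if ("test_date" %in% names(records)) "test_date" else "diagnosis_date"
  }
  stopifnot(date_col %in% names(records))
  event_year <- as.integer(format(records[[date_col]], "%Y"))
  dob_year <- as.integer(format(records$dob, "%Y"))
  birth_year <- dplyr::if_else(
    !is.na(dob_year), dob_year,
    event_year - as.integer(records$age)
  )
  birth_year_alt <- dplyr::if_else(
    is.na(dob_year) & !is.na(birth_year), birth_year - 1L, NA_integer_
  )
  dplyr::mutate(
    records,
    norm_first_name = normalize_name(.data$first_name),
    norm_surname = normalize_name(.data$surname),
    phonetic_surname = phonetic_code(normalize_name(.data$surname)),
    birth_year = birth_year,
    birth_year_alt = birth_year_alt
  )
}

#' Blocking keys for a standardized record set
#'
#' A record's key set is the union of: Soundex of the surname + birth year,
#' first two letters of the first name + birth year, and the episode number
#' when present; when the birth year was derived from a recorded age (and
#' is therefore ambiguous by one year), both candidate years contribute
#' keys. Two records are compared iff their key sets intersect; the
#' union-of-keys design means a single corrupted field cannot sever a true
#' pair.
#'
#' @param records A standardized record tibble (see [standardize_records()]).
#' @return A tibble with columns `record_id`, `key`.
#' @export
blocking_keys <- function(records) {
  stopifnot(all(c("record_id", "phonetic_surname", "norm_first_name",
                  "birth_year") %in% names(records)))
  k1 <- tibble::tibble(
    record_id = records$record_id,
    key = dplyr::if_else(
      is.na(records$phonetic_surname) | is.na(records$birth_year),
      NA_character_,
      paste0("S:", records$phonetic_surname, ":", records$birth_year)
    )
  )
  k2 <- tibble::tibble(
    record_id = records$record_id,
    key = dplyr::if_else(
      is.na(records$norm_first_name) | is.na(records$birth_year),
      NA_character_,
      paste0("F:", substr(records$norm_first_name, 1, 2), ":", records$birth_year)
    )
  )
  k3 <- tibble::tibble(
    record_id = records$record_id,
    key = dplyr::if_else(
      is.na(records$episode_number), NA_character_,
      paste0("E:", records$episode_number)
    )
  )
  keys <- list(k1, k2, k3)
  alt <- !is.na(records$birth_year_alt %||% rep(NA_integer_, nrow(records)))
  if (any(alt)) {
    keys <- c(keys, list(
      tibble::tibble(
        record_id = records$record_id[alt],
        key = dplyr::if_else(
          is.na(records$phonetic_surname[alt]), NA_character_,
          paste0("S:", records$phonetic_surname[alt], ":",
                 records$birth_year_alt[alt])
        )
      ),
      tibble::tibble(
        record_id = records$record_id[alt],
        key = dplyr::if_else(
          is.na(records$norm_first_name[alt]), NA_character_,
          paste0("F:", substr(records$norm_first_name[alt], 1, 2), ":",
                 records$birth_year_alt[alt])
        )
      )
    ))
  }
  dplyr::distinct(dplyr::filter(dplyr::bind_rows(keys), !is.na(.data$key)))
}

#' Candidate record pairs from blocking
#'
#' Within one record set (`b = NULL`, deduplication) returns each unordered
#' pair of distinct records sharing at least one blocking key; across two
#' record sets returns each (a, b) pair sharing a key. Pair order within a
#' set is canonical (`record_id_a < record_id_b`), and each pair appears
#' once however many keys it shares.
#'
#' @param a,b Standardized record tibbles; `b = NULL` for within-set pairs.
#' @return A tibble with columns `record_id_a`, `record_id_b`.
#' @export
candidate_pairs <- function(a, b = NULL) {
  ka <- blocking_keys(a)
  if (is.null(b)) {
    ids <- sort(unique(a$record_id))
    ia <- tibble::tibble(key = ka$key, idx = match(ka$record_id, ids))
    joined <- dplyr::inner_join(ia, ia, by = "key", suffix = c("_a", "_b"),
                                relationship = "many-to-many")
    pa <- pmin(joined$idx_a, joined$idx_b)
    pb <- pmax(joined$idx_a, joined$idx_b)
    keep <- pa < pb
    pa <- pa[keep]; pb <- pb[keep]
    dup <- duplicated(pa * (length(ids) + 1) + pb)
    tibble::tibble(record_id_a = ids[pa[!dup]], record_id_b = ids[pb[!dup]])
  } else {
    kb <- blocking_keys(b)
    idsa <- sort(unique(a$record_id))
    idsb <- sort(unique(b$record_id))
    ia <- tibble::tibble(key = ka$key, idx = match(ka$record_id, idsa))
    ib <- tibble::tibble(key = kb$key, idx = match(kb$record_id, idsb))
    joined <- dplyr::inner_join(ia, ib, by = "key", suffix = c("_a", "_b"),
                                relationship = "many-to-many")
    dup <- duplicated(joined$idx_a * (length(idsb) + 1) + joined$idx_b)
    tibble::tibble(record_id_a = idsa[joined$idx_a[!dup]],
                   record_id_b = idsb[joined$idx_b[!dup]])
  }
}
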