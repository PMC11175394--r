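#' South African province codes
#'
#' The nine provinces, coded as in national laboratory and cancer-registry
#' data: Eastern Cape (EC), Free State (FS), Gauteng (GAU), KwaZulu-Natal
#' (KZN), Limpopo (LIM), Mpumalanga (MPU), North West (NW), Northern Cape
#' (NC), Western Cape (WC).
#'
#' @return Character vector of the nine province codes, in canonical order.
#' @export
province_codes <- function() {
  c("EC", "FS", "GAU", "KZN", "LIM", "MPU", "NW", "NC", "WC")
}

#' Approximate province centroids
#'
#' Longitude/latitude of an interior point of each province, used to anchor
#' origin-destination flow lines. Coordinates are approximate (suitable for
#' schematic flow maps, not for geodesy).
#'
#' @return A tibble with columns `province`, `lon`, `lat`.
#' @export
province_centroids <- function() {
  tibble::tibble(
    province = province_codes(),
    lon = c(26.5, 26.8, 28.1, 30.9, 29.5, 30.3, 25.6, 21.5, 20.4),
    lat = c(-32.2, -28.9, -26.0, -28.9, -23.9, -25.8, -26.7, -29.7, -33.2)
  )
}

#' Cancer type labels
#'
#' The cancer-type vocabulary used throughout the package: the site labels
#' reported in province-of-diagnosis odds-ratio tables, plus the two
#' high-volume screening-detected sites in women (cervix, breast) and a
#' residual "other" class.
#'
#' @return Character vector of 20 labels.
#' @export
cancer_type_labels <- function() {
  c(
    "cervix", "breast", "other",
    "BCC", "bladder", "bone", "Burkitt lymphoma", "Hodgkin lymphoma",
    "Kaposi sarcoma", "kidney", "melanoma", "mesothelioma",
    "non-Hodgkin lymphoma", "pancreas", "prostate", "skin other",
    "stomach", "testis", "thyroid", "tongue"
  )
}

race_labels <- function() c("Black", "Coloured", "White", "Asian")

hiv_result_labels <- function() c("positive", "negative", "unknown")

#' Study window
#'
#' The fixed observation window for all generated laboratory events:
#' 2004-01-01 through 2014-12-31.
#'
#' @return A Date vector of length two (start, end).
#' @export
study_window <- function() {
  as.Date(c("2004-01-01", "2014-12-31"))
}
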