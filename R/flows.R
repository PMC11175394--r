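#' Extract out-of-province diagnosis flows
#'
#' One flow per off-diagonal cell with a positive count: origin = province
#' of HIV care, destination = province of cancer diagnosis, with centroid
#' coordinates attached for mapping. A province missing from the centroid
#' lookup is an error.
#'
#' @param od An `hcm_od_matrix`.
#' @param centroids Tibble `province`, `lon`, `lat`; defaults to the
#'   packaged approximate centroids.
#' @return A tibble of class `hcm_flows`: `origin`, `destination`, `count`,
#'   `origin_lon`, `origin_lat`, `dest_lon`, `dest_lat`.
#' @export
export_flows <- function(od, centroids = province_centroids()) {
  stopifnot(inherits(od, "hcm_od_matrix"))
  missing_p <- setdiff(province_codes(), centroids$province)
  if (length(missing_p) > 0) {
    stop("missing centroid for: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  m <- od$counts
  idx <- which(m > 0 & row(m) != col(m), arr.ind = TRUE)
  flows <- tibble::tibble(
    origin = province_codes()[idx[, 2]],       # HIV-care province (column)
    destination = province_codes()[idx[, 1]],  # diagnosis province (row)
    count = as.integer(m[idx])
  ) |>
    dplyr::arrange(dplyr::desc(.data$count)) |>
    dplyr::left_join(
      dplyr::rename(centroids, origin_lon = "lon", origin_lat = "lat"),
      by = c(origin = "province")
    ) |>
    dplyr::left_join(
      dplyr::rename(centroids, dest_lon = "lon", dest_lat = "lat"),
      by = c(destination = "province")
    )
  class(flows) <- c("hcm_flows", class(flows))
  flows
}

#' Write flows as GeoJSON
#'
#' Each flow becomes a LineString feature from the origin centroid to the
#' destination centroid with `origin`, `destination` and `count`
#' properties, suitable for any GeoJSON-aware mapping tool.
#'
#' @param flows An `hcm_flows` tibble from [export_flows()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flows_geojson <- function(flows, path) {
  features <- purrr::pmap(flows, function(origin, destination, count,
                                          origin_lon, origin_lat,
                                          dest_lon, dest_lat, ...) {
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(c(origin_lon, origin_lat), c(dest_lon, dest_lat))
      ),
      properties = list(origin = origin, destination = destination,
                        count = count)
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
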