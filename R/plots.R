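#' Plot an origin-destination matrix as a heatmap
#'
#' Tile heatmap of column percentages (where each HIV-care province's
#' patients obtained their cancer diagnoses), annotated with counts.
#'
#' @param object An `hcm_od_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcm_od_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$counts), .name_repair = "minimal")
  names(df) <- c("diagnosis_province", "hiv_province", "count")
  df$pct <- as.vector(object$col_pct)
  df$diagnosis_province <- factor(df$diagnosis_province,
                                  levels = rev(province_codes()))
  df$hiv_province <- factor(df$hiv_province, levels = province_codes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hiv_province,
                                   y = .data$diagnosis_province,
                                   fill = .data$pct)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 name = "column %") +
    ggplot2::labs(x = "Province of HIV care",
                  y = "Province of cancer diagnosis") +
    ggplot2::theme_minimal()
}

#' Plot out-of-province flows as a schematic map
#'
#' Straight-line flows between province centroids, line width proportional
#' to the number of patients; a lightweight stand-in for a choropleth flow
#' map.
#'
#' @param object An `hcm_flows` tibble from [export_flows()].
#' @param min_count Hide flows below this count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcm_flows <- function(object, min_count = 1, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$count >= min_count)
  cent <- province_centroids()
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$origin_lon, y = .data$origin_lat,
                   xend = .data$dest_lon, yend = .data$dest_lat,
                   linewidth = .data$count, colour = .data$destination),
      alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(data = cent, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_text(data = cent,
                       ggplot2::aes(x = .data$lon, y = .data$lat,
                                    label = .data$province),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 3)) +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  linewidth = "patients", colour = "diagnosed in") +
    ggplot2::theme_minimal()
}

#' Plot cohort attrition
#'
#' Bar chart of the ordered eligibility-filter attrition counts.
#'
#' @param object An `hcm_cohort` from [build_cases()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcm_cohort <- function(object, ...) {
  a <- object$attrition
  df <- tibble::tibble(
    stage = factor(names(a), levels = names(a)),
    count = as.integer(a)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "clusters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
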