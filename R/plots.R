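#' @importFrom rlang .data
NULL

# long tibble of polygon ring vertices for ggplot2
geometry_fortify <- function(areas) {
  purrr::map_dfr(seq_len(nrow(areas)), function(i) {
    purrr::map_dfr(seq_along(areas$geometry[[i]]), function(pp) {
      part <- areas$geometry[[i]][[pp]]
      purrr::map_dfr(seq_along(part), function(rr) {
        ring <- part[[rr]]
        tibble::tibble(
          area_id = areas$area_id[i],
          piece = paste(areas$area_id[i], pp, rr, sep = "."),
          x = ring[, 1], y = ring[, 2]
        )
      })
    })
  })
}

#' Choropleth of a per-area variable
#'
#' @param areas an [area_table()].
#' @param fill name of the column (in `areas` or in `data`) to map to fill.
#' @param data optional tibble with `area_id` plus the fill column (e.g. a
#'   rate table or LISA result), joined onto the areas.
#' @return a ggplot.
#' @export
plot_areas <- function(areas, fill, data = NULL) {
  df <- geometry_fortify(areas)
  values <- if (is.null(data)) {
    tibble::tibble(area_id = areas$area_id, value = areas[[fill]])
  } else {
    tibble::tibble(area_id = data$area_id, value = data[[fill]])
  }
  df <- dplyr::left_join(df, values, by = "area_id")
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         group = .data$piece,
                                         fill = .data$value)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = fill)
  if (is.numeric(values$value)) gg <- gg + ggplot2::scale_fill_viridis_c()
  gg
}

#' Plot a LISA cluster map
#' @param object a [local_moran()] result.
#' @param areas the matching [area_table()].
#' @param ... unused.
#' @return a ggplot with the conventional HH/LL/LH/HL colouring.
#' @export
autoplot.local_moran_tbl <- function(object, areas, ...) {
  plot_areas(areas, "quadrant", data = object) +
    ggplot2::scale_fill_manual(values = c(
      HH = "#d7191c", LL = "#2c7bb6", HL = "#fdae61", LH = "#abd9e9",
      `not-significant` = "grey85"
    )) +
    ggplot2::labs(fill = "LISA cluster")
}

#' Plot a scan result as ranked space-time windows
#' @param object a `scan_result`.
#' @param ... unused.
#' @return a ggplot timeline of cluster windows sized by relative risk.
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- cluster_report(object)
  if (!nrow(df)) abort("no clusters to plot")
  ggplot2::ggplot(df, ggplot2::aes(y = factor(.data$rank))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$year_start - 0.45,
                                       xend = .data$year_end + 0.45,
                                       yend = factor(.data$rank),
                                       linewidth = .data$rr,
                                       colour = .data$p <= 0.05)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "year", y = "cluster rank", linewidth = "RR",
                  colour = "p ≤ 0.05")
}

#' Map a local coefficient or pseudo-t surface
#' @param fit a `gwr_fit` or `mgwr_fit`.
#' @param areas the matching [area_table()] (rows aligned with the fit).
#' @param term model term to map.
#' @param what `"estimate"`, `"pseudo_t"` or `"local_r2"`.
#' @return a ggplot choropleth.
#' @export
plot_coefficients <- function(fit, areas, term = fit$terms[2],
                              what = c("estimate", "pseudo_t", "local_r2")) {
  what <- match.arg(what)
  td <- tidy(fit)
  td <- td[td$term == term, ]
  plot_areas(areas, what, data = td) +
    ggplot2::labs(title = paste0(term, " (", what, ")"))
}
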