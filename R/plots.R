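# ggplot2 views of the main result types.

poly_to_df <- function(p, name) {
  if (length(p) == 0) return(NULL)
  bind_rows(lapply(seq_along(p), function(i) {
    tibble(x = p[[i]]$x, y = p[[i]]$y,
           ring = paste0(name, "-", i), region = name)
  }))
}

#' Plot the MPA analysis regions
#'
#' @param regions A `region_set` from [build_regions()].
#' @return A ggplot object (planar coordinates, metres from the radar).
#' @export
plot_regions <- function(regions) {
  df <- bind_rows(
    poly_to_df(regions$polys$inner, "inner"),
    poly_to_df(regions$polys$boundary, "boundary"),
    poly_to_df(regions$polys$outer, "outer"),
    poly_to_df(regions$polys$full_range, "full_range")
  )
  df$region <- factor(df$region,
                      levels = c("full_range", "outer", "boundary", "inner"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$ring,
                                   fill = .data$region)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2, alpha = 0.7) +
    ggplot2::scale_fill_manual(values = c(
      full_range = "grey95", outer = "#4575b4",
      boundary = "#fee090", inner = "#d73027")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "East of radar (m)", y = "North of radar (m)",
                  fill = "Region") +
    ggplot2::theme_minimal()
}

#' @rdname plot_regions
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.region_set <- function(object, ...) plot_regions(object)

#' Plot gridded track hours
#'
#' Renders a [grid_rollup()] result as a filled lattice, one facet per
#' activity category, shading by (optionally min-max normalised) track
#' hours.
#'
#' @param grid_hours Output of [grid_rollup()].
#' @param grid The `activity_grid` used.
#' @param value Column to shade by (`"track_hours"` or `"relative"`).
#' @return A ggplot object.
#' @export
plot_grid_hours <- function(grid_hours, grid, value = "track_hours") {
  cells <- grid$cells |>
    mutate(cx = grid$origin["x"] + (.data$col - 0.5) * grid$cell_size_m,
           cy = grid$origin["y"] + (.data$row - 0.5) * grid$cell_size_m)
  df <- grid_hours |>
    left_join(cells, by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cx, y = .data$cy,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile(width = grid$cell_size_m, height = grid$cell_size_m) +
    ggplot2::scale_fill_gradient(low = "#313695", high = "#a50026") +
    ggplot2::facet_wrap(~category) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "East of radar (m)", y = "North of radar (m)",
                  fill = value) +
    ggplot2::theme_minimal()
}

#' Plot daily activity records over time
#'
#' Daily hours per km² by region for one activity category, with a 7-day
#' running mean.
#'
#' @param records Normalised daily records ([normalize_by_area()]).
#' @param category Activity category to display.
#' @param regions_shown Regions to include.
#' @return A ggplot object.
#' @export
plot_daily_activity <- function(records, category = "focal",
                                regions_shown = c("inner", "boundary", "outer")) {
  df <- records |>
    filter(.data$category == !!category,
           .data$region %in% regions_shown) |>
    group_by(.data$region) |>
    arrange(.data$date, .by_group = TRUE) |>
    mutate(smooth = stats::filter(.data$hours_per_km2, rep(1 / 7, 7),
                                  sides = 2)) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$hours_per_km2,
                                   colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(
      inner = "#d73027", boundary = "#fdae61", outer = "#4575b4")) +
    ggplot2::labs(x = NULL, y = "Daily hours per km²",
                  colour = "Region", title = paste(category, "activity")) +
    ggplot2::theme_minimal()
}
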