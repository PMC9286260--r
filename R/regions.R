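#' Build MPA analysis regions for a site
#'
#' Partitions the monitored water around the MPA into the analysis regions:
#' the *vicinity* (MPA interior plus an outward buffer, default 1 km), the
#' *boundary* region (a band centred on the MPA boundary line, default
#' 200 m wide, i.e. 100 m each side), and the *inner* and *outer* remainders
#' inside/outside the MPA. Everything is intersected with the *full range* —
#' the detection-range disc minus any exclusion polygons. Buffers use round
#' joins.
#'
#' @param site A [site_geometry()] object.
#' @param vicinity_buffer_m Outward buffer distance around the MPA, metres.
#' @param boundary_halfwidth_m Half-width of the boundary band, metres
#'   (100 m gives the 200-m band).
#' @return A `region_set`: polygons (planar, radar-centred) for
#'   `full_range`, `vicinity`, `inner`, `boundary`, `outer`, and an `areas`
#'   tibble in km² that additionally includes `outside_vicinity`
#'   (full range minus vicinity).
#' @export
build_regions <- function(site, vicinity_buffer_m = 1000,
                          boundary_halfwidth_m = 100) {
  stopifnot(is_site_geometry(site))
  full_range <- disc_poly(site$detection_range_m)
  excl <- .site_exclusions_planar(site)
  if (!poly_empty(excl)) full_range <- poly_op(full_range, excl, "minus")

  mpa <- .site_mpa_planar(site)
  if (poly_empty(poly_op(mpa, full_range, "intersection"))) {
    abort(sprintf("Site '%s': MPA polygons do not intersect the detection range.",
                  site$site_id))
  }

  dilated <- if (vicinity_buffer_m > 0) {
    poly_offset(mpa, vicinity_buffer_m)
  } else {
    mpa
  }
  vicinity <- poly_op(poly_op(mpa, dilated, "union"), full_range, "intersection")

  band <- poly_boundary_band(mpa, boundary_halfwidth_m)
  boundary <- poly_op(band, full_range, "intersection")
  inner <- poly_op(poly_op(mpa, band, "minus"), full_range, "intersection")
  outer <- poly_op(poly_op(vicinity, mpa, "minus"), band, "minus")

  polys <- list(full_range = full_range, vicinity = vicinity,
                inner = inner, boundary = boundary, outer = outer)
  areas <- tibble(
    region = c(names(polys), "outside_vicinity"),
    area_km2 = unname(c(vapply(polys, poly_area_km2, numeric(1)),
                        poly_area_km2(full_range) - poly_area_km2(vicinity)))
  )
  structure(
    list(site_id = site$site_id, polys = polys, areas = areas,
         vicinity_buffer_m = vicinity_buffer_m,
         boundary_halfwidth_m = boundary_halfwidth_m),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> site %s (buffer %g m, band half-width %g m)\n",
              x$site_id, x$vicinity_buffer_m, x$boundary_halfwidth_m))
  print(x$areas)
  invisible(x)
}

#' Region areas as a tibble
#'
#' @param regions A `region_set` from [build_regions()].
#' @return Tibble with columns `region`, `area_km2`.
#' @export
region_areas <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  regions$areas
}

#' Assign detection points to MPA regions
#'
#' Labels each point `inner`, `boundary`, `outer`, `range_only` (inside the
#' detection range but beyond the vicinity) or `outside`. Points falling on
#' shared region edges are resolved by the fixed precedence
#' boundary > inner > outer, so labelling is deterministic.
#'
#' @param data Data frame with planar `x`, `y` columns
#'   (see [project_to_planar()]).
#' @param regions A `region_set`.
#' @return `data` as a tibble with a `region` factor column appended.
#' @export
assign_region <- function(data, regions) {
  stopifnot(inherits(regions, "region_set"))
  data <- as_tibble(data)
  lv <- c("inner", "boundary", "outer", "range_only", "outside")
  lab <- rep("outside", nrow(data))
  in_full <- points_in_poly(data$x, data$y, regions$polys$full_range)
  lab[in_full] <- "range_only"
  in_vic <- in_full & points_in_poly(data$x, data$y, regions$polys$vicinity)
  idx <- which(in_vic)
  if (length(idx) > 0) {
    sub_lab <- rep("outer", length(idx))
    in_inner <- points_in_poly(data$x[idx], data$y[idx], regions$polys$inner)
    sub_lab[in_inner] <- "inner"
    in_b <- points_in_poly(data$x[idx], data$y[idx], regions$polys$boundary)
    sub_lab[in_b] <- "boundary"
    lab[idx] <- sub_lab
  }
  mutate(data, region = factor(lab, levels = lv))
}

#' Build the analysis grid over an extent polygon
#'
#' Lays an axis-aligned square lattice (default 246-m cells, ~0.06 km²)
#' anchored at the lower-left corner of the extent's bounding box, clips
#' each cell to the extent, and drops empty cells. Clipped cell areas sum
#' to the extent area.
#'
#' @param extent A planar polygon (e.g. `regions$polys$full_range` or
#'   `$vicinity`), or a `region_set` whose `full_range` is used.
#' @param cell_size_m Cell edge length in metres.
#' @return An `activity_grid`: tibble `cells` (`cell_id`, `row`, `col`,
#'   `area_km2`) plus the clipped cell polygons.
#' @export
build_grid <- function(extent, cell_size_m = 246) {
  if (inherits(extent, "region_set")) extent <- extent$polys$full_range
  if (cell_size_m <= 0) abort("`cell_size_m` must be positive.")
  if (poly_empty(extent)) abort("`extent` is empty.")
  bb <- poly_bbox(extent)
  ncol <- ceiling((bb["xmax"] - bb["xmin"]) / cell_size_m)
  nrow_ <- ceiling((bb["ymax"] - bb["ymin"]) / cell_size_m)
  cells <- list(); rows <- integer(); cols <- integer(); areas <- numeric()
  for (i in seq_len(nrow_)) {
    y0 <- bb["ymin"] + (i - 1) * cell_size_m
    for (j in seq_len(ncol)) {
      x0 <- bb["xmin"] + (j - 1) * cell_size_m
      cell <- rect_poly(x0, y0, x0 + cell_size_m, y0 + cell_size_m)
      clipped <- poly_op(cell, extent, "intersection")
      a <- poly_area_km2(clipped)
      if (a > 0) {
        cells <- c(cells, list(clipped))
        rows <- c(rows, i); cols <- c(cols, j); areas <- c(areas, a)
      }
    }
  }
  structure(
    list(
      cells = tibble(cell_id = seq_along(rows), row = rows, col = cols,
                     area_km2 = areas),
      polys = cells,
      origin = c(x = unname(bb["xmin"]), y = unname(bb["ymin"])),
      cell_size_m = cell_size_m
    ),
    class = "activity_grid"
  )
}

#' @export
print.activity_grid <- function(x, ...) {
  cat(sprintf("<activity_grid> %d cells of %g m (%0.6f km² unclipped)\n",
              nrow(x$cells), x$cell_size_m, (x$cell_size_m / 1000)^2))
  invisible(x)
}

# cell index containing each point (fast lattice lookup; clipping means a
# looked-up cell may be absent, in which case NA).
grid_cell_of <- function(x, y, grid) {
  j <- floor((x - grid$origin["x"]) / grid$cell_size_m) + 1
  i <- floor((y - grid$origin["y"]) / grid$cell_size_m) + 1
  key <- paste(i, j)
  idx <- match(key, paste(grid$cells$row, grid$cells$col))
  grid$cells$cell_id[idx]
}

#' Write regions or a grid as GeoJSON
#'
#' Planar polygons are unprojected back to WGS84 around the site's radar and
#' written as a `FeatureCollection` with `region`/`cell_id` and `area_km2`
#' properties.
#'
#' @param regions A `region_set`, or an `activity_grid` for
#'   `write_grid_geojson()`.
#' @param site The [site_geometry()] the planar workspace is centred on.
#' @param path Output file.
#' @param values Optional tibble with `cell_id` plus value columns copied
#'   into grid-cell properties.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, site, path) {
  feats <- imap(regions$polys, function(p, nm) {
    .poly_feature(p, site, list(
      region = nm,
      area_km2 = regions$areas$area_km2[match(nm, regions$areas$region)]
    ))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = unname(feats)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions_geojson
#' @param grid An `activity_grid`.
#' @export
write_grid_geojson <- function(grid, site, path, values = NULL) {
  feats <- lapply(seq_len(nrow(grid$cells)), function(k) {
    props <- list(cell_id = grid$cells$cell_id[k],
                  area_km2 = grid$cells$area_km2[k])
    if (!is.null(values)) {
      row <- values[values$cell_id == grid$cells$cell_id[k], , drop = FALSE]
      if (nrow(row) == 1) {
        for (cn in setdiff(names(row), "cell_id")) props[[cn]] <- row[[cn]]
      }
    }
    .poly_feature(grid$polys[[k]], site, props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# planar poly -> GeoJSON MultiPolygon feature (each ring its own polygon;
# ring nesting is preserved well enough for rendering and area properties
# carry the authoritative values).
.poly_feature <- function(p, site, props) {
  rings <- lapply(p, function(r) {
    ll <- .aeqd_inv(r$x, r$y, site$radar_lon, site$radar_lat)
    n <- length(ll$lon)
    list(lapply(c(seq_len(n), 1L), function(i) c(ll$lon[i], ll$lat[i])))
  })
  list(type = "Feature",
       geometry = list(type = "MultiPolygon", coordinates = rings),
       properties = props)
}
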