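#' Construct an area table
#'
#' The area table is the package's central container: one row per areal unit
#' (e.g. a neighbourhood), with the polygon geometry carried in a list-column
#' so the whole object pipes through dplyr verbs. Centroids and areas are
#' computed from the geometry on construction.
#'
#' @param geometry a list with one element per area; each element is a list of
#'   polygon parts, each part a list of rings (first exterior, rest holes),
#'   each ring an m x 2 coordinate matrix in projected metres. A bare m x 2
#'   matrix is accepted for a simple single-ring polygon.
#' @param area_id unique labels, one per area.
#' @param population population at risk per area (non-negative).
#' @param covariates optional data frame of numeric per-area covariates.
#' @return a tibble of class `area_tbl` with columns `area_id`, `population`,
#'   the covariates, `centroid_x`, `centroid_y`, `area_km2` and `geometry`.
#' @export
area_table <- function(geometry, area_id, population, covariates = NULL) {
  geometry <- lapply(geometry, normalize_geom)
  n <- length(geometry)
  area_id <- as.character(area_id)
  if (length(area_id) != n || length(population) != n) {
    abort("geometry, area_id and population must have one entry per area")
  }
  if (anyDuplicated(area_id)) abort("area_id values must be unique")
  if (any(!is.finite(population)) || any(population < 0)) {
    abort("population must be finite and >= 0")
  }
  for (i in seq_len(n)) {
    g <- geometry[[i]]
    for (part in g) for (ring in part) {
      if (nrow(ring) < 3 || any(!is.finite(ring))) {
        abort(paste0("invalid/empty geometry for area_id ", area_id[i]))
      }
      if (ring_self_intersects(ring)) {
        abort(paste0("self-intersecting ring in area_id ", area_id[i],
                     "; repair the geometry upstream"))
      }
    }
  }
  cents <- t(vapply(geometry, poly_centroid, numeric(2)))
  check_projected(cents[, 1], cents[, 2], "area centroids")
  out <- tibble::tibble(
    area_id = area_id,
    population = as.double(population)
  )
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (nrow(covariates) != n) abort("covariates must have one row per area")
    if (!all(vapply(covariates, is.numeric, logical(1)))) {
      abort("all covariates must be numeric")
    }
    out <- dplyr::bind_cols(out, covariates)
  }
  out$centroid_x <- cents[, 1]
  out$centroid_y <- cents[, 2]
  out$area_km2 <- vapply(geometry, poly_area, numeric(1)) / 1e6
  out$geometry <- geometry
  class(out) <- c("area_tbl", class(tibble::tibble()))
  out
}

# accept a bare ring matrix, a list of rings, or a full multipolygon list
normalize_geom <- function(g) {
  close_strip <- function(r) {
    r <- as.matrix(r)
    if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    storage.mode(r) <- "double"
    r
  }
  if (is.matrix(g)) return(list(list(close_strip(g))))
  if (is.list(g) && all(vapply(g, is.matrix, logical(1)))) {
    return(list(lapply(g, close_strip)))
  }
  lapply(g, function(part) lapply(part, close_strip))
}

#' Covariate column names of an area table
#' @param areas an `area_tbl`.
#' @return character vector of covariate column names.
#' @export
covariate_names <- function(areas) {
  setdiff(names(areas), c("area_id", "population", "centroid_x", "centroid_y",
                          "area_km2", "geometry"))
}

#' Read an area table from GeoJSON
#'
#' Reads a FeatureCollection of polygons/multipolygons. All numeric feature
#' properties other than the id and population fields become covariates.
#'
#' @param path GeoJSON file.
#' @param id_field,pop_field property names holding the unique area label and
#'   the population at risk.
#' @return an [area_table()].
#' @export
read_areas <- function(path, id_field = "area_id", pop_field = "population") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% abort("not a GeoJSON FeatureCollection")
  props <- lapply(feats, function(f) f$properties)
  for (fld in c(id_field, pop_field)) {
    if (!all(vapply(props, function(p) fld %in% names(p), logical(1)))) {
      abort(paste0("configuration error: field '", fld, "' missing from GeoJSON properties"))
    }
  }
  geometry <- lapply(feats, function(f) {
    g <- f$geometry
    rings_of <- function(poly) lapply(poly, function(ring) {
      do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    })
    switch(g$type,
      Polygon = list(rings_of(g$coordinates)),
      MultiPolygon = lapply(g$coordinates, rings_of),
      abort(paste0("unsupported geometry type: ", g$type))
    )
  })
  ids <- vapply(props, function(p) as.character(p[[id_field]]), character(1))
  pop <- vapply(props, function(p) as.double(p[[pop_field]]), numeric(1))
  cov_names <- setdiff(
    Reduce(union, lapply(props, names)), c(id_field, pop_field)
  )
  numericish <- function(v) is.numeric(v) || (is.character(v) && !is.na(suppressWarnings(as.numeric(v))))
  keep <- cov_names[vapply(cov_names, function(nm) {
    all(vapply(props, function(p) is.null(p[[nm]]) || numericish(p[[nm]]), logical(1)))
  }, logical(1))]
  covs <- NULL
  if (length(keep)) {
    covs <- tibble::as_tibble(lapply(setNames(keep, keep), function(nm) {
      vapply(props, function(p) if (is.null(p[[nm]])) NA_real_ else as.double(p[[nm]]), numeric(1))
    }))
  }
  area_table(geometry, ids, pop, covs)
}

#' Write an area table to GeoJSON
#' @param areas an `area_tbl`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_areas <- function(areas, path) {
  covs <- covariate_names(areas)
  feats <- lapply(seq_len(nrow(areas)), function(i) {
    props <- c(
      list(area_id = areas$area_id[i], population = areas$population[i]),
      as.list(areas[i, covs, drop = FALSE])
    )
    coords <- lapply(areas$geometry[[i]], function(part) {
      lapply(part, function(ring) {
        ring <- rbind(ring, ring[1, , drop = FALSE])  # close ring
        lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))
      })
    })
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "MultiPolygon", coordinates = coords)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
print.area_tbl <- function(x, ...) {
  cat("# Area table:", nrow(x), "areas,", length(covariate_names(x)), "covariates\n")
  NextMethod()
}

#' Read point events from CSV or GeoJSON
#'
#' @param path CSV with `x`, `y` and a year column (plus optional `category`),
#'   or a GeoJSON FeatureCollection of points.
#' @param year_field name of the year column/property.
#' @param period optional `c(first, last)` study period; events outside are
#'   dropped with a logged count.
#' @return a tibble with columns `x`, `y`, `year` and (if present) `category`.
#' @export
read_events <- function(path, year_field = "year", period = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    ev <- purrr::map_dfr(gj$features, function(f) {
      tibble::tibble(
        x = as.double(f$geometry$coordinates[[1]]),
        y = as.double(f$geometry$coordinates[[2]]),
        year = as.integer(f$properties[[year_field]]),
        category = as.character(f$properties$category %||% NA_character_)
      )
    })
  } else {
    ev <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("x", "y") %in% names(ev))) abort("events CSV must have x and y columns")
    if (!year_field %in% names(ev)) {
      abort(paste0("configuration error: year column '", year_field, "' not found"))
    }
    bad <- which(!is.finite(suppressWarnings(as.numeric(ev$x))) |
                   !is.finite(suppressWarnings(as.numeric(ev$y))))
    if (length(bad)) {
      abort(paste0("non-numeric coordinates at row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    ev <- dplyr::rename(ev, year = dplyr::all_of(year_field))
    ev$x <- as.double(ev$x); ev$y <- as.double(ev$y); ev$year <- as.integer(ev$year)
  }
  if (nrow(ev)) check_projected(ev$x, ev$y, "event coordinates")
  if (!is.null(period) && nrow(ev)) {
    keep <- ev$year >= period[1] & ev$year <= period[2]
    if (any(!keep)) log_line("read_events", dropped_out_of_period = sum(!keep))
    ev <- ev[keep, , drop = FALSE]
  }
  tibble::as_tibble(ev)
}
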