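# Synthetic study region: a square polygon lattice with heterogeneous
# populations, spatially autocorrelated covariates, smoothly varying
# regression coefficient surfaces, and Poisson space-time event counts with
# optionally implanted clusters of elevated relative risk. The defaults
# emulate the scale of the motivating study: ~140 urban neighbourhoods
# observed for 10 years with ~700 events in total (an overall rate of about
# 2.5 events per 100,000 person-years).

#' Simulate a square lattice of areas
#'
#' @param nx,ny lattice dimensions (nx * ny >= 4).
#' @param cell_size polygon side length in metres.
#' @param pop_range `c(min, max)` for per-area populations, drawn as uniform
#'   integers.
#' @param seed integer seed; identical seeds give identical tables.
#' @param origin lower-left corner, in metres. The default keeps coordinates
#'   well outside the lon/lat-degree range.
#' @return an [area_table()] of `nx * ny` square areas, row-major from the
#'   lower-left corner.
#' @export
sim_lattice <- function(nx = 12, ny = 12, cell_size = 1000,
                        pop_range = c(5000, 35000), seed = 1,
                        origin = c(5e5, 5e6)) {
  if (nx * ny < 4) abort("lattice must have at least 4 cells")
  set.seed(seed)
  geoms <- list(); ids <- character(0)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      x0 <- origin[1] + (ix - 1) * cell_size
      y0 <- origin[2] + (iy - 1) * cell_size
      ring <- rbind(
        c(x0, y0), c(x0 + cell_size, y0),
        c(x0 + cell_size, y0 + cell_size), c(x0, y0 + cell_size)
      )
      geoms[[length(geoms) + 1L]] <- ring
      ids <- c(ids, sprintf("A%03d", (iy - 1) * nx + ix))
    }
  }
  pop_vals <- seq.int(pop_range[1], pop_range[2])
  pop <- if (length(pop_vals) == 1) {
    rep(pop_vals, nx * ny)  # guard: sample(n) would draw from 1:n
  } else {
    sample(pop_vals, nx * ny, replace = TRUE)
  }
  area_table(geoms, ids, pop)
}

#' Simulate spatially autocorrelated covariates
#'
#' Zero-mean, unit-variance Gaussian fields with exponential spatial
#' correlation `exp(-d / range_m)`, realized by pushing independent standard
#' normals through the (symmetric) square root of the correlation matrix.
#'
#' @param areas an [area_table()].
#' @param vars names of the covariate columns to create.
#' @param range_m correlation range in metres (> 0). Small values give
#'   spatially unstructured fields; values of a few cell widths give strongly
#'   positive Moran's I.
#' @param seed integer seed.
#' @return `areas` with the new covariate columns appended.
#' @export
sim_covariates <- function(areas, vars = c("x1", "x2"), range_m = 3000, seed = 1) {
  if (range_m <= 0) abort("range_m must be > 0")
  d <- centroid_distances(areas)
  S <- exp(-d / range_m)
  e <- eigen(S, symmetric = TRUE)
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  set.seed(seed)
  z <- rt %*% matrix(rnorm(nrow(areas) * length(vars)), nrow(areas))
  colnames(z) <- vars
  out <- dplyr::bind_cols(
    areas[setdiff(names(areas), vars)],
    tibble::as_tibble(z)
  )
  # keep the column layout of area_table (geometry and centroids last)
  out <- out[, c(setdiff(names(out), c("centroid_x", "centroid_y", "area_km2", "geometry")),
                 "centroid_x", "centroid_y", "area_km2", "geometry")]
  class(out) <- class(areas)
  out
}

#' Coefficient surfaces for synthetic regression data
#'
#' Descriptions of how a regression coefficient varies over space:
#' `surf_constant()` is flat; `surf_gradient()` rises linearly along a
#' direction from `range[1]` to `range[2]` across the region; `surf_hotspot()`
#' is a Gaussian bump of the given `amplitude` and spatial `range` (metres)
#' on top of a `baseline`.
#'
#' @param value constant coefficient value.
#' @param angle gradient direction in radians (0 = towards +x).
#' @param range for `surf_gradient`, `c(low, high)` coefficient values at the
#'   two extremes; for `surf_hotspot`, the e-folding radius in metres.
#' @param centre hotspot centre `c(x, y)` in metres, or `NULL` for the region
#'   midpoint.
#' @param amplitude hotspot height.
#' @param baseline hotspot background level.
#' @return an object of class `coef_surface`.
#' @export
surf_constant <- function(value) {
  structure(list(kind = "constant", value = value), class = "coef_surface")
}

#' @rdname surf_constant
#' @export
surf_gradient <- function(angle = 0, range = c(-1, 1)) {
  structure(list(kind = "gradient", angle = angle, range = range),
            class = "coef_surface")
}

#' @rdname surf_constant
#' @export
surf_hotspot <- function(centre = NULL, range = 3000, amplitude = 1, baseline = 0) {
  structure(list(kind = "hotspot", centre = centre, range = range,
                 amplitude = amplitude, baseline = baseline),
            class = "coef_surface")
}

#' Evaluate a coefficient surface at area centroids
#' @param surface a `coef_surface`.
#' @param areas an [area_table()].
#' @return numeric vector, one coefficient per area.
#' @export
eval_surface <- function(surface, areas) {
  x <- areas$centroid_x; y <- areas$centroid_y
  switch(surface$kind,
    constant = rep(surface$value, length(x)),
    gradient = {
      proj <- x * cos(surface$angle) + y * sin(surface$angle)
      if (max(proj) == min(proj)) return(rep(mean(surface$range), length(x)))
      t01 <- (proj - min(proj)) / (max(proj) - min(proj))
      surface$range[1] + t01 * (surface$range[2] - surface$range[1])
    },
    hotspot = {
      ctr <- surface$centre %||% c(mean(range(x)), mean(range(y)))
      d2 <- (x - ctr[1])^2 + (y - ctr[2])^2
      surface$baseline + surface$amplitude * exp(-d2 / surface$range^2)
    },
    abort(paste0("unknown surface kind: ", surface$kind))
  )
}

#' Simulate Poisson space-time counts
#'
#' Counts follow `Poisson(pop_i * base_rate * exp(sum_j beta_j(u_i, v_i) *
#' x_ij) * RR_it)`, where the log-linear coefficients may vary over space via
#' [surf_constant()]-family surfaces and `RR_it` comes from implanted
#' space-time clusters (1 outside all clusters).
#'
#' @param areas an [area_table()] carrying any covariates named in `coefs`.
#' @param years number of years (or an explicit year vector).
#' @param base_rate events per person-year in a baseline area.
#' @param coefs named list of `coef_surface`s, one per covariate column.
#' @param clusters list of implanted clusters; each a list with either
#'   `areas` (ids) or `centre` + `radius` (metres), plus `years = c(first,
#'   last)` (1-based indexes into the study years) and `rr > 0`.
#' @param seed integer seed.
#' @return a [count_panel()]; the true per-area-year relative risk matrix is
#'   attached as attribute `"rr"`, and cluster membership as `"cluster_areas"`.
#' @export
sim_counts <- function(areas, years = 10, base_rate = 2.5e-5, coefs = list(),
                       clusters = list(), seed = 1) {
  if (base_rate < 0) abort("base_rate must be >= 0")
  yr <- if (length(years) == 1) seq_len(years) else years
  n <- nrow(areas); T <- length(yr)
  eta <- rep(0, n)
  for (nm in names(coefs)) {
    if (!nm %in% names(areas)) abort(paste0("covariate '", nm, "' not present in areas"))
    eta <- eta + eval_surface(coefs[[nm]], areas) * areas[[nm]]
  }
  if (any(eta > 50)) {
    abort("rate overflow: exp() argument exceeds 50; use smaller coefficient amplitudes")
  }
  # centre the log-linear effects so base_rate is the population-average
  # rate and covariates act as relative risks around it: the expected total
  # (before clusters) is sum(pop) * base_rate * years for every seed
  if (any(eta != 0)) {
    eta <- eta - log(sum(areas$population * exp(eta)) / sum(areas$population))
  }
  rr <- matrix(1, n, T)
  cluster_areas <- list()
  for (cl in clusters) {
    if (is.null(cl$rr) || cl$rr <= 0) abort("cluster rr must be > 0")
    idx <- if (!is.null(cl$areas)) {
      match(cl$areas, areas$area_id)
    } else {
      d <- sqrt((areas$centroid_x - cl$centre[1])^2 + (areas$centroid_y - cl$centre[2])^2)
      which(d <= cl$radius)
    }
    if (anyNA(idx) || !length(idx)) abort("cluster areas not found")
    tw <- seq(cl$years[1], cl$years[2])
    rr[idx, tw] <- rr[idx, tw] * cl$rr
    cluster_areas[[length(cluster_areas) + 1L]] <- areas$area_id[idx]
  }
  mu <- outer(areas$population * base_rate * exp(eta), rep(1, T)) * rr
  set.seed(seed)
  counts <- matrix(rpois(n * T, mu), n, T)
  out <- count_panel(counts, areas$population, yr, areas$area_id)
  attr(out, "rr") <- rr
  attr(out, "cluster_areas") <- cluster_areas
  out
}

#' Scatter panel counts into point events
#'
#' Each counted event is placed uniformly at random inside its area polygon
#' (rejection sampling from the bounding box), so the point events and the
#' panel agree by construction.
#'
#' @param panel a [count_panel()].
#' @param areas the matching [area_table()].
#' @param seed integer seed.
#' @return a point-event tibble with `x`, `y`, `year`.
#' @export
sim_events <- function(panel, areas, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(panel$counts))) {
    tot <- sum(panel$counts[i, ])
    if (tot == 0) next
    g <- areas$geometry[[i]]
    bb <- poly_bbox(g)
    pts <- matrix(NA_real_, 0, 2)
    while (nrow(pts) < tot) {
      m <- max(2 * (tot - nrow(pts)), 8)
      cx <- runif(m, bb[1], bb[3]); cy <- runif(m, bb[2], bb[4])
      ok <- vapply(seq_len(m), function(k) point_in_poly(cx[k], cy[k], g), logical(1))
      pts <- rbind(pts, cbind(cx[ok], cy[ok]))
    }
    pts <- pts[seq_len(tot), , drop = FALSE]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x = pts[, 1], y = pts[, 2],
      year = rep(panel$years, times = panel$counts[i, ])
    )
  }
  if (!length(rows)) return(tibble::tibble(x = double(), y = double(), year = integer()))
  dplyr::bind_rows(rows)
}

#' Simulate a Gaussian spatially varying coefficient response
#'
#' The regression test-bed: `y_i = beta_0(u_i, v_i) + sum_j beta_j(u_i, v_i)
#' x_ij + eps_i` with `eps ~ N(0, noise_sd^2)`, on the scale of the (already
#' standardized) covariates. Used to validate GWR/MGWR coefficient recovery
#' and the Monte Carlo surface-variability test against known truth.
#'
#' @param areas an [area_table()] carrying the covariates named in `coefs`.
#' @param coefs named list of `coef_surface`s (one per covariate column).
#' @param intercept a `coef_surface` for the intercept.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return `areas` with a `y` column appended; the true coefficient matrix
#'   (areas x terms, including `"intercept"`) is attached as attribute
#'   `"true_coefs"`.
#' @export
sim_response <- function(areas, coefs, intercept = surf_constant(0),
                         noise_sd = 0.25, seed = 1) {
  n <- nrow(areas)
  B <- cbind(intercept = eval_surface(intercept, areas))
  y <- B[, 1]
  for (nm in names(coefs)) {
    b <- eval_surface(coefs[[nm]], areas)
    B <- cbind(B, b); colnames(B)[ncol(B)] <- nm
    y <- y + b * areas[[nm]]
  }
  set.seed(seed)
  y <- y + rnorm(n, 0, noise_sd)
  out <- areas
  out$y <- y
  out <- out[, c(setdiff(names(out), c("centroid_x", "centroid_y", "area_km2", "geometry")),
                 "centroid_x", "centroid_y", "area_km2", "geometry")]
  class(out) <- class(areas)
  attr(out, "true_coefs") <- B
  out
}
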