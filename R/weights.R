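#' Build a spatial weights structure
#'
#' Contiguity (queen/rook) is decided from shared ring vertices: two areas are
#' queen-contiguous when their boundaries share at least one vertex, and
#' rook-contiguous when they share a full edge (two consecutive vertices).
#' `knn` connects each area to the `k` nearest centroids (the adjacency
#' pattern of knn weights is not forced symmetric). Binary weights are
#' optionally row-standardized to sum to one per non-isolated area.
#'
#' @param areas an [area_table()].
#' @param scheme `"queen"` (default), `"rook"` or `"knn"`.
#' @param k neighbour count for `scheme = "knn"`.
#' @param row_standardize divide each area's weights by their sum.
#' @param snap tolerance (metres) within which boundary vertices are
#'   considered identical.
#' @return an object of class `spatial_weights`: per-area neighbour index
#'   lists, aligned positive weights, and the scheme metadata.
#' @export
build_weights <- function(areas, scheme = c("queen", "rook", "knn"), k = 5,
                          row_standardize = TRUE, snap = 1e-6) {
  scheme <- match.arg(scheme)
  n <- nrow(areas)
  if (n < 2) abort("need at least 2 areas to build weights")
  nb <- vector("list", n)
  if (scheme == "knn") {
    d <- centroid_distances(areas)
    if (k >= n) abort("knn k must be < number of areas")
    for (i in seq_len(n)) nb[[i]] <- order(d[i, ])[2:(k + 1)]
  } else {
    key_of <- function(g) {
      unique(unlist(lapply(g, function(part) lapply(part, function(r) {
        paste(round(r[, 1] / snap), round(r[, 2] / snap))
      }))))
    }
    edge_of <- function(g) {
      unlist(lapply(g, function(part) lapply(part, function(r) {
        kk <- paste(round(r[, 1] / snap), round(r[, 2] / snap))
        kn <- c(kk[-1], kk[1])
        ifelse(kk < kn, paste(kk, kn, sep = "|"), paste(kn, kk, sep = "|"))
      })))
    }
    keys <- lapply(areas$geometry, key_of)
    # invert vertex -> areas to avoid the O(n^2) all-pairs comparison
    vert_map <- split(
      rep(seq_len(n), lengths(keys)), unlist(keys)
    )
    cand <- lapply(seq_len(n), function(i) integer(0))
    for (as_ in vert_map) {
      if (length(as_) > 1) {
        for (i in as_) cand[[i]] <- union(cand[[i]], setdiff(as_, i))
      }
    }
    if (scheme == "queen") {
      nb <- lapply(cand, sort)
    } else {
      edges <- lapply(areas$geometry, edge_of)
      for (i in seq_len(n)) {
        nb[[i]] <- sort(Filter(function(j) length(intersect(edges[[i]], edges[[j]])) > 0,
                               cand[[i]]))
      }
    }
  }
  iso <- which(lengths(nb) == 0)
  if (length(iso) == n) abort("all areas are isolated; spatial autocorrelation undefined")
  if (length(iso)) {
    log_line("build_weights", isolated_areas = paste(areas$area_id[iso], collapse = ","))
  }
  w <- lapply(nb, function(jj) rep(1, length(jj)))
  if (row_standardize) {
    w <- lapply(w, function(v) if (length(v)) v / sum(v) else v)
  }
  structure(
    list(area_id = areas$area_id, neighbours = nb, weights = w,
         row_standardized = row_standardize, scheme = scheme),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights:", length(x$neighbours), "areas, scheme =", x$scheme,
      if (x$row_standardized) "(row-standardized)" else "(binary)", "\n")
  cat("  average neighbours:", round(mean(lengths(x$neighbours)), 2), "\n")
  invisible(x)
}

#' Spatial weights as a sparse matrix
#' @param w a `spatial_weights` object.
#' @return a sparse `dgCMatrix` with w_ij in row i, column j.
#' @export
weights_matrix <- function(w) {
  n <- length(w$neighbours)
  i <- rep(seq_len(n), lengths(w$neighbours))
  Matrix::sparseMatrix(
    i = i, j = unlist(w$neighbours), x = unlist(w$weights), dims = c(n, n),
    dimnames = list(w$area_id, w$area_id)
  )
}

#' Pairwise centroid distances
#' @param areas an [area_table()].
#' @return a symmetric n x n matrix of Euclidean distances in metres.
#' @export
centroid_distances <- function(areas) {
  if (nrow(areas) < 2) abort("need at least 2 areas")
  as.matrix(dist(cbind(areas$centroid_x, areas$centroid_y)))
}

#' Aggregate point events to an area-by-year count panel
#'
#' Point-in-polygon with boundary points assigned to exactly one area: the
#' first containing area in stable input order. Events falling in no polygon
#' are counted in an `unassigned` bucket rather than silently dropped.
#'
#' @param events a point-event tibble (from [read_events()] or simulation).
#' @param areas an [area_table()].
#' @param years the year labels of the panel; defaults to the full range seen
#'   in `events`.
#' @return a `count_panel`: list with `counts` (areas x years integer matrix),
#'   `population`, `years`, `area_id` and the `unassigned` count.
#' @export
aggregate_events <- function(events, areas, years = NULL) {
  if (is.null(years)) {
    if (!nrow(events)) abort("cannot infer years from an empty event table")
    years <- seq(min(events$year), max(events$year))
  }
  n <- nrow(areas)
  counts <- matrix(0L, n, length(years),
                   dimnames = list(areas$area_id, as.character(years)))
  unassigned <- 0L
  if (nrow(events)) {
    # cheap bbox prefilter, then exact inclusive containment in stable order
    bbs <- t(vapply(areas$geometry, poly_bbox, numeric(4)))
    for (e in seq_len(nrow(events))) {
      yr <- match(events$year[e], years)
      if (is.na(yr)) next
      px <- events$x[e]; py <- events$y[e]
      cand <- which(px >= bbs[, 1] & px <= bbs[, 3] & py >= bbs[, 2] & py <= bbs[, 4])
      hit <- 0L
      for (i in cand) {
        if (point_in_poly(px, py, areas$geometry[[i]])) { hit <- i; break }
      }
      if (hit > 0L) counts[hit, yr] <- counts[hit, yr] + 1L else unassigned <- unassigned + 1L
    }
  }
  if (unassigned > 0) log_line("aggregate_events", unassigned = unassigned)
  count_panel(counts, areas$population, years, areas$area_id, unassigned)
}

#' Construct a count panel
#' @param counts areas x years non-negative integer matrix.
#' @param population per-area population at risk.
#' @param years ordered year labels.
#' @param area_id area labels aligned with `counts` rows.
#' @param unassigned number of events that fell in no area.
#' @return a `count_panel` object.
#' @export
count_panel <- function(counts, population, years, area_id = rownames(counts),
                        unassigned = 0L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (nrow(counts) != length(population)) abort("counts rows must match population length")
  if (ncol(counts) != length(years)) abort("counts columns must match years length")
  if (is.null(area_id)) area_id <- paste0("A", seq_len(nrow(counts)))
  dimnames(counts) <- list(area_id, as.character(years))
  structure(
    list(counts = counts, population = as.double(population),
         years = as.integer(years), area_id = as.character(area_id),
         unassigned = as.integer(unassigned)),
    class = "count_panel"
  )
}

#' @export
print.count_panel <- function(x, ...) {
  cat("Count panel:", nrow(x$counts), "areas x", ncol(x$counts), "years;",
      sum(x$counts), "events", if (x$unassigned) paste0("(+", x$unassigned, " unassigned)") else "", "\n")
  invisible(x)
}

#' Tidy a count panel into a long area-year tibble
#' @param x a `count_panel`.
#' @param ... unused.
#' @return a tibble with columns `area_id`, `year`, `count`, `population`.
#' @export
tidy.count_panel <- function(x, ...) {
  tibble::tibble(
    area_id = rep(x$area_id, times = ncol(x$counts)),
    year = rep(x$years, each = nrow(x$counts)),
    count = as.integer(x$counts),
    population = rep(x$population, times = ncol(x$counts))
  )
}
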