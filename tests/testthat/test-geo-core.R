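test_that("GeoJSON areas round-trip ids, population and covariates exactly", {
  a <- square_lattice(2, 1)
  a$cov_a <- c(1.25, -3.5)
  a$cov_b <- c(10, 20.125)
  class(a) <- c("area_tbl", class(tibble::tibble()))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_areas(a, path)
  b <- read_areas(path)
  expect_equal(b$area_id, a$area_id)
  expect_identical(b$population, a$population)
  expect_identical(b$cov_a, a$cov_a)
  expect_identical(b$cov_b, a$cov_b)
  expect_equal(b$centroid_x, a$centroid_x)
  expect_equal(nrow(b), 2)
})

test_that("centroids: square symmetry and L-shape area-weighted decomposition", {
  sq <- area_table(list(unit_square(5e5, 5e6, 1000)), "s", 1)
  expect_equal(c(sq$centroid_x, sq$centroid_y), c(5e5 + 500, 5e6 + 500))

  # L-shape = 2x1 horizontal rectangle + 1x1 block on top of its left half
  L <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2)) * 1000 +
    matrix(rep(c(5e5, 5e6), each = 6), ncol = 2)
  got <- spatepi:::poly_centroid(list(list(L)))
  # decompose-and-average oracle: rect A (2x1, centroid (1, .5), area 2),
  # rect B (1x1, centroid (.5, 1.5), area 1)
  cx <- (2 * 1 + 1 * 0.5) / 3 * 1000 + 5e5
  cy <- (2 * 0.5 + 1 * 1.5) / 3 * 1000 + 5e6
  expect_equal(got, c(cx, cy))
})

test_that("geometry validation refuses lon/lat-looking and self-intersecting input", {
  expect_error(area_table(list(unit_square(0, 0, 1)), "a", 1), "longitude/latitude")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)) * 1000 +
    matrix(rep(c(5e5, 5e6), each = 4), ncol = 2)
  expect_error(area_table(list(bowtie), "b", 1), "self-intersecting")
})

test_that("event reading drops out-of-period rows and flags bad coordinates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,year", "500100,5000100,2012", "500200,5000100,2013",
               "500300,5000200,2030"), path)
  expect_message(ev <- read_events(path, period = c(2012, 2021)),
                 "dropped_out_of_period=1")
  expect_equal(nrow(ev), 2)

  ev_all <- read_events(path)
  expect_equal(nrow(ev_all), 3)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,year", "500100,oops,2012"), bad)
  expect_error(read_events(bad), "row")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y,year", empty)
  expect_equal(nrow(read_events(empty)), 0)
})

test_that("queen/rook contiguity matches lattice adjacency structure", {
  a22 <- square_lattice(2, 2)
  wq <- build_weights(a22, "queen", row_standardize = FALSE)
  expect_true(all(lengths(wq$neighbours) == 3))  # complete mutual adjacency

  a33 <- square_lattice(3, 3)
  wr <- build_weights(a33, "rook", row_standardize = FALSE)
  # brute-force oracle: rook neighbours iff centroids exactly one side apart
  cx <- a33$centroid_x; cy <- a33$centroid_y
  for (i in seq_len(9)) {
    oracle <- which(abs(cx - cx[i]) + abs(cy - cy[i]) == 1000)
    expect_equal(sort(wr$neighbours[[i]]), sort(oracle))
  }
  expect_equal(length(wr$neighbours[[5]]), 4)          # centre
  expect_equal(lengths(wr$neighbours)[c(1, 3, 7, 9)], rep(2L, 4))  # corners
})

test_that("weights: pattern symmetry, row standardization, isolation handling", {
  a <- square_lattice(3, 3)
  for (scheme in c("queen", "rook")) {
    w <- build_weights(a, scheme, row_standardize = FALSE)
    M <- as.matrix(weights_matrix(w))
    expect_equal((M > 0), t(M > 0))
    expect_true(all(diag(M) == 0))
  }
  ws <- build_weights(a, "queen", row_standardize = TRUE)
  expect_equal(unname(Matrix::rowSums(weights_matrix(ws))), rep(1, 9))

  wk <- build_weights(a, "knn", k = 3, row_standardize = TRUE)
  expect_true(all(lengths(wk$neighbours) == 3))
})

test_that("event aggregation conserves counts and matches containment oracle", {
  a <- square_lattice(2, 2)
  set.seed(42)
  ev <- tibble::tibble(x = runif(100, 5e5, 5e5 + 2000),
                       y = runif(100, 5e6, 5e6 + 2000),
                       year = sample(1:2, 100, replace = TRUE))
  p <- aggregate_events(ev, a, years = 1:2)
  expect_equal(sum(p$counts) + p$unassigned, 100)
  # O(n*m) containment oracle
  for (i in 1:4) {
    oracle <- sum(vapply(seq_len(100), function(e) {
      spatepi:::point_in_poly(ev$x[e], ev$y[e], a$geometry[[i]])
    }, logical(1)))
    expect_gte(oracle, sum(p$counts[i, ]))  # oracle includes boundary double-hits
  }
  # boundary point between C01 and C02 is assigned to exactly one area
  evb <- tibble::tibble(x = 5e5 + 1000, y = 5e6 + 500, year = 1L)
  pb <- aggregate_events(evb, a, years = 1)
  expect_equal(sum(pb$counts), 1)
  expect_equal(pb$unassigned, 0L)
  # event outside all polygons lands in the unassigned bucket
  evo <- tibble::tibble(x = 5e5 + 9000, y = 5e6, year = 1L)
  expect_message(po <- aggregate_events(evo, a, years = 1), "unassigned=1")
  expect_equal(sum(po$counts), 0)
  expect_equal(po$unassigned, 1L)
})

test_that("uniformly scattered points match per-cell brute-force tallies exactly", {
  a <- square_lattice(2, 2)
  set.seed(7)
  # strictly interior points (away from shared boundaries): assignment unique
  ev <- tibble::tibble(
    x = 5e5 + runif(100) * 1999 + 0.5,
    y = 5e6 + runif(100) * 1999 + 0.5,
    year = 1L
  )
  ev <- ev[abs((ev$x - 5e5) - 1000) > 1 & abs((ev$y - 5e6) - 1000) > 1, ]
  p <- aggregate_events(ev, a, years = 1)
  for (i in 1:4) {
    oracle <- sum(vapply(seq_len(nrow(ev)), function(e) {
      spatepi:::point_in_poly(ev$x[e], ev$y[e], a$geometry[[i]])
    }, logical(1)))
    expect_equal(unname(p$counts[i, 1]), oracle)
  }
})

test_that("centroid distances are Euclidean, symmetric, zero-diagonal", {
  a <- area_table(list(unit_square(5e5 - 500, 5e6 - 500, 1000),
                       unit_square(5e5 + 2500, 5e6 + 3500, 1000)),
                  c("p", "q"), c(1, 1))
  d <- centroid_distances(a)
  expect_equal(d[1, 2], 5000)  # 3-4-5 triangle in km
  set.seed(3)
  b <- sim_lattice(3, 4, seed = 5)
  D <- centroid_distances(b)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # brute-force pairwise loop oracle
  for (i in 1:5) for (j in 6:12) {
    expect_equal(D[i, j], sqrt((b$centroid_x[i] - b$centroid_x[j])^2 +
                                 (b$centroid_y[i] - b$centroid_y[j])^2))
  }
})
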