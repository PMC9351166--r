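# Shared in-code fixtures. Everything is generated programmatically; the
# heavier ones are cached per test run.

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# n x n lattice of unit squares offset far from the lon/lat-degree range
square_lattice <- function(nx, ny, side = 1000, pop = 1000) {
  geoms <- list(); ids <- character(0)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    geoms[[length(geoms) + 1L]] <- unit_square(5e5 + (ix - 1) * side,
                                               5e6 + (iy - 1) * side, side)
    ids <- c(ids, sprintf("C%02d", (iy - 1) * nx + ix))
  }
  area_table(geoms, ids, rep(pop, nx * ny))
}

# O(n^2) explicit double-sum Moran oracle (independent of the package path)
moran_oracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# brute-force optimal 1-D classification: enumerate all contiguous partitions
jenks_oracle <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  cuts <- combn(seq_len(n - 1), k - 1, simplify = FALSE)
  best <- Inf
  for (cc in cuts) {
    bounds <- c(0, cc, n)
    tot <- sum(vapply(seq_len(k), function(g) {
      ss(x[(bounds[g] + 1):bounds[g + 1]])
    }, numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

# standard regression testbed: lattice + autocorrelated covariates + known
# spatially varying coefficient response
make_regression_fixture <- function(seed = 1, nx = 12, ny = 12,
                                    noise_sd = 0.25) {
  a <- sim_lattice(nx, ny, seed = seed)
  a <- sim_covariates(a, c("x1", "x2"), range_m = 3000, seed = seed + 100)
  sim_response(
    a,
    coefs = list(x1 = surf_constant(0.5),
                 x2 = surf_hotspot(range = 4000, amplitude = 1)),
    noise_sd = noise_sd, seed = seed + 200
  )
}

expect_tbl_cols <- function(x, cols) {
  expect_true(all(cols %in% names(x)), info = paste("missing:", paste(setdiff(cols, names(x)), collapse = ",")))
}
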