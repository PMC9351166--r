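test_that("Poisson LLR follows the closed form with 0*log(0) = 0", {
  expect_equal(poisson_llr(2, 2, 10), 0)  # null identity
  expect_equal(poisson_llr(5, 2, 10, "high"),
               5 * log(2.5) + 5 * log(5 / 8), tolerance = 1e-12)
  expect_equal(poisson_llr(0, 2, 10, "low"),
               10 * log(10 / 8), tolerance = 1e-12)
  expect_equal(poisson_llr(0, 2, 10, "high"), 0)  # wrong direction gated to 0
  expect_equal(poisson_llr(10, 2, 10, "high"), 10 * log(10 / 2))  # c = C boundary
  expect_error(poisson_llr(1, 0, 10), "0 < e < C")
})

test_that("cluster reporting computes OE and RR as stated", {
  p <- count_panel(matrix(c(20, 80), 1, 2), 1000, 1:2, "a")
  # O=20, E=10, C=100 style check via the rr helper
  expect_equal(spatepi:::scan_rr(20, 10, 100), (20 / 10) / (80 / 90))
  expect_equal(spatepi:::scan_rr(10, 10, 100), 1)
  expect_true(is.infinite(spatepi:::scan_rr(100, 10, 100)))  # O = C flagged
})

test_that("temporal scan finds the dominant year and respects the window cap", {
  counts <- matrix(0L, 3, 6, dimnames = list(paste0("a", 1:3), 1:6))
  counts[, 4] <- c(5L, 7L, 8L)
  p <- count_panel(counts, rep(1000, 3), 1:6)
  s <- temporal_scan(p, n_sim = 99, seed = 1)
  expect_equal(s$year_start[1], 4)
  expect_equal(s$year_end[1], 4)
  expect_lte(max(s$year_end - s$year_start + 1), 3)  # <= 50% of 6 years
  expect_lte(s$p[1], 0.05)
  # all-zero panel: empty result, no error
  pz <- count_panel(matrix(0L, 2, 4), c(10, 10), 1:4)
  expect_equal(nrow(temporal_scan(pz, n_sim = 9)), 0)
})

test_that("temporal scan Monte Carlo p is calibrated under uniform risk", {
  a <- sim_lattice(4, 4, seed = 2)
  rej <- 0
  reps <- 200
  for (s in 1:reps) {
    p <- sim_counts(a, years = 10, base_rate = 5e-5, seed = 5000 + s)
    sc <- temporal_scan(p, n_sim = 199, seed = s)
    if (nrow(sc) && !is.na(sc$p[1]) && sc$p[1] < 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.08)
})

test_that("temporal scan recovers an elevated late period", {
  a <- sim_lattice(4, 4, seed = 2)
  hit <- 0
  reps <- 100
  for (s in 1:reps) {
    p <- sim_counts(a, years = 10, base_rate = 5e-5, seed = 7000 + s,
                    clusters = list(list(areas = a$area_id, years = c(8, 10),
                                         rr = 2.5)))
    sc <- temporal_scan(p, n_sim = 0, seed = s)
    if (nrow(sc) && sc$year_start[1] <= 10 && sc$year_end[1] >= 8) hit <- hit + 1
  }
  expect_gte(hit / reps, 0.9)
})

test_that("space-time scan constraints, determinism and single-area reduction", {
  a <- sim_lattice(4, 4, seed = 9)
  p <- sim_counts(a, years = 6, base_rate = 1e-4, seed = 10)
  s1 <- spacetime_scan(p, a, n_sim = 19, seed = 5)
  s2 <- spacetime_scan(p, a, n_sim = 19, seed = 5)
  expect_identical(cluster_report(s1), cluster_report(s2))
  # the <= 50% constraints forbid the whole region/period window
  expect_true(all(lengths(s1$areas) < 16))
  tot_pop <- sum(a$population)
  for (cl in s1$areas) {
    expect_lte(sum(a$population[match(cl, a$area_id)]), 0.5 * tot_pop)
  }
  expect_true(all(s1$year_end - s1$year_start + 1 <= 3))
  expect_error(spacetime_scan(p, a, max_pop_frac = 1.5), "max_pop_frac")
  # secondary clusters share no areas with better-ranked ones
  if (nrow(s1) > 1) {
    expect_equal(length(intersect(s1$areas[[1]], s1$areas[[2]])), 0)
  }
  # single-area panel reduces to the purely temporal scan
  p1 <- count_panel(p$counts[1, , drop = FALSE], p$population[1], p$years, "a1")
  st <- spacetime_scan(p1, a[1, ], n_sim = 0)
  tt <- temporal_scan(p1, n_sim = 0)
  expect_equal(st$llr[1], tt$llr[1])
  expect_equal(st$year_start[1], tt$year_start[1])
})

test_that("Monte Carlo p-values are bounded and reproducible", {
  a <- sim_lattice(4, 4, seed = 3)
  p <- sim_counts(a, years = 5, base_rate = 2e-4, seed = 4,
                  clusters = list(list(areas = a$area_id[1:3], years = c(2, 3),
                                       rr = 4)))
  s <- spacetime_scan(p, a, n_sim = 99, seed = 11)
  expect_true(all(s$p >= 1 / 100 & s$p <= 1))
  expect_true(all(s$llr >= 0))
  expect_true(all(s$rr[s$observed > s$expected] >= s$oe[s$observed > s$expected]))
})
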