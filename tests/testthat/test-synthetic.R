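test_that("lattice generation is deterministic and respects pop_range", {
  a1 <- sim_lattice(12, 12, seed = 3)
  a2 <- sim_lattice(12, 12, seed = 3)
  expect_identical(a1$population, a2$population)
  expect_equal(nrow(a1), 144)
  expect_equal(unique(a1$area_km2), 1)
  a3 <- sim_lattice(4, 4, pop_range = c(500, 500), seed = 1)
  expect_true(all(a3$population == 500))
  expect_error(sim_lattice(1, 2), "at least 4")
})

test_that("covariate fields have the requested spatial structure", {
  a <- sim_lattice(12, 12, seed = 2)
  w <- build_weights(a)
  # near-zero correlation range: Moran's I ~ E[I] = -1/(n-1) over reps
  Is_small <- vapply(1:200, function(s) {
    f <- sim_covariates(a, "v", range_m = 1, seed = s)
    global_moran(f$v, w)$I
  }, numeric(1))
  expect_lt(abs(mean(Is_small) - (-1 / 143)), 3 * sd(Is_small) / sqrt(200))
  # large range: strongly positive autocervation
  Is_big <- vapply(1:20, function(s) {
    f <- sim_covariates(a, "v", range_m = 5000, seed = s)
    global_moran(f$v, w)$I
  }, numeric(1))
  expect_gt(mean(Is_big), 0.3)
  # determinism
  f1 <- sim_covariates(a, c("u", "v"), range_m = 3000, seed = 9)
  f2 <- sim_covariates(a, c("u", "v"), range_m = 3000, seed = 9)
  expect_identical(f1$u, f2$u)
})

test_that("coefficient surfaces have their stated functional form", {
  a <- sim_lattice(6, 6, seed = 1)
  expect_equal(var(eval_surface(surf_constant(2.5), a)), 0)
  g <- eval_surface(surf_gradient(angle = 0, range = c(-1, 1)), a)
  ord <- order(a$centroid_x)
  expect_true(all(diff(g[ord]) >= 0))        # monotone along direction
  expect_equal(range(g), c(-1, 1))
  h <- eval_surface(surf_hotspot(range = 2000, amplitude = 2), a)
  ctr <- c(mean(range(a$centroid_x)), a$centroid_y[which.max(h)])
  expect_lte(max(h), 2)
  expect_true(all(h > 0))
})

test_that("Poisson counts calibrate to base_rate and implanted relative risk", {
  a <- sim_lattice(12, 12, seed = 2)
  py <- sum(a$population) * 5
  # all-beta-zero: pooled mean events per person-year ~ base_rate
  rates <- vapply(1:200, function(s) {
    sum(sim_counts(a, years = 5, base_rate = 2.5e-5, seed = s)$counts) / py
  }, numeric(1))
  mc_se <- sd(rates) / sqrt(200)
  expect_lt(abs(mean(rates) - 2.5e-5), 3 * mc_se)
  # implanted cluster: in/out rate ratio recovers RR = 3
  ctr <- c(mean(range(a$centroid_x)), mean(range(a$centroid_y)))
  cl <- list(list(centre = ctr, radius = 1600, years = c(2, 4), rr = 3))
  ratios <- vapply(1:200, function(s) {
    p <- sim_counts(a, years = 5, base_rate = 1e-4, clusters = cl, seed = s)
    idx <- match(attr(p, "cluster_areas")[[1]], p$area_id)
    rate_in <- sum(p$counts[idx, 2:4]) / (sum(p$population[idx]) * 3)
    rate_out <- (sum(p$counts) - sum(p$counts[idx, 2:4])) /
      (sum(p$population) * 5 - sum(p$population[idx]) * 3)
    rate_in / rate_out
  }, numeric(1))
  expect_gte(mean(ratios), 2.5)
  expect_lte(mean(ratios), 3.5)
  # degenerate and overflow cases
  expect_true(all(sim_counts(a, years = 3, base_rate = 0, seed = 1)$counts == 0))
  a2 <- sim_covariates(a, "v", range_m = 2000, seed = 1)
  expect_error(
    sim_counts(a2, years = 2, coefs = list(v = surf_constant(100)), seed = 1),
    "overflow"
  )
})

test_that("count panels and scattered events agree by construction", {
  a <- sim_lattice(4, 4, seed = 5)
  p <- sim_counts(a, years = 3, base_rate = 2e-4, seed = 6)
  ev <- sim_events(p, a, seed = 7)
  expect_equal(nrow(ev), sum(p$counts))
  p2 <- aggregate_events(ev, a, years = p$years)
  expect_equal(p2$counts, p$counts)
  expect_equal(p2$unassigned, 0L)
  # determinism
  ev2 <- sim_events(p, a, seed = 7)
  expect_identical(ev, ev2)
})

test_that("Gaussian response generator attaches the true coefficient surfaces", {
  a <- sim_lattice(6, 6, seed = 1)
  a <- sim_covariates(a, "x1", range_m = 2000, seed = 2)
  d <- sim_response(a, coefs = list(x1 = surf_constant(0.7)), noise_sd = 0,
                    seed = 3)
  B <- attr(d, "true_coefs")
  expect_equal(colnames(B), c("intercept", "x1"))
  expect_equal(d$y, B[, "intercept"] + B[, "x1"] * d$x1)
})
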