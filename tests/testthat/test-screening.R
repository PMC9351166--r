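test_that("Pearson screen matches the product-moment formula by hand", {
  d <- tibble::tibble(x = 1:5, y = c(2, 4, 5, 4, 5))
  # explicit product-moment oracle
  r_hand <- sum((d$x - 3) * (d$y - 4)) /
    sqrt(sum((d$x - 3)^2) * sum((d$y - 4)^2))
  expect_equal(round(r_hand, 4), 0.7746)
  scr <- pearson_screen(d, "y", "x")
  expect_equal(scr$r, r_hand, tolerance = 1e-12)

  # perfect correlation retained, zero-variance column excluded with warning
  d2 <- tibble::tibble(y = rnorm(10))
  d2$x <- d2$y
  d2$z <- 5
  expect_warning(scr2 <- pearson_screen(d2, "y", c("x", "z")), "zero variance")
  expect_equal(scr2$stage, c("candidate", "pearson"))
  expect_equal(scr2$r[1], 1)
})

test_that("Pearson screen p-values are uniform under the null", {
  set.seed(31)
  reps <- 500
  rej <- vapply(1:reps, function(s) {
    d <- tibble::tibble(y = rnorm(30), x = rnorm(30))
    pearson_screen(d, "y", "x")$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("VIF equals 1/(1 - R2_j) against an lm oracle", {
  set.seed(32)
  n <- 60
  base <- rnorm(n)
  d <- tibble::tibble(a = base + rnorm(n, 0, 0.5),
                      b = base + rnorm(n, 0, 0.5),
                      c = rnorm(n))
  v <- vif(d)
  for (j in names(d)) {
    r2 <- summary(lm(reformulate(setdiff(names(d), j), j), data = d))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # centred, mutually orthogonal columns: VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(60), 20, 3))))[, 2:4]
  dd <- tibble::as_tibble(as.data.frame(Q))
  expect_equal(unname(vif(dd)), rep(1, 3), tolerance = 1e-10)
  # duplicated column: infinite VIF flagged, not an error
  d$dup <- d$a
  expect_true(any(is.infinite(vif(d))))
})

test_that("exploratory regression prunes collinearity and ranks subsets exactly", {
  set.seed(33)
  n <- 80
  x1 <- rnorm(n)
  d <- tibble::tibble(
    x1 = x1, x1dup = x1 + rnorm(n, 0, 0.01),  # r ~ 0.999
    x2 = rnorm(n), x3 = rnorm(n)
  )
  d$y <- 1.2 * d$x1 + 0.8 * d$x2 + rnorm(n, 0, 0.5)
  ex <- exploratory_regression(d, "y", c("x1", "x1dup", "x2", "x3"))
  expect_equal(length(intersect(c("x1", "x1dup"), ex$removed_collinearity)), 1)
  expect_true(any(c("x1", "x1dup") %in% ex$best_vars))
  expect_true("x2" %in% ex$best_vars)
  # ranking equals brute-force lm enumeration on a 3-variable case
  d3 <- tibble::tibble(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  d3$y <- 0.9 * d3$a + 0.4 * d3$b + rnorm(40, 0.3)
  ex3 <- exploratory_regression(d3, "y", c("a", "b", "c"), alpha = 1)
  ys <- drop(scale(d3$y))
  oracle <- vapply(strsplit(ex3$models$vars, "+", fixed = TRUE), function(ss) {
    summary(lm(ys ~ scale(as.matrix(d3[ss]))))$adj.r.squared
  }, numeric(1))
  expect_equal(ex3$models$adj_r2, oracle, tolerance = 1e-10)
  expect_true(all(diff(ex3$models$adj_r2[ex3$models$admissible]) <= 1e-12))
})

test_that("exploratory regression recovers a strong true predictor", {
  hits <- 0
  reps <- 50
  for (s in 1:reps) {
    set.seed(400 + s)
    n <- 100
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 5), n)))
    names(d) <- paste0("v", 1:5)
    d$y <- 1.5 * d$v1 + rnorm(n, 0, 0.8)
    ex <- exploratory_regression(d, "y", paste0("v", 1:5))
    if ("v1" %in% ex$best_vars) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("OLS agrees with the normal-equations oracle and prunes noise", {
  set.seed(34)
  n <- 140
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
  beta <- c(0.8, -0.5, 0.3, 0.2)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.6)
  d <- dplyr::bind_cols(tibble::as_tibble(X), y = y)
  f <- fit_ols(d, "y", paste0("v", 1:4), standardize = FALSE)
  # independent normal-equations oracle
  Xi <- cbind(1, X)
  bh <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(f$coef$estimate, unname(drop(bh)), tolerance = 1e-10)
  sm <- summary(lm(y ~ X))
  expect_equal(f$r2, sm$r.squared, tolerance = 1e-10)
  expect_equal(f$adj_r2, sm$adj.r.squared, tolerance = 1e-10)
  expect_equal(f$coef$std_error, unname(sm$coefficients[, 2]), tolerance = 1e-8)
  # recovery within 3 SE
  expect_true(all(abs(f$coef$estimate[-1] - beta) <=
                    3 * f$coef$std_error[-1]))
  # residuals sum to ~0 with intercept; adjusted R2 <= R2
  expect_lt(abs(sum(f$residuals)), 1e-8)
  expect_lte(f$adj_r2, f$r2)
})

test_that("perfect fits, singular designs, and all-noise pruning behave", {
  d <- tibble::tibble(x = rnorm(30))
  d$y <- 2 * d$x
  f <- fit_ols(d, "y", "x")  # standardized: slope exactly 1
  expect_equal(f$coef$estimate[2], 1, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  d$x2 <- d$x
  expect_error(fit_ols(d, "y", c("x", "x2")), "singular|standardize|dependent")

  # all-noise designs are pruned to (near-)empty models; with pruning at
  # alpha = 0.05 the chance that some noise column survives selection is
  # bounded below by 1 - 0.95^4 ~ 0.19, so "empty" happens in roughly 4 of
  # 5 replicates, not almost always
  empties <- 0
  reps <- 100
  for (s in 1:reps) {
    set.seed(600 + s)
    dn <- tibble::as_tibble(as.data.frame(matrix(rnorm(200), 50)))
    names(dn) <- paste0("n", 1:4)
    dn$y <- rnorm(50)
    fp <- fit_ols(dn, "y", paste0("n", 1:4), prune = TRUE)
    if (length(fp$vars) == 0) empties <- empties + 1
  }
  expect_gte(empties / reps, 0.8)
})

test_that("zero-count areas are excluded with a log and degenerate panels error", {
  a <- sim_lattice(3, 3, seed = 1)
  counts <- matrix(1L, 9, 2)
  counts[c(2, 5, 7), ] <- 0L
  p <- count_panel(counts, a$population, 1:2, a$area_id)
  expect_message(kept <- exclude_zero_count_areas(a, p), "n_excluded=3")
  expect_equal(nrow(kept), 6)
  expect_setequal(attr(kept, "excluded"), a$area_id[c(2, 5, 7)])
  # no zero areas: identity
  p2 <- count_panel(matrix(1L, 9, 2), a$population, 1:2, a$area_id)
  expect_equal(nrow(exclude_zero_count_areas(a, p2)), 9)
  # all-zero: nothing to model
  pz <- count_panel(matrix(0L, 9, 2), a$population, 1:2, a$area_id)
  expect_error(exclude_zero_count_areas(a, pz), "nothing to model")
})

test_that("the full cascade partitions variables and finds the active set", {
  hits <- 0
  reps <- 10
  partition_ok <- TRUE
  for (s in 1:reps) {
    set.seed(700 + s)
    a <- sim_lattice(12, 12, seed = 700 + s)
    vars <- paste0("v", 1:12)
    a <- sim_covariates(a, vars, range_m = 2500, seed = 800 + s)
    set.seed(900 + s)
    a$y <- 0.8 * a$v1 - 0.6 * a$v2 + 0.5 * a$v3 + 0.45 * a$v4 + rnorm(144, 0, 0.6)
    sc <- screen_variables(a, "y", vars)
    stages <- table(factor(sc$report$stage,
                           c("pearson", "collinearity", "subset-search", "ols",
                             "retained")))
    if (sum(stages) != length(vars)) partition_ok <- FALSE
    if (length(intersect(sc$report$variable[sc$report$stage == "retained"],
                         paste0("v", 1:4))) >= 3) hits <- hits + 1
  }
  expect_true(partition_ok)
  expect_gte(hits / reps, 0.8)
})
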