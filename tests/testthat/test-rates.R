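test_that("raw rates scale events by population and period pool", {
  p <- count_panel(matrix(c(6, 4, 0, 0, 3, 2), 3, 2), c(1e5, 5e4, 2e4), 1:2,
                   c("a", "b", "c"))
  r <- raw_rates(p)
  # hand-computed oracle: row sums (6, 7, 2) over pooled years
  expect_equal(r$raw_rate, c(6 / 1e5, 7 / 5e4, 2 / 2e4) * 1e5)
  expect_equal(r$events, c(6L, 7L, 2L))
  # zero events give zero, zero population is excluded with a log entry
  p0 <- count_panel(matrix(c(0, 5), 2, 1), c(1000, 0), 1, c("z", "w"))
  expect_message(r0 <- raw_rates(p0), "excluded_zero_population")
  expect_equal(r0$area_id, "z")
  expect_equal(r0$raw_rate, 0)
})

test_that("EB smoothing follows the method-of-moments estimator exactly", {
  # 4-area toy, formula-by-hand oracle
  O <- c(2, 0, 5, 1); n <- c(1000, 500, 2000, 800)
  r <- O / n
  m <- sum(O) / sum(n)
  A <- max(0, sum(n * (r - m)^2) / sum(n) - m / mean(n))
  w <- A / (A + m / n)
  eb_hand <- (w * r + (1 - w) * m) * 1e5
  got <- eb_smooth(setNames(O, paste0("a", 1:4)), n)
  expect_equal(got$eb_rate, eb_hand, tolerance = 1e-12)
  expect_equal(got$shrinkage_weight, w, tolerance = 1e-12)
  expect_true(all(got$shrinkage_weight >= 0 & got$shrinkage_weight <= 1))
})

test_that("EB degenerate and limit behaviour", {
  # identical raw rates: A = 0, everything shrunk exactly to m
  got <- eb_smooth(c(2, 4, 8), c(1000, 2000, 4000))
  expect_equal(unique(round(got$eb_rate, 10)), 2 / 1000 * 1e5)
  expect_equal(got$shrinkage_weight, rep(0, 3))
  # huge-population area keeps its raw rate (w -> 1)
  got2 <- eb_smooth(c(1000, 1, 3), c(1e9, 500, 900))
  expect_gt(got2$shrinkage_weight[1], 0.999)
  expect_equal(got2$eb_rate[1], got2$raw_rate[1], tolerance = 1e-3)
  expect_error(eb_smooth(c(1), c(100)), "at least 2")
})

test_that("EB rates stay between the raw rate and prior mean; shrinkage monotone in population", {
  set.seed(11)
  O <- rpois(30, 8); n <- sample(500:50000, 30)
  got <- eb_smooth(O, n)
  m <- sum(O) / sum(n) * 1e5
  expect_true(all(got$eb_rate >= pmin(got$raw_rate, m) - 1e-9))
  expect_true(all(got$eb_rate <= pmax(got$raw_rate, m) + 1e-9))
  # equal raw rates, different populations: smaller pop shrinks (weakly) more
  got2 <- eb_smooth(c(2, 20), c(1000, 10000))
  expect_equal(got2$raw_rate[1], got2$raw_rate[2])
  m2 <- sum(c(2, 20)) / 11000 * 1e5
  expect_lte(abs(got2$eb_rate[1] - m2), abs(got2$eb_rate[2] - m2) + 1e-12)
  expect_gte(got2$shrinkage_weight[2], got2$shrinkage_weight[1])
})

test_that("Jenks classification is exactly optimal", {
  jb <- jenks_breaks(c(1, 2, 10, 11), k = 2)
  expect_true(jb$breaks >= 2 && jb$breaks < 10)
  expect_equal(jb$labels, c(1L, 1L, 2L, 2L))
  # k = number of distinct values: singleton classes, zero within-class ss
  jb2 <- jenks_breaks(c(5, 1, 3), k = 3)
  expect_equal(jb2$wss, 0)
  expect_equal(sort(unique(jb2$labels)), 1:3)
  expect_error(jenks_breaks(c(1, 1, 2), k = 3), "distinct")
  # brute-force partition enumeration oracle on random values
  for (s in 1:5) {
    set.seed(s)
    v <- round(runif(8, 0, 100), 1)
    for (k in 2:4) {
      expect_equal(jenks_breaks(v, k)$wss, jenks_oracle(v, k), tolerance = 1e-9)
    }
  }
})

test_that("rate_table combines smoothing and classification", {
  a <- sim_lattice(6, 6, seed = 2)
  a <- sim_covariates(a, "v", range_m = 2500, seed = 4)
  # real between-area risk variation, so EB does not shrink everything to m
  p <- sim_counts(a, years = 5, base_rate = 5e-4,
                  coefs = list(v = surf_constant(0.6)), seed = 3)
  rt <- rate_table(p, k = 4)
  expect_tbl_cols(rt, c("area_id", "raw_rate", "eb_rate", "shrinkage_weight",
                        "class_label"))
  expect_equal(sort(unique(rt$class_label)), 1:4)
  expect_equal(length(attr(rt, "breaks")), 3)
  # labels ascend with eb_rate
  expect_true(all(diff(rt$class_label[order(rt$eb_rate)]) >= 0))
})
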