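#' Raw pooled-period event rates
#'
#' Rate per `per` persons over the pooled study period:
#' `rate_i = sum_t counts[i, t] / population_i * per`. Areas with zero
#' population are excluded with a logged entry.
#'
#' @param panel a [count_panel()].
#' @param per rate denominator scale (default events per 100,000 persons).
#' @return a tibble with `area_id`, `events`, `population`, `raw_rate`.
#' @export
raw_rates <- function(panel, per = 1e5) {
  keep <- panel$population > 0
  if (any(!keep)) {
    log_line("raw_rates", excluded_zero_population =
               paste(panel$area_id[!keep], collapse = ","))
  }
  tibble::tibble(
    area_id = panel$area_id[keep],
    events = unname(as.integer(rowSums(panel$counts))[keep]),
    population = panel$population[keep],
    raw_rate = unname(rowSums(panel$counts)[keep]) / panel$population[keep] * per
  )
}

#' Empirical Bayes rate smoothing
#'
#' Global (method-of-moments) empirical Bayes shrinkage of small-area rates
#' towards the overall prior mean, stabilizing rates in sparsely populated
#' areas. With observed counts `O_i` and populations `n_i` (`r_i = O_i /
#' n_i`): prior mean `m = sum(O) / sum(n)`; between-area variance `A =
#' max(0, sum(n_i (r_i - m)^2) / sum(n) - m / mean(n))`; shrinkage weight
#' `w_i = A / (A + m / n_i)`; smoothed rate `w_i r_i + (1 - w_i) m`. When
#' `A = 0` every area is shrunk fully to `m`.
#'
#' @param panel a [count_panel()], or a numeric vector of counts.
#' @param population per-area populations (only when `panel` is a vector).
#' @param per output rate scale (events per `per` persons).
#' @return a tibble with `area_id`, `events`, `population`, `raw_rate`,
#'   `eb_rate` and `shrinkage_weight` (in `[0, 1]`).
#' @export
eb_smooth <- function(panel, population = NULL, per = 1e5) {
  if (inherits(panel, "count_panel")) {
    O <- rowSums(panel$counts); n <- panel$population; id <- panel$area_id
  } else {
    O <- as.double(panel); n <- as.double(population)
    id <- names(panel) %||% paste0("A", seq_along(O))
  }
  keep <- n > 0
  if (any(!keep)) log_line("eb_smooth", excluded_zero_population = sum(!keep))
  O <- O[keep]; n <- n[keep]; id <- id[keep]
  if (length(O) < 2) abort("need at least 2 areas with positive population")
  if (sum(n) == 0) abort("total population is zero")
  r <- O / n
  m <- sum(O) / sum(n)
  A <- max(0, sum(n * (r - m)^2) / sum(n) - m / mean(n))
  w <- if (A == 0) rep(0, length(O)) else A / (A + m / n)
  eb <- w * r + (1 - w) * m
  tibble::tibble(
    area_id = id, events = as.integer(O), population = n,
    raw_rate = r * per, eb_rate = eb * per, shrinkage_weight = w
  )
}

#' Fisher-Jenks natural breaks classification
#'
#' Exact dynamic-programming minimization of the total within-class sum of
#' squared deviations over all partitions of the sorted values into `k`
#' contiguous classes. Labels are 1..k by ascending value.
#'
#' @param values numeric vector (at least `k` distinct values).
#' @param k number of classes (>= 2).
#' @return a list with `breaks` (the k - 1 interior class boundaries, taken
#'   as the upper value of each lower class), `labels` (integer class per
#'   input value) and `wss` (the optimal within-class sum of squares).
#' @export
jenks_breaks <- function(values, k = 5) {
  if (k < 2) abort("k must be >= 2")
  ux <- sort(unique(values))
  if (length(ux) < k) abort("need at least k distinct values")
  x <- sort(values)
  n <- length(x)
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  # ssq of x[i..j], prefix-sum form
  ssq <- function(i, j) {
    s <- cx[j] - if (i > 1) cx[i - 1] else 0
    s2 <- cx2[j] - if (i > 1) cx2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)     # cost[c, j]: best wss of x[1..j] in c classes
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1, j] <- ssq(1, j)
  if (k > 1) {
    for (cc in 2:k) {
      for (j in cc:n) {
        for (i in cc:j) {
          v <- cost[cc - 1, i - 1] + ssq(i, j)
          if (v < cost[cc, j]) { cost[cc, j] <- v; back[cc, j] <- i }
        }
      }
    }
  }
  # recover class start indices
  starts <- integer(k); j <- n
  for (cc in k:2) { starts[cc] <- back[cc, j]; j <- starts[cc] - 1L }
  starts[1] <- 1L
  breaks <- x[starts[-1] - 1L]  # upper value of each lower class
  labels <- findInterval(values, c(-Inf, breaks, Inf), left.open = TRUE)
  list(breaks = breaks, labels = as.integer(labels), wss = cost[k, n])
}

#' Full rate table with smoothing and classification
#'
#' Convenience wrapper combining [raw_rates()], [eb_smooth()] and
#' [jenks_breaks()] into the per-area table behind a smoothed-rate
#' choropleth.
#'
#' @param panel a [count_panel()].
#' @param k Jenks class count.
#' @param per rate scale.
#' @return the [eb_smooth()] tibble plus an integer `class_label` column
#'   (Jenks classes of the smoothed rate).
#' @export
rate_table <- function(panel, k = 5, per = 1e5) {
  out <- eb_smooth(panel, per = per)
  jb <- jenks_breaks(out$eb_rate, k = k)
  out$class_label <- jb$labels
  attr(out, "breaks") <- jb$breaks
  out
}
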