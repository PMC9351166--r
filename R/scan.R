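#' Discrete Poisson scan log-likelihood ratio
#'
#' For a candidate window with observed count `c`, expected count `e` (under
#' indirect standardization on person-time) and study total `C`:
#' `LLR = c log(c/e) + (C - c) log((C - c)/(C - e))` when the direction
#' condition holds (`c > e` for `"high"`, `c < e` for `"low"`), else 0.
#' Terms with `c = 0` or `c = C` use the `0 log 0 = 0` convention.
#'
#' @param c observed window count(s).
#' @param e expected window count(s), `0 < e < C`.
#' @param C total study count.
#' @param direction `"high"`, `"low"` or `"both"`.
#' @return LLR value(s), all `>= 0`.
#' @export
poisson_llr <- function(c, e, C, direction = c("high", "low", "both")) {
  direction <- match.arg(direction)
  if (any(e <= 0) || any(e >= C)) abort("expected counts must satisfy 0 < e < C")
  llr <- xlogxy(c, e) + xlogxy(C - c, C - e)
  ok <- switch(direction, high = c > e, low = c < e, both = c != e)
  llr * ok
}

scan_rr <- function(O, E, C) {
  rr <- (O / E) / ((C - O) / (C - E))
  rr[O >= C] <- Inf
  rr
}

new_scan_result <- function(tbl, type, C, n_sim, seed) {
  attr(tbl, "type") <- type
  attr(tbl, "C") <- C
  attr(tbl, "n_sim") <- n_sim
  attr(tbl, "seed") <- seed
  class(tbl) <- c("scan_result", class(tbl))
  tbl
}

# all contiguous year windows of length <= max_len: matrix with cols a, b
year_windows <- function(T, max_len) {
  out <- do.call(rbind, lapply(seq_len(max_len), function(len) {
    a <- seq_len(T - len + 1)
    cbind(a = a, b = a + len - 1)
  }))
  out
}

#' Purely temporal Poisson scan
#'
#' Scans all contiguous year intervals spanning at most `max_window_frac` of
#' the study period (time aggregation: 1 year) for an excess (or deficit) of
#' events relative to person-time. Expected counts are proportional to
#' person-time; Monte Carlo replicates redistribute the study total `C` over
#' the years multinomially with probabilities proportional to the
#' expectations, and `p = (1 + #{max LLR_sim >= LLR_obs}) / (n_sim + 1)`.
#'
#' @param panel a [count_panel()] with at least 2 years.
#' @param max_window_frac maximum window length as a fraction of the period.
#' @param n_sim Monte Carlo replicates (0 skips inference; `p` is `NA`).
#' @param seed integer seed.
#' @param direction `"high"`, `"low"` or `"both"`.
#' @return a `scan_result` tibble of non-overlapping ranked windows with
#'   columns `areas` (empty for temporal clusters), `year_start`, `year_end`,
#'   `observed`, `expected`, `oe`, `rr`, `llr`, `p`, `rank`.
#' @export
temporal_scan <- function(panel, max_window_frac = 0.5, n_sim = 999,
                          seed = NULL, direction = c("high", "low", "both")) {
  direction <- match.arg(direction)
  T <- length(panel$years)
  if (T < 2) abort("temporal scan needs at least 2 years")
  Ot <- colSums(panel$counts)
  C <- sum(Ot)
  empty <- tibble::tibble(
    areas = list(), year_start = integer(), year_end = integer(),
    observed = double(), expected = double(), oe = double(), rr = double(),
    llr = double(), p = double(), rank = integer()
  )
  if (C == 0) return(new_scan_result(empty, "temporal", 0, n_sim, seed))
  et <- rep(C / T, T)  # population constant over years: uniform person-time
  max_len <- max(1L, floor(max_window_frac * T))
  wins <- year_windows(T, max_len)
  cum <- c(0, cumsum(Ot)); ecum <- c(0, cumsum(et))
  Ow <- cum[wins[, "b"] + 1] - cum[wins[, "a"]]
  Ew <- ecum[wins[, "b"] + 1] - ecum[wins[, "a"]]
  llr <- poisson_llr(Ow, Ew, C, direction)
  ord <- order(llr, decreasing = TRUE)
  # greedy non-overlapping-in-time reporting
  chosen <- integer(0); used <- rep(FALSE, T)
  for (k in ord) {
    if (llr[k] <= 0) break
    span <- wins[k, "a"]:wins[k, "b"]
    if (!any(used[span])) { chosen <- c(chosen, k); used[span] <- TRUE }
  }
  if (!length(chosen)) return(new_scan_result(empty, "temporal", C, n_sim, seed))
  pvals <- rep(NA_real_, length(chosen))
  if (n_sim > 0) {
    if (!is.null(seed)) set.seed(seed)
    sims <- rmultinom(n_sim, C, et / sum(et))
    csims <- rbind(0, apply(sims, 2, cumsum))
    maxsim <- vapply(seq_len(n_sim), function(s) {
      Osw <- csims[wins[, "b"] + 1, s] - csims[wins[, "a"], s]
      max(poisson_llr(Osw, Ew, C, direction))
    }, numeric(1))
    pvals <- vapply(llr[chosen], function(l) (1 + sum(maxsim >= l)) / (n_sim + 1),
                    numeric(1))
  }
  out <- tibble::tibble(
    areas = rep(list(character(0)), length(chosen)),
    year_start = panel$years[wins[chosen, "a"]],
    year_end = panel$years[wins[chosen, "b"]],
    observed = Ow[chosen], expected = Ew[chosen],
    oe = Ow[chosen] / Ew[chosen],
    rr = scan_rr(Ow[chosen], Ew[chosen], C),
    llr = llr[chosen], p = pvals, rank = seq_along(chosen)
  )
  new_scan_result(out, "temporal", C, n_sim, seed)
}

#' Space-time Poisson scan (cylindrical windows)
#'
#' Kulldorff-style discrete Poisson scan over cylinders: circular spatial
#' windows grown around each area centroid over nearest-centroid areas until
#' they hold at most `max_pop_frac` of the total population, crossed with
#' contiguous year windows of at most `max_time_frac` of the period.
#' Expected counts are `C * person-time in cylinder / total person-time`.
#' Monte Carlo inference redistributes `C` multinomially over the area-year
#' cells with probabilities proportional to expectations; secondary clusters
#' are reported greedily provided they share no areas with a better-ranked
#' cluster.
#'
#' @param panel a [count_panel()].
#' @param areas the matching [area_table()] (for centroids).
#' @param max_pop_frac maximum fraction of the population in the spatial
#'   window, in `(0, 1]`.
#' @param max_time_frac maximum fraction of the study period in the time
#'   window.
#' @param n_sim Monte Carlo replicates (0 skips inference).
#' @param seed integer seed.
#' @param direction `"high"` (default), `"low"` or `"both"`.
#' @return a `scan_result` tibble as in [temporal_scan()], with `areas`
#'   holding the member area ids of each cylinder.
#' @export
spacetime_scan <- function(panel, areas, max_pop_frac = 0.5,
                           max_time_frac = 0.5, n_sim = 999, seed = NULL,
                           direction = c("high", "low", "both")) {
  direction <- match.arg(direction)
  if (max_pop_frac <= 0 || max_pop_frac > 1) {
    abort("configuration error: max_pop_frac must be in (0, 1]")
  }
  n <- nrow(panel$counts); T <- length(panel$years)
  if (n < 2 && T >= 2) {
    # degenerate single-area panel: purely temporal scan
    return(temporal_scan(panel, max_time_frac, n_sim, seed, direction))
  }
  C <- sum(panel$counts)
  empty <- tibble::tibble(
    areas = list(), year_start = integer(), year_end = integer(),
    observed = double(), expected = double(), oe = double(), rr = double(),
    llr = double(), p = double(), rank = integer()
  )
  if (C == 0) return(new_scan_result(empty, "space-time", 0, n_sim, seed))
  D <- centroid_distances(areas)
  pop <- panel$population
  Ptot <- sum(pop) * T
  max_len <- max(1L, floor(max_time_frac * T))
  wins <- year_windows(T, max_len)
  wlen <- wins[, "b"] - wins[, "a"] + 1
  # precompute, per centre: ordered areas and admissible ring count
  ords <- lapply(seq_len(n), function(i) order(D[i, ]))
  rmaxs <- vapply(seq_len(n), function(i) {
    cp <- cumsum(pop[ords[[i]]])
    r <- sum(cp <= max_pop_frac * sum(pop))
    max(r, 0L)
  }, numeric(1))
  # best cylinder per centre given a counts matrix; returns llr and window
  best_for_centre <- function(counts, i) {
    r <- rmaxs[i]
    if (r < 1) return(NULL)
    ord <- ords[[i]][seq_len(r)]
    M <- counts[ord, , drop = FALSE]
    Rcum <- apply(M, 2, cumsum)                 # rings x years (cum over rings)
    if (r == 1) Rcum <- matrix(Rcum, nrow = 1)
    Ycum <- cbind(0, t(apply(Rcum, 1, cumsum))) # rings x (years+1)
    O <- Ycum[, wins[, "b"] + 1, drop = FALSE] - Ycum[, wins[, "a"], drop = FALSE]
    cpop <- cumsum(pop[ord])
    E <- outer(cpop, wlen) * (C / Ptot)
    keep <- E > 0 & E < C
    llr <- matrix(0, nrow(O), ncol(O))
    llr[keep] <- poisson_llr(O[keep], E[keep], C, direction)
    k <- arrayInd(which.max(llr), dim(llr))
    list(llr = llr[k], ring = k[1], win = k[2], O = O[k], E = E[k],
         members = ord[seq_len(k[1])])
  }
  scan_max <- function(counts) {
    best <- -Inf
    for (i in seq_len(n)) {
      b <- best_for_centre(counts, i)
      if (!is.null(b) && b$llr > best) best <- b$llr
    }
    best
  }
  cands <- purrr::compact(lapply(seq_len(n), function(i) {
    b <- best_for_centre(panel$counts, i)
    if (!is.null(b)) b$centre <- i
    b
  }))
  if (!length(cands)) return(new_scan_result(empty, "space-time", C, n_sim, seed))
  cands <- cands[order(vapply(cands, `[[`, numeric(1), "llr"), decreasing = TRUE)]
  # greedy secondary reporting: no shared areas with a better-ranked cluster
  chosen <- list(); used <- rep(FALSE, n)
  for (b in cands) {
    if (b$llr <= 0) break
    if (!any(used[b$members])) {
      chosen[[length(chosen) + 1L]] <- b
      used[b$members] <- TRUE
    }
  }
  if (!length(chosen)) return(new_scan_result(empty, "space-time", C, n_sim, seed))
  pvals <- rep(NA_real_, length(chosen))
  if (n_sim > 0) {
    if (!is.null(seed)) set.seed(seed)
    cellp <- rep(pop, T) / (sum(pop) * T)
    maxsim <- vapply(seq_len(n_sim), function(s) {
      cnt <- matrix(rmultinom(1, C, cellp), n, T)
      scan_max(cnt)
    }, numeric(1))
    pvals <- vapply(chosen, function(b) (1 + sum(maxsim >= b$llr)) / (n_sim + 1),
                    numeric(1))
  }
  out <- tibble::tibble(
    areas = lapply(chosen, function(b) panel$area_id[b$members]),
    year_start = panel$years[wins[vapply(chosen, `[[`, numeric(1), "win"), "a"]],
    year_end = panel$years[wins[vapply(chosen, `[[`, numeric(1), "win"), "b"]],
    observed = vapply(chosen, `[[`, numeric(1), "O"),
    expected = vapply(chosen, `[[`, numeric(1), "E"),
    oe = vapply(chosen, function(b) b$O / b$E, numeric(1)),
    rr = vapply(chosen, function(b) scan_rr(b$O, b$E, C), numeric(1)),
    llr = vapply(chosen, `[[`, numeric(1), "llr"),
    p = pvals, rank = seq_along(chosen)
  )
  new_scan_result(out, "space-time", C, n_sim, seed)
}

#' Flat cluster report table
#'
#' The reporting vocabulary of scan results: per cluster, member areas,
#' window, observed (O), expected (E), O/E, relative risk, LLR and the Monte
#' Carlo p-value.
#'
#' @param clusters a `scan_result`.
#' @return a plain tibble with `areas` collapsed to a comma-separated string
#'   and an `n_areas` column.
#' @export
cluster_report <- function(clusters) {
  tibble::tibble(
    rank = clusters$rank,
    n_areas = lengths(clusters$areas),
    areas = vapply(clusters$areas, paste, character(1), collapse = ","),
    year_start = clusters$year_start, year_end = clusters$year_end,
    observed = clusters$observed, expected = clusters$expected,
    oe = clusters$oe, rr = clusters$rr, llr = clusters$llr, p = clusters$p
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Poisson", attr(x, "type"), "scan:", nrow(x), "cluster(s), C =",
      attr(x, "C"), "\n")
  print(cluster_report(x), ...)
  invisible(x)
}
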