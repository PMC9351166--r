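#' Global Moran's I
#'
#' The cross-product statistic `I = n / S0 * sum_ij w_ij z_i z_j / sum_i
#' z_i^2` with `z = x - mean(x)` and `S0 = sum_ij w_ij`; its expectation
#' under no spatial autocorrelation is `-1/(n-1)`. Inference is either the
#' analytic two-sided test under the randomization assumption, or a
#' permutation test that reshuffles `x` over the areas (two-sided on
#' `|I - E[I]|`), with `p = (1 + #{|I_perm - E| >= |I_obs - E|}) /
#' (n_perm + 1)`.
#'
#' @param x per-area values (variance > 0).
#' @param w a [build_weights()] object.
#' @param inference `"analytic"` (randomization variance) or `"permutation"`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation test.
#' @return an object of class `global_moran` with fields `I`, `expected`,
#'   `variance`, `z`, `p`, `method`, `n`.
#' @export
global_moran <- function(x, w, inference = c("analytic", "permutation"),
                         n_perm = 999, seed = NULL) {
  inference <- match.arg(inference)
  n <- length(x)
  if (n != length(w$neighbours)) abort("x length must match the weights")
  if (sd(x) == 0) abort("x is constant; Moran's I undefined (zero variance)")
  W <- weights_matrix(w)
  z <- x - mean(x)
  S0 <- sum(W)
  I_of <- function(zz) (n / S0) * as.numeric(zz %*% (W %*% zz)) / sum(zz^2)
  I <- I_of(z)
  E <- -1 / (n - 1)
  if (inference == "analytic") {
    S1 <- sum((W + Matrix::t(W))^2) / 2
    S2 <- sum((Matrix::rowSums(W) + Matrix::colSums(W))^2)
    b2 <- n * sum(z^4) / sum(z^2)^2
    num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
      b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
    V <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - E^2
    zs <- (I - E) / sqrt(V)
    p <- 2 * pnorm(-abs(zs))
    res <- list(I = I, expected = E, variance = V, z = zs, p = p,
                method = "analytic-randomization", n = n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    # vectorized: columns of Z are permutations of z
    Z <- vapply(seq_len(n_perm), function(k) z[sample.int(n)], numeric(n))
    Isim <- (n / S0) * colSums(Z * as.matrix(W %*% Z)) / sum(z^2)
    p <- (1 + sum(abs(Isim - E) >= abs(I - E))) / (n_perm + 1)
    V <- var(Isim)
    res <- list(I = I, expected = E, variance = V, z = (I - E) / sqrt(V), p = p,
                method = "permutation", n = n, n_perm = n_perm, seed = seed)
  }
  structure(res, class = "global_moran")
}

#' @export
print.global_moran <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (expected %.4f), z = %.2f, p = %.4g [%s]\n",
              x$I, x$expected, x$z, x$p, x$method))
  invisible(x)
}

#' Glance at a global Moran test
#' @param x a `global_moran`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.global_moran <- function(x, ...) {
  tibble::tibble(I = x$I, expected = x$expected, variance = x$variance,
                 z = x$z, p.value = x$p, method = x$method, n = x$n)
}

#' Anselin local Moran's I with conditional permutation inference
#'
#' Per-area decomposition `I_i = z_i / m2 * sum_j w_ij z_j` with `m2 =
#' sum(z^2) / n`. Significance is assessed by conditional permutation:
#' holding `x_i` fixed, the remaining values are randomly reassigned to its
#' neighbour slots; the two-sided pseudo p-value is `2 * min(p_low, p_high)`
#' (capped at 1), with each one-sided `p = (1 + #{extreme}) / (n_perm + 1)`.
#' Cluster/outlier quadrants come from the signs of `z_i` and the spatial lag
#' (HH, LL, HL, LH), masked to `"not-significant"` when the pseudo p exceeds
#' `alpha` (after optional Benjamini-Hochberg adjustment across areas).
#'
#' Under row-standardized weights `mean(I_i)` equals the global I exactly.
#'
#' @param x per-area values.
#' @param w a [build_weights()] object.
#' @param n_perm conditional permutations per area.
#' @param seed integer seed.
#' @param alpha significance level for quadrant masking.
#' @param fdr apply Benjamini-Hochberg adjustment across areas before
#'   masking.
#' @return a tibble with `area_id`, `I_i`, `pseudo_p` (and `pseudo_p_adj` if
#'   `fdr`), `quadrant`; permutation settings are kept as attributes.
#' @export
local_moran <- function(x, w, n_perm = 999, seed = NULL, alpha = 0.05,
                        fdr = FALSE) {
  n <- length(x)
  if (n != length(w$neighbours)) abort("x length must match the weights")
  if (sd(x) == 0) abort("x is constant; local Moran undefined")
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- vapply(seq_len(n), function(i) {
    sum(w$weights[[i]] * z[w$neighbours[[i]]])
  }, numeric(1))
  Ii <- z * lag / m2
  if (!is.null(seed)) set.seed(seed)
  pseudo_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    k <- length(w$neighbours[[i]])
    if (k == 0) next
    zi <- z[-i]
    wi <- w$weights[[i]]
    sims <- vapply(seq_len(n_perm), function(s) {
      sum(wi * zi[sample.int(n - 1, k)])
    }, numeric(1)) * z[i] / m2
    p_hi <- (1 + sum(sims >= Ii[i])) / (n_perm + 1)
    p_lo <- (1 + sum(sims <= Ii[i])) / (n_perm + 1)
    pseudo_p[i] <- min(1, 2 * min(p_hi, p_lo))
  }
  p_mask <- if (fdr) p.adjust(pseudo_p, "BH") else pseudo_p
  quad <- dplyr::case_when(
    z > 0 & lag > 0 ~ "HH",
    z < 0 & lag < 0 ~ "LL",
    z > 0 & lag <= 0 ~ "HL",
    TRUE ~ "LH"
  )
  quad[is.na(p_mask) | p_mask > alpha] <- "not-significant"
  out <- tibble::tibble(area_id = w$area_id, I_i = Ii, pseudo_p = pseudo_p,
                        quadrant = quad)
  if (fdr) out$pseudo_p_adj <- p_mask
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  class(out) <- c("local_moran_tbl", class(out))
  out
}

#' Moran test of regression residuals
#'
#' [global_moran()] applied to the residuals of a fitted model — the
#' diagnostic used to decide whether an aspatial OLS fit leaves spatially
#' structured error (motivating GWR/MGWR).
#'
#' @param fit an `ols_fit`, `gwr_fit`, `mgwr_fit`, `lm`, or a numeric vector
#'   of residuals.
#' @param w a [build_weights()] object.
#' @param ... passed to [global_moran()].
#' @return a `global_moran` object.
#' @export
residual_moran <- function(fit, w, ...) {
  r <- if (is.numeric(fit)) fit else stats::residuals(fit)
  global_moran(r, w, ...)
}
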