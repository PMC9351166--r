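# Geographically weighted regression with an adaptive bisquare kernel and
# golden-section AICc bandwidth search, plus the multiscale (per-term
# bandwidth) variant calibrated by backfitting. Local fits are weighted
# least squares; the hat (smoother) matrix S gives the effective number of
# parameters trace(S), the corrected AIC, and the adjusted local inference
# (adjusted alpha, adjusted critical t).

#' Bisquare kernel weights
#'
#' `w = (1 - (d / b)^2)^2` for `d < b`, else 0; `w = 1` at `d = 0`. For the
#' adaptive kernel, `b` is the distance to the k-th nearest neighbour of the
#' calibration site (self included), so the kernel's support adapts to the
#' local density of sites.
#'
#' @param d distances from the calibration site, metres.
#' @param b local bandwidth (> 0), metres.
#' @return weights in `[0, 1]`.
#' @export
bisquare_weights <- function(d, b) {
  if (b <= 0) abort("bisquare bandwidth is 0 (duplicate centroids?); use a larger k")
  ifelse(d < b, (1 - (d / b)^2)^2, 0)
}

# per-site adaptive bandwidths: distance to the k-th nearest (self included)
adaptive_bw <- function(Dsort, k) Dsort[, k]

# one multivariate GWR calibration at fixed adaptive k.
# X includes the intercept column. Returns local coefficients, their
# covariance-based SEs, hat diagonal, trace(S), RSS and local R^2.
gwr_fit_k <- function(X, y, D, Dsort, k, kernel = "bisquare", need_local_r2 = TRUE) {
  n <- length(y); p <- ncol(X)
  beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  se_raw <- matrix(NA_real_, n, p)  # sqrt(diag(C C')) pre-sigma
  hat <- numeric(n)
  local_r2 <- rep(NA_real_, n)
  bws <- adaptive_bw(Dsort, k)
  for (i in seq_len(n)) {
    w <- if (kernel == "uniform") rep(1, n) else bisquare_weights(D[i, ], bws[i])
    Xw <- X * w
    XtWX <- crossprod(X, Xw)
    M <- tryCatch(solve(XtWX, t(Xw)), error = function(e) NULL)  # C = (X'WX)^-1 X'W
    if (is.null(M)) {
      abort(paste0("singular local design at site ", i, "; use a larger k"))
    }
    b <- drop(M %*% y)
    beta[i, ] <- b
    hat[i] <- drop(X[i, ] %*% M[, i])
    se_raw[i, ] <- sqrt(rowSums(M^2))
    if (need_local_r2) {
      fit_i <- drop(X %*% b)
      ybar_w <- sum(w * y) / sum(w)
      tss <- sum(w * (y - ybar_w)^2)
      local_r2[i] <- if (tss > 0) 1 - sum(w * (y - fit_i)^2) / tss else NA_real_
    }
  }
  fitted <- rowSums(X * beta)
  res <- y - fitted
  rss <- sum(res^2)
  list(beta = beta, se_raw = se_raw, hat = hat, tr_s = sum(hat), rss = rss,
       fitted = fitted, residuals = res, local_r2 = local_r2, k = k)
}

# golden-section search over integer k in [lo, hi] minimizing f(k), with
# memoization; stops when the bracket is <= 1 neighbour wide
golden_int_search <- function(f, lo, hi) {
  memo <- new.env(parent = emptyenv())
  fm <- function(k) {
    key <- as.character(k)
    if (is.null(memo[[key]])) memo[[key]] <- f(k)
    memo[[key]]
  }
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  while (b - a > 2) {
    g <- round(phi * (b - a))
    c1 <- max(a + 1, b - g)
    d1 <- min(b - 1, a + g)
    if (c1 >= d1) {            # narrow bracket: fall back to a midpoint pair
      c1 <- a + (b - a) %/% 2
      d1 <- c1 + 1
    }
    if (fm(c1) <= fm(d1)) b <- d1 else a <- c1
  }
  ks <- seq(a, b)
  vals <- vapply(ks, fm, numeric(1))
  best <- ks[which.min(vals)]
  list(k = best, value = min(vals), evaluated = length(ls(memo)))
}

#' Fit a geographically weighted regression
#'
#' At every site, weighted least squares with adaptive bisquare kernel
#' weights gives local coefficients `beta_j(u_i, v_i)`; the single shared
#' neighbour count `k` is chosen by golden-section search minimizing the
#' corrected AIC, `AICc = 2n log(sigma_hat) + n log(2*pi) + n (n + tr(S)) /
#' (n - 2 - tr(S))` with `sigma_hat^2 = RSS / n`. Coefficient standard
#' errors use `RSS / (n - tr(S))`. Local inference is corrected for the
#' effective number of tests: `adj_alpha = alpha (p + 1) / tr(S)` and the
#' adjusted critical t is the two-sided Student-t quantile at `adj_alpha`
#' with `n - tr(S)` degrees of freedom.
#'
#' @param data data frame carrying the response, covariates and coordinates.
#' @param response response column name.
#' @param vars covariate column names.
#' @param coords two-column matrix of site coordinates, or `NULL` to use
#'   `centroid_x`/`centroid_y` columns.
#' @param k adaptive neighbour count; `NULL` (default) searches
#'   `[p + 2, n]` by golden section.
#' @param kernel `"bisquare"` (default) or `"uniform"` (all weights 1 — a
#'   debug kernel under which GWR reproduces global OLS exactly).
#' @param standardize z-standardize response and covariates (default).
#' @param alpha nominal significance level behind the adjusted alpha.
#' @return a `gwr_fit`: local coefficient/SE/pseudo-t matrices, `bandwidth`,
#'   `trace_s`, `aicc`/`aic`/`bic`, `r2`, `adj_r2`, `sigma`, `local_r2`,
#'   `adj_alpha`, `adj_critical_t`, residuals and fitted values.
#' @export
fit_gwr <- function(data, response, vars, coords = NULL, k = NULL,
                    kernel = c("bisquare", "uniform"), standardize = TRUE,
                    alpha = 0.05) {
  kernel <- match.arg(kernel)
  n <- nrow(data)
  if (is.null(coords)) coords <- cbind(data$centroid_x, data$centroid_y)
  if (anyDuplicated(coords)) warn("duplicate site coordinates present")
  y <- data[[response]]
  X <- as.matrix(tibble::as_tibble(data)[vars])
  if (standardize) {
    y <- drop(standardize_cols(matrix(y, dimnames = list(NULL, response))))
    X <- standardize_cols(X)
  }
  Xi <- cbind(intercept = 1, X)
  p <- ncol(Xi)
  if (n <= p + 2) abort("need n > p + 2 sites")
  D <- as.matrix(dist(coords))
  Dsort <- t(apply(D, 1, sort))
  lo <- p + 2; hi <- n
  if (is.null(k)) {
    search <- golden_int_search(function(kk) {
      f <- gwr_fit_k(Xi, y, D, Dsort, kk, kernel, need_local_r2 = FALSE)
      aicc_gauss(f$rss, n, f$tr_s)
    }, lo, hi)
    k <- search$k
  }
  fit <- gwr_fit_k(Xi, y, D, Dsort, k, kernel)
  tr_s <- fit$tr_s
  sigma2_se <- fit$rss / (n - tr_s)
  se <- fit$se_raw * sqrt(sigma2_se)
  tval <- fit$beta / se
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - fit$rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - tr_s - 1)
  adj_alpha <- min(1, alpha * p / tr_s)
  structure(list(
    bandwidth = k, kernel = kernel, terms = colnames(Xi),
    coefficients = fit$beta, std_errors = se, pseudo_t = tval,
    hat = fit$hat, trace_s = tr_s,
    rss = fit$rss, r2 = r2, adj_r2 = adj_r2,
    sigma = sqrt(fit$rss / n), sigma_se = sqrt(sigma2_se),
    aicc = aicc_gauss(fit$rss, n, tr_s), aic = aic_gauss(fit$rss, n, tr_s),
    bic = bic_gauss(fit$rss, n, tr_s), loglik = gauss_loglik(fit$rss, n),
    df = n - tr_s, adj_alpha = adj_alpha,
    adj_critical_t = critical_t(adj_alpha, n - tr_s),
    local_r2 = fit$local_r2, residuals = fit$residuals, fitted = fit$fitted,
    n = n, response = response, vars = vars, standardized = standardize,
    area_id = data$area_id %||% as.character(seq_len(n))
  ), class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf(
    "GWR fit: %d sites, adaptive k = %d, trace(S) = %.3f\n  R2 = %.3f, adj R2 = %.3f, AICc = %.3f, adj critical t = %.3f\n",
    x$n, x$bandwidth, x$trace_s, x$r2, x$adj_r2, x$aicc, x$adj_critical_t))
  invisible(x)
}

#' @export
residuals.gwr_fit <- function(object, ...) object$residuals

#' Two-sided Student-t critical value at an adjusted alpha
#'
#' `qt(1 - adj_alpha / 2, df)` — the threshold against which local pseudo-t
#' surfaces are judged after correcting the significance level for the
#' effective number of parameters.
#'
#' @param adj_alpha adjusted significance level in `(0, 1]`.
#' @param df degrees of freedom (> 0; may be fractional, `n - tr(S)`).
#' @return the critical value (0 when `adj_alpha = 1`).
#' @export
critical_t <- function(adj_alpha, df) {
  if (df <= 0) abort("df must be > 0")
  qt(1 - adj_alpha / 2, df)
}
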