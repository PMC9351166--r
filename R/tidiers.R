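#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an OLS fit
#' @param x an `ols_fit`.
#' @param ... unused.
#' @return a tibble with one row per term: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.ols_fit <- function(x, ...) x$coef

#' Glance at an OLS fit
#' @param x an `ols_fit`.
#' @param ... unused.
#' @return a one-row tibble of model-level diagnostics.
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, adj_r2 = x$adj_r2, sigma = x$sigma, loglik = x$loglik,
    aic = x$aic, aicc = x$aicc, bic = x$bic, rss = x$rss,
    enp = x$enp, n = x$n
  )
}

#' Tidy a GWR or MGWR fit into per-area local coefficients
#'
#' One row per area and term: local estimate, standard error, pseudo-t and a
#' significance flag at the model's adjusted critical t.
#'
#' @param x a `gwr_fit` or `mgwr_fit`.
#' @param ... unused.
#' @return a long tibble with `area_id`, `term`, `estimate`, `std_error`,
#'   `pseudo_t`, `significant`, `local_r2`.
#' @export
tidy.gwr_fit <- function(x, ...) {
  crit <- if (length(x$adj_critical_t) > 1) {
    x$adj_critical_t[col(x$pseudo_t)]
  } else {
    x$adj_critical_t
  }
  tibble::tibble(
    area_id = rep(x$area_id, times = length(x$terms)),
    term = rep(x$terms, each = x$n),
    estimate = as.vector(x$coefficients),
    std_error = as.vector(x$std_errors),
    pseudo_t = as.vector(x$pseudo_t),
    significant = abs(as.vector(x$pseudo_t)) > as.vector(crit),
    local_r2 = rep(x$local_r2, times = length(x$terms))
  )
}

#' @rdname tidy.gwr_fit
#' @export
tidy.mgwr_fit <- tidy.gwr_fit

#' Glance at a GWR fit
#' @param x a `gwr_fit`.
#' @param ... unused.
#' @return a one-row tibble mirroring the standard GWR diagnostics block
#'   (RSS, trace(S), df, R2, adjusted R2, sigma, log-likelihood, AIC, AICc,
#'   BIC, adjusted alpha, adjusted critical t).
#' @export
glance.gwr_fit <- function(x, ...) {
  tibble::tibble(
    bandwidth = x$bandwidth, rss = x$rss, trace_s = x$trace_s, df = x$df,
    r2 = x$r2, adj_r2 = x$adj_r2, sigma = x$sigma, loglik = x$loglik,
    aic = x$aic, aicc = x$aicc, bic = x$bic,
    adj_alpha = x$adj_alpha[1], adj_critical_t = x$adj_critical_t[1],
    n = x$n
  )
}

#' Glance at an MGWR fit
#' @param x an `mgwr_fit`.
#' @param ... unused.
#' @return a one-row tibble: GWR diagnostics plus backfitting metadata
#'   (`iterations`, `converged`).
#' @export
glance.mgwr_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, trace_s = x$trace_s, df = x$df,
    r2 = x$r2, adj_r2 = x$adj_r2, sigma = x$sigma, loglik = x$loglik,
    aic = x$aic, aicc = x$aicc, bic = x$bic,
    iterations = x$iterations, converged = x$converged, n = x$n
  )
}

#' Per-term MGWR summary
#'
#' Bandwidth, effective parameters, adjusted inference threshold and the
#' distribution of each local coefficient surface — the per-term summary
#' table conventionally reported for a multiscale fit.
#'
#' @param x an `mgwr_fit`.
#' @return a tibble with one row per term.
#' @export
mgwr_term_summary <- function(x) {
  tibble::tibble(
    term = x$terms,
    bandwidth = unname(x$bandwidths),
    enp = unname(x$enp),
    adj_alpha = unname(x$adj_alpha),
    adj_critical_t = unname(x$adj_critical_t),
    mean = colMeans(x$coefficients),
    sd = apply(x$coefficients, 2, sd),
    min = apply(x$coefficients, 2, min),
    median = apply(x$coefficients, 2, stats::median),
    max = apply(x$coefficients, 2, max)
  )
}
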