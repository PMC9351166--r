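#' @importFrom rlang abort warn inform %||%
#' @importFrom stats lm cor.test qt pt pnorm quantile rnorm runif rpois sd var
#'   complete.cases coef dist p.adjust rmultinom setNames
#' @importFrom utils combn head
NULL

# x * log(x / y) with the 0 * log 0 = 0 convention; x, y vectorized
xlogxy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos] / y[pos])
  out
}

#' Percentage change between two values
#'
#' Relative change expressed in percent. `reference = "first"` is the usual
#' convention, 100 * (b - a) / a; `reference = "last"` divides by the later
#' value instead, 100 * (b - a) / b, a convention sometimes seen in applied
#' reports when a change "by year Y" is quoted against year Y itself.
#'
#' @param a,b the earlier and later value.
#' @param reference which value the change is expressed relative to.
#' @return a single number, in percent.
#' @export
#' @examples
#' pct_change(57, 84)          # +47.4%
#' pct_change(57, 84, "last")  # +32.1%
pct_change <- function(a, b, reference = c("first", "last")) {
  reference <- match.arg(reference)
  denom <- if (reference == "first") a else b
  if (denom == 0) abort("percentage change undefined: reference value is 0")
  100 * (b - a) / denom
}

# Deterministic per-stage seed derivation: one global seed reproduces the
# whole pipeline. Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}

# Structured log line used across the pipeline: key=value pairs
log_line <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0(
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " stage=", stage,
    if (length(kv)) paste0(" ", paste(names(kv), unlist(kv), sep = "=", collapse = " ")) else ""
  )
  inform(msg, class = "spatepi_log")
  invisible(msg)
}

# Gaussian log-likelihood and information criteria shared by OLS/GWR/MGWR so
# models are compared on one scale. sigma2 = RSS/n; enp = trace of the hat
# matrix (p + 1 for OLS).
gauss_loglik <- function(rss, n) -(n / 2) * (log(2 * pi) + log(rss / n) + 1)

aicc_gauss <- function(rss, n, enp) {
  sigma <- sqrt(rss / n)
  2 * n * log(sigma) + n * log(2 * pi) + n * (n + enp) / (n - 2 - enp)
}

aic_gauss <- function(rss, n, enp) -2 * gauss_loglik(rss, n) + 2 * (enp + 1)
bic_gauss <- function(rss, n, enp) -2 * gauss_loglik(rss, n) + log(n) * (enp + 1)

# z-standardize columns of a data frame / matrix; constant columns error
standardize_cols <- function(m) {
  m <- as.matrix(m)
  s <- apply(m, 2, sd)
  if (any(s == 0)) {
    abort(paste0("cannot standardize constant column(s): ",
                 paste(colnames(m)[s == 0], collapse = ", ")))
  }
  scale(m)[, , drop = FALSE]
}
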