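# Variable-selection cascade: Pearson screen -> iterative VIF gate ->
# all-subsets exploratory regression -> OLS with p-value pruning. All fits
# run on z-standardized variables, matching the near-zero intercepts and
# comparable coefficient magnitudes of the motivating analysis.

# fast standardized least squares; X without intercept column
ols_core <- function(X, y) {
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrx$pivot[seq(qrx$rank + 1, ncol(Xi))]]
    abort(paste0("singular design; linearly dependent column(s): ",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(Xi %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  p <- ncol(Xi)
  df <- n - p
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(
    coef = tibble::tibble(term = colnames(Xi), estimate = unname(beta),
                          std_error = unname(se), statistic = unname(tval),
                          p_value = unname(pval)),
    residuals = res, fitted = fitted, rss = rss, r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
    aicc = aicc_gauss(rss, n, p), aic = aic_gauss(rss, n, p),
    bic = bic_gauss(rss, n, p), loglik = gauss_loglik(rss, n),
    sigma = sqrt(rss / n), n = n, enp = p
  )
}

# VIFs of standardized columns via the inverse correlation matrix
vif_std <- function(Xs) {
  if (ncol(Xs) < 2) return(setNames(rep(1, ncol(Xs)), colnames(Xs)))
  R <- crossprod(Xs) / (nrow(Xs) - 1)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    return(setNames(rep(Inf, ncol(Xs)), colnames(Xs)))
  }
  v <- diag(inv)
  v[v > 1e12] <- Inf
  setNames(v, colnames(Xs))
}

#' Pearson correlation screen
#'
#' Stage 1 of the selection cascade: each candidate variable is tested for
#' product-moment correlation with the response (two-sided t test); variables
#' with `p > alpha` are excluded.
#'
#' @param data data frame holding response and candidates.
#' @param response response column name (e.g. the smoothed rate).
#' @param vars candidate variable names; defaults to all numeric columns
#'   other than the response.
#' @param alpha significance cut-off.
#' @return a tibble with `variable`, `r`, `p_value` and `stage`
#'   (`"pearson"` for exclusions, `"candidate"` for survivors).
#' @export
pearson_screen <- function(data, response, vars = NULL, alpha = 0.05) {
  vars <- vars %||% setdiff(
    names(data)[vapply(data, is.numeric, logical(1))],
    c(response, "centroid_x", "centroid_y", "area_km2", "population")
  )
  y <- data[[response]]
  if (length(y) < 3) abort("need at least 3 observations")
  rows <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    if (sd(x) == 0) {
      warn(paste0("variable '", v, "' has zero variance; excluded"))
      return(tibble::tibble(variable = v, r = NA_real_, p_value = NA_real_,
                            stage = "pearson"))
    }
    ct <- cor.test(x, y)
    tibble::tibble(variable = v, r = unname(ct$estimate),
                   p_value = ct$p.value,
                   stage = ifelse(ct$p.value > alpha, "pearson", "candidate"))
  })
  rows
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column j on the remaining
#' columns (with intercept). Perfectly collinear columns report `Inf`.
#'
#' @param data data frame.
#' @param vars columns to assess; defaults to all numeric columns.
#' @return a named numeric vector of VIFs.
#' @export
vif <- function(data, vars = NULL) {
  vars <- vars %||% names(data)[vapply(data, is.numeric, logical(1))]
  X <- as.matrix(tibble::as_tibble(data)[vars])
  if (nrow(X) <= ncol(X)) abort("need more observations than variables for VIF")
  vif_std(standardize_cols(X))
}

#' Exploratory regression with a VIF gate
#'
#' Two passes. Pass A removes collinear variables: while the largest VIF in
#' the full model exceeds `vif_thresh`, the worst variable is dropped and
#' VIFs recomputed. Pass B enumerates all subsets of the survivors up to
#' `max_size` and keeps models in which every coefficient is significant at
#' `alpha` and every VIF is at most `vif_thresh`; admissible models are
#' ranked by adjusted R-squared (ties by AICc, then lexicographic variable
#' order).
#'
#' @param data data frame (variables are z-standardized internally).
#' @param response response column name.
#' @param vars candidate variable names.
#' @param vif_thresh collinearity gate (default 7.5).
#' @param max_size largest subset size searched; default `min(6, #vars)`.
#' @param alpha coefficient significance requirement.
#' @return a list with `best_vars`, `models` (ranked admissible subsets),
#'   `removed_collinearity` (pass-A exclusions) and `removed_subset` (pass-B
#'   exclusions).
#' @export
exploratory_regression <- function(data, response, vars, vif_thresh = 7.5,
                                   max_size = NULL, alpha = 0.05) {
  y <- drop(standardize_cols(matrix(data[[response]], dimnames = list(NULL, response))))
  Xall <- standardize_cols(as.matrix(tibble::as_tibble(data)[vars]))
  # pass A: iterative largest-VIF-first removal
  removed_a <- character(0)
  keep <- vars
  repeat {
    v <- vif_std(Xall[, keep, drop = FALSE])
    if (length(keep) < 2 || max(v) <= vif_thresh) break
    worst <- names(v)[which.max(v)]
    removed_a <- c(removed_a, worst)
    keep <- setdiff(keep, worst)
  }
  max_size <- min(max_size %||% 6L, length(keep), nrow(Xall) - 2L)
  if (max_size < 1) {
    return(list(best_vars = character(0),
                models = tibble::tibble(vars = character(), size = integer(),
                                        adj_r2 = double(), aicc = double(),
                                        max_p = double(), max_vif = double(),
                                        admissible = logical()),
                removed_collinearity = removed_a,
                removed_subset = keep))
  }
  # pass B: exhaustive subsets of the survivors
  subsets <- unlist(lapply(seq_len(max_size), function(s) {
    combn(sort(keep), s, simplify = FALSE)
  }), recursive = FALSE)
  rows <- purrr::map_dfr(subsets, function(ss) {
    fit <- ols_core(Xall[, ss, drop = FALSE], y)
    slope_p <- fit$coef$p_value[-1]
    vifs <- vif_std(Xall[, ss, drop = FALSE])
    tibble::tibble(
      vars = paste(ss, collapse = "+"), size = length(ss),
      adj_r2 = fit$adj_r2, aicc = fit$aicc,
      max_p = max(slope_p), max_vif = max(vifs),
      admissible = all(slope_p <= alpha) && all(vifs <= vif_thresh)
    )
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$admissible),
                         dplyr::desc(.data$adj_r2), .data$aicc, .data$vars)
  best <- if (nrow(rows) && rows$admissible[1]) {
    strsplit(rows$vars[1], "+", fixed = TRUE)[[1]]
  } else {
    character(0)
  }
  if (!length(best)) {
    log_line("exploratory_regression", admissible_models = 0)
  }
  list(
    best_vars = best,
    models = rows,
    removed_collinearity = removed_a,
    removed_subset = setdiff(keep, best)
  )
}

#' Ordinary least squares with optional backward pruning
#'
#' Least squares on z-standardized response and covariates. With
#' `prune = TRUE`, terms with `p > alpha` are dropped one at a time (largest
#' p first) and the model refit, yielding the final geographic variable set.
#'
#' @param data data frame.
#' @param response response column name.
#' @param vars covariate names.
#' @param standardize z-standardize response and covariates (default).
#' @param prune backward-prune non-significant terms.
#' @param alpha pruning significance level.
#' @return an `ols_fit` object (see [tidy.ols_fit()], [glance.ols_fit()]):
#'   coefficient table, `r2`, `adj_r2`, `aicc`/`aic`/`bic`, residuals,
#'   per-covariate `vif`, the retained `vars` and `dropped` terms.
#' @export
fit_ols <- function(data, response, vars, standardize = TRUE, prune = FALSE,
                    alpha = 0.05) {
  if (length(data[[response]]) <= length(vars) + 1) {
    abort("need n > p + 1 observations")
  }
  y <- data[[response]]
  X <- as.matrix(tibble::as_tibble(data)[vars])
  if (standardize) {
    y <- drop(standardize_cols(matrix(y, dimnames = list(NULL, response))))
    X <- standardize_cols(X)
  }
  dropped <- character(0)
  keep <- vars
  repeat {
    fit <- ols_core(X[, keep, drop = FALSE], y)
    if (!prune || length(keep) == 0) break
    slope_p <- setNames(fit$coef$p_value[-1], keep)
    if (!length(slope_p) || max(slope_p) <= alpha) break
    worst <- names(slope_p)[which.max(slope_p)]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  fit$vars <- keep
  fit$dropped <- dropped
  fit$vif <- if (length(keep) >= 1) vif_std(X[, keep, drop = FALSE]) else numeric(0)
  fit$standardized <- standardize
  fit$response <- response
  class(fit) <- "ols_fit"
  fit
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %d terms, R2 = %.3f, adj R2 = %.3f, AICc = %.2f\n",
              length(x$vars), x$r2, x$adj_r2, x$aicc))
  print(x$coef)
  invisible(x)
}

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' Exclude areas with zero pooled event counts
#'
#' Areas where no events occurred over the whole study period are treated as
#' outliers and removed before the regression stages (OLS/GWR/MGWR); the
#' removal list is logged and attached.
#'
#' @param areas an [area_table()].
#' @param panel the matching [count_panel()].
#' @return the filtered area table, with attribute `"excluded"` holding the
#'   removed ids.
#' @export
exclude_zero_count_areas <- function(areas, panel) {
  tot <- rowSums(panel$counts)
  if (all(tot == 0)) abort("all areas have zero counts; nothing to model")
  drop_ids <- panel$area_id[tot == 0]
  if (length(drop_ids)) {
    log_line("exclude_zero_count_areas", n_excluded = length(drop_ids),
             excluded = paste(drop_ids, collapse = ","))
  }
  out <- areas[!areas$area_id %in% drop_ids, , drop = FALSE]
  attr(out, "excluded") <- drop_ids
  out
}

#' Run the full variable-selection cascade
#'
#' Pearson screen, iterative VIF gate, all-subsets search, then OLS backward
#' pruning — assigning every input variable exactly one removal stage,
#' mirroring the status coding of a screening table: `"pearson"`,
#' `"collinearity"`, `"subset-search"`, `"ols"` or `"retained"`.
#'
#' @inheritParams exploratory_regression
#' @param pearson_alpha stage-1 significance cut-off.
#' @return a list with `report` (tibble: `variable`, `r`, `p_value`,
#'   `stage`), `ols` (the final pruned `ols_fit`) and `exploratory` (the
#'   pass-B model ranking).
#' @export
screen_variables <- function(data, response, vars, pearson_alpha = 0.05,
                             vif_thresh = 7.5, max_size = NULL, alpha = 0.05) {
  scr <- pearson_screen(data, response, vars, alpha = pearson_alpha)
  cand <- scr$variable[scr$stage == "candidate"]
  ex <- exploratory_regression(data, response, cand, vif_thresh = vif_thresh,
                               max_size = max_size, alpha = alpha)
  ols <- if (length(ex$best_vars)) {
    fit_ols(data, response, ex$best_vars, prune = TRUE, alpha = alpha)
  } else {
    NULL
  }
  retained <- if (is.null(ols)) character(0) else ols$vars
  stage <- dplyr::case_when(
    scr$stage == "pearson" ~ "pearson",
    scr$variable %in% ex$removed_collinearity ~ "collinearity",
    scr$variable %in% retained ~ "retained",
    !is.null(ols) & scr$variable %in% ols$dropped ~ "ols",
    TRUE ~ "subset-search"
  )
  list(
    report = tibble::tibble(variable = scr$variable, r = scr$r,
                            p_value = scr$p_value, stage = stage),
    ols = ols,
    exploratory = ex
  )
}
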