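#' Fit a single-predictor GLM of a network metric on a landscape metric
#'
#' One intercept-plus-slope model per (response, predictor) pair, fitted by
#' iteratively reweighted least squares via [stats::glm()]: identity-link
#' Gaussian for continuous responses, log-link Poisson for counts (network
#' size). Rows with a missing response or predictor are dropped listwise.
#'
#' @param data Data frame of runs (e.g. from [run_experiment()]).
#' @param response,predictor Column names.
#' @param family `"gaussian"` or `"poisson"`.
#' @return One-row tibble: `response`, `predictor`, `family`, `estimate`,
#'   `std_error`, `statistic` (t for Gaussian, z for Poisson), `p_value`,
#'   `n`.
#' @export
fit_single_glm <- function(data, response, predictor,
                           family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  y <- data[[response]]
  x <- data[[predictor]]
  if (is.null(y) || is.null(x)) {
    stop(sprintf("columns '%s' and '%s' must both exist", response, predictor),
         call. = FALSE)
  }
  ok <- stats::complete.cases(y, x)
  y <- y[ok]
  x <- x[ok]
  if (length(y) < 3L) {
    stop("need at least 3 complete observations", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop(sprintf("predictor '%s' has zero variance", predictor),
         call. = FALSE)
  }
  if (family == "poisson" &&
      (any(y < 0) || any(abs(y - round(y)) > 1e-8))) {
    stop("Poisson family requires non-negative integer responses",
         call. = FALSE)
  }
  fam <- if (family == "gaussian") gaussian() else poisson()
  fit <- glm(y ~ x, family = fam)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    response = response,
    predictor = predictor,
    family = family,
    estimate = sm["x", 1],
    std_error = sm["x", 2],
    statistic = sm["x", 3],
    p_value = sm["x", 4],
    n = length(y)
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are used for ties; the p-value uses the t approximation
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom
#' (two-sided).
#'
#' @param x,y Equal-length numeric vectors (pairs with missing values are
#'   dropped; at least 3 complete pairs required).
#' @return List with `r`, `p`, `n`. A constant vector gives `r = NA` with a
#'   warning.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Regression and correlation analysis of an experiment table
#'
#' Fits the 30 single-predictor GLMs — five network responses (connectance,
#' nestedness, H2', network size, asymmetry) on six landscape predictors
#' (PLAND, AREA_MN, AREA_AM, SHAPE_MN, SHAPE_AM, CONNECT) — with Gaussian
#' errors except network size, which is Poisson, and computes the pairwise
#' Spearman correlation matrix of the six landscape metrics.
#'
#' @param results A [run_experiment()] table.
#' @return List with `models` (30-row tibble from [fit_single_glm()]) and
#'   `correlations` (list of 6 x 6 matrices `r` and `p`, plus `n`).
#' @examples
#' \donttest{
#' res <- run_experiment(experiment_design(cover_levels = c(0.2, 0.5, 0.8),
#'                                         n_replicates = 2))
#' an <- analyze_experiment(res)
#' an$models[an$models$response == "h2", ]
#' }
#' @export
analyze_experiment <- function(results) {
  responses <- c("connectance", "nestedness", "h2", "size", "asymmetry")
  predictors <- c("pland", "area_mn", "area_am", "shape_mn", "shape_am",
                  "connect")
  models <- dplyr::bind_rows(lapply(responses, function(resp) {
    fam <- if (resp == "size") "poisson" else "gaussian"
    dplyr::bind_rows(lapply(predictors, function(pred) {
      tryCatch(
        fit_single_glm(results, resp, pred, family = fam),
        error = function(e) {
          stop(sprintf("model %s ~ %s failed: %s", resp, pred,
                       conditionMessage(e)), call. = FALSE)
        }
      )
    }))
  }))

  k <- length(predictors)
  r_mat <- matrix(NA_real_, k, k, dimnames = list(predictors, predictors))
  p_mat <- r_mat
  diag(r_mat) <- 1
  diag(p_mat) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sc <- suppressWarnings(
        spearman_cor(results[[predictors[i]]], results[[predictors[j]]])
      )
      r_mat[i, j] <- r_mat[j, i] <- sc$r
      p_mat[i, j] <- p_mat[j, i] <- sc$p
    }
  }
  list(models = models,
       correlations = list(r = r_mat, p = p_mat, n = nrow(results)))
}
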