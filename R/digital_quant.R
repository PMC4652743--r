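#' Construct a dilution series
#'
#' @param d Dilution factors in (0, 1] relative to one cell-equivalent.
#' @param k Positive reactions per dilution.
#' @param N Total reactions per dilution (scalar or vector).
#' @param target Target label.
#' @return A `dilution_series` data frame.
#' @export
dilution_series <- function(d, k, N, target = "target") {
  if (!length(d)) stop("empty dilution series", call. = FALSE)
  if (any(d <= 0 | d > 1)) stop("'d' must lie in (0, 1]", call. = FALSE)
  N <- rep_len(as.integer(N), length(d))
  if (any(N < 1)) stop("'N' must be >= 1", call. = FALSE)
  if (any(k < 0 | k > N)) stop("'k' must satisfy 0 <= k <= N", call. = FALSE)
  out <- data.frame(target = target, d = d, k = as.integer(k), N = N)
  class(out) <- c("dilution_series", "data.frame")
  out
}

#' Poisson error estimate of a positive-reaction frequency
#'
#' Standard error of the observed positive fraction `k/N` computed from the
#' number of positive reactions: `sqrt(k)/N`, with a one-count floor of
#' `1/N` when `k = 0`.
#'
#' @param k Number of positive reactions (vectorized).
#' @param N Total number of reactions.
#' @return Standard error(s) of the frequency.
#' @export
#' @examples
#' poisson_error(9, 18)   # 0.1667
#' poisson_error(0, 18)   # 1/18 floor
poisson_error <- function(k, N) {
  if (any(N <= 0)) stop("'N' must be positive", call. = FALSE)
  if (any(k < 0 | k > N)) stop("'k' must satisfy 0 <= k <= N", call. = FALSE)
  ifelse(k == 0, 1 / N, sqrt(k) / N)
}

#' Fit per-cell copy number from a limiting-dilution series
#'
#' Estimates the mean template copies per cell-equivalent, lambda, by
#' least-squares fitting of the observed positive fractions `k/N` to the
#' Poisson zero-class model `P(positive) = 1 - exp(-lambda * d)` over the
#' dilution factors `d`.  The sum of squared frequency residuals is
#' minimized over lambda >= 0 by a bounded one-dimensional search (coarse
#' log-grid bracketing followed by golden-section refinement).
#'
#' @param series A `dilution_series` (columns `d`, `k`, `N`).
#' @param weighted If `TRUE`, weight residuals by `1/SE^2` with SE from
#'   [poisson_error()]; the default (`FALSE`) is plain least squares on the
#'   frequency scale.
#' @param lambda_max Upper search bound for lambda.
#' @return A `lambda_fit` list: `lambda_hat`, `residual_ss`, `fitted`
#'   (predicted frequency per dilution), `se` (frequency standard errors),
#'   `lower_bound` (`TRUE` when every reaction was positive so lambda is
#'   only bounded from below), and the input `series`.
#' @export
#' @examples
#' s <- dilution_series(d = 1, k = 9, N = 18)
#' fit_lambda(s)$lambda_hat      # -log(1 - 0.5) ~ 0.693
fit_lambda <- function(series, weighted = FALSE, lambda_max = 1e4) {
  if (!all(c("d", "k", "N") %in% names(series)))
    stop("series must have columns d, k, N", call. = FALSE)
  if (!nrow(series)) stop("empty dilution series", call. = FALSE)
  d <- series$d; k <- series$k; N <- series$N
  if (any(d <= 0 | d > 1)) stop("'d' must lie in (0, 1]", call. = FALSE)
  freq <- k / N
  se <- poisson_error(k, N)
  w <- if (weighted) 1 / se^2 else rep(1, length(d))
  ssr <- function(lambda) sum(w * (freq - (1 - exp(-lambda * d)))^2)

  lower_bound <- all(k == N)
  if (all(k == 0)) {
    lam <- 0
  } else {
    # coarse log-grid bracket, then golden-section refinement
    grid <- c(0, 10^seq(-4, log10(lambda_max), length.out = 300))
    pred <- 1 - exp(-outer(grid, d))
    res2 <- (matrix(freq, nrow = length(grid), ncol = length(d),
                    byrow = TRUE) - pred)^2
    vals <- as.vector(res2 %*% w)
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    lam <- optimize(ssr, interval = c(lo, hi), tol = 1e-10)$minimum
    if (ssr(0) <= ssr(lam)) lam <- 0
  }
  structure(list(
    lambda_hat = lam,
    residual_ss = ssr(lam),
    fitted = 1 - exp(-lam * d),
    se = se,
    lower_bound = lower_bound,
    weighted = weighted,
    series = series
  ), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("<lambda_fit> lambda_hat = %.4g copies/cell (RSS %.4g, %d dilutions)%s\n",
              x$lambda_hat, x$residual_ss, nrow(x$series),
              if (x$lower_bound) " [lower bound: all reactions positive]" else ""))
  invisible(x)
}

#' Parametric-bootstrap goodness of fit for the Poisson dilution model
#'
#' Simulates `B` replicate series from the fitted zero-class model
#' (`k* ~ Binomial(N, 1 - exp(-lambda_hat * d))`), refits lambda to each,
#' and returns the bootstrap p-value of the observed residual sum of
#' squares: `p = (1 + #{RSS* >= RSS_obs}) / (B + 1)`.  A close fit (large
#' p) supports single-molecule Poisson detection.
#'
#' @param series A `dilution_series`.
#' @param fit A `lambda_fit` for `series`; refitted if missing.
#' @param B Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @return A list with `p_value`, `rss_obs`, `lambda_hat` and `B`.
#' @export
poisson_gof <- function(series, fit = fit_lambda(series), B = 500,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(series) < 2)
    return(list(p_value = 1, rss_obs = fit$residual_ss,
                lambda_hat = fit$lambda_hat, B = 0L))
  d <- series$d; N <- series$N
  p_pos <- 1 - exp(-fit$lambda_hat * d)
  rss_boot <- vapply(seq_len(B), function(b) {
    kb <- rbinom(length(d), size = N, prob = p_pos)
    fit_lambda(dilution_series(d, kb, N))$residual_ss
  }, 0)
  list(p_value = (1 + sum(rss_boot >= fit$residual_ss)) / (B + 1),
       rss_obs = fit$residual_ss, lambda_hat = fit$lambda_hat, B = B)
}
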