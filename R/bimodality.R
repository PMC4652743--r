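#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and any unimodal CDF (convex up to the mode, concave
#' after, an atom permitted at the mode).  Large values indicate departure
#' from unimodality.  Computed in C by the iterative greatest-convex-
#' minorant / least-concave-majorant algorithm; for an n-point sample with
#' at least two distinct values the statistic lies in [1/(2n), 1/4] and is
#' invariant to strictly increasing transforms of the data.
#'
#' @param x Numeric sample, n >= 2, all values finite.
#' @return A `dip_result` list: `dip` (the statistic), `n`, and
#'   `modal_interval` (the modal interval located on the data scale).
#' @export
#' @examples
#' dip_statistic(c(0, 1))$dip                 # 0.25, the two-point maximum
#' dip_statistic(rnorm(100))$dip              # small: unimodal
dip_statistic <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (length(x) < 2) stop("'x' must have at least 2 values", call. = FALSE)
  if (any(!is.finite(x))) stop("'x' contains non-finite values", call. = FALSE)
  r <- .Call(C_dipstat, as.double(sort(x)))
  structure(list(dip = r[1], n = length(x),
                 modal_interval = c(r[2], r[3])),
            class = "dip_result")
}

#' Hartigan's dip test of unimodality
#'
#' Bootstrap p-value for the dip statistic against the least-favorable
#' unimodal null: `B` samples of size n are drawn from Uniform(0, 1), and
#' `p = (1 + #\{D_b >= D\}) / (B + 1)`.  Small p declares the sample's
#' distribution (e.g. per-cell transcript abundance across colonies)
#' significantly non-unimodal, i.e. at least bimodal.
#'
#' @param x Numeric sample, n >= 4.
#' @param B Number of bootstrap replicates (default 2000); values below 100
#'   give unreliable p-values and raise a warning.
#' @param seed Optional integer seed for the bootstrap.
#' @param null_dips Optional pre-computed vector of null dip statistics for
#'   samples of size `length(x)`; when supplied the bootstrap is skipped,
#'   which makes large calibration studies cheap.
#' @return A `dip_result` list with `dip`, `p_value`, `n`, `B` and
#'   `modal_interval`.
#' @export
#' @examples
#' dip_test(runif(50), B = 200, seed = 1)$p_value             # large
#' dip_test(c(rnorm(50), rnorm(50, 8)), B = 200, seed = 1)$p_value  # tiny
dip_test <- function(x, B = 2000, seed = NULL, null_dips = NULL) {
  if (length(x) < 4) stop("'x' must have at least 4 values", call. = FALSE)
  res <- dip_statistic(x)
  n <- res$n
  if (is.null(null_dips)) {
    if (B < 100)
      warning("B < 100 bootstrap replicates: p-value is unreliable")
    if (!is.null(seed)) set.seed(seed)
    null_dips <- vapply(seq_len(B),
                        function(b) .Call(C_dipstat, sort(runif(n)))[1], 0)
  } else {
    B <- length(null_dips)
  }
  res$p_value <- (1 + sum(null_dips >= res$dip)) / (B + 1)
  res$B <- as.integer(B)
  res
}

#' Null dip distribution for a given sample size
#'
#' Draws `B` dip statistics of Uniform(0, 1) samples of size `n`, for reuse
#' across many [dip_test()] calls at the same n.
#'
#' @param n Sample size.
#' @param B Number of replicates.
#' @param seed Optional integer seed.
#' @return Numeric vector of `B` null dip statistics.
#' @export
dip_null_distribution <- function(n, B = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(B), function(b) .Call(C_dipstat, sort(runif(n)))[1], 0)
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("<dip_result> dip = %.4g (n = %d)", x$dip, x$n))
  if (!is.null(x$p_value))
    cat(sprintf(", bootstrap P = %.4g (B = %d)", x$p_value, x$B))
  cat(sprintf("\n  modal interval: [%.4g, %.4g]\n",
              x$modal_interval[1], x$modal_interval[2]))
  invisible(x)
}
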