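#' GAPDH-gate an abundance matrix and normalize areas per cell
#'
#' Only reactions with a detected GAPDH peak are considered successful
#' assays of live cells; all other samples are removed.  Peak areas of the
#' retained samples are divided by the sample's cell count, giving per-cell
#' normalized abundance.
#'
#' @param matrix An `abundance_matrix` from [collapse_to_matrix()] (raw
#'   areas).
#' @return An `abundance_matrix` of gated samples whose target columns hold
#'   per-cell normalized areas, with a `gapdh_positive` column (all `TRUE`).
#' @export
gate_and_normalize <- function(matrix) {
  targets <- intersect(ALL_TARGETS, names(matrix))
  if (!("GAPDH" %in% targets))
    stop("abundance matrix has no GAPDH column", call. = FALSE)
  areas <- as.matrix(matrix[, targets, drop = FALSE])
  bad <- matrix$cells == 0 & rowSums(areas) > 0
  if (any(bad))
    stop("sample(s) with zero cells but nonzero areas: ",
         paste(matrix$sample_id[bad], collapse = ", "), call. = FALSE)
  keep <- matrix$GAPDH > 0
  out <- matrix[keep, , drop = FALSE]
  out[, targets] <- out[, targets] / out$cells
  out$gapdh_positive <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("abundance_matrix", "data.frame")
  out
}

total_htert <- function(matrix)
  rowSums(as.matrix(matrix[, intersect(hTERT_VARIANTS, names(matrix)),
                           drop = FALSE]))

#' Splice-variant co-occurrence per colony
#'
#' For every hTERT-positive sample of the requested day, computes the
#' dominant-variant fraction (largest variant abundance over total hTERT
#' abundance) and the number of distinct variants detected, ordered by
#' decreasing total hTERT.  On day 0, when nearly all samples are single
#' cells, exclusive bursting makes the dominant fraction close to 1.
#'
#' @param matrix A gated, normalized `abundance_matrix`.
#' @param day Culture day to analyze (default: all days present).
#' @return Data frame with `sample_id`, `day`, `condition`, `cells`,
#'   `total_htert`, `dominant_variant`, `dominant_fraction`, `n_variants`.
#' @export
cooccurrence <- function(matrix, day = NULL) {
  if (!is.null(day)) matrix <- matrix[matrix$day %in% day, , drop = FALSE]
  vm <- as.matrix(matrix[, hTERT_VARIANTS, drop = FALSE])
  tot <- rowSums(vm)
  pos <- tot > 0
  m <- matrix[pos, , drop = FALSE]
  vm <- vm[pos, , drop = FALSE]
  tot <- tot[pos]
  out <- data.frame(
    sample_id = m$sample_id,
    day = m$day,
    condition = m$condition,
    cells = m$cells,
    total_htert = tot,
    dominant_variant = hTERT_VARIANTS[max.col(vm, ties.method = "first")],
    dominant_fraction = apply(vm, 1, max) / tot,
    n_variants = rowSums(vm > 0)
  )
  out <- out[order(-out$total_htert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-colony growth rates and between-condition comparison
#'
#' Computes per-colony exponential growth rates
#' `rate = ln(cells_to / cells_from) / (day_to - day_from)` (per day) from
#' ground-truth or counted colony sizes, the implied doubling times, and a
#' Welch two-tailed t-test of rate differences between conditions when two
#' conditions are present.  Colonies with a zero count at either day are
#' skipped.
#'
#' @param truth Data frame with columns `droplet_id`, `condition`, `day`,
#'   `cell_count` (e.g. the `truth` element of
#'   [simulate_colony_experiment()]).
#' @param day_from,day_to Days delimiting the growth interval.
#' @return A list with `rates` (per-colony data frame incl.
#'   `doubling_time_h`), `summary` (per-condition mean rate and doubling
#'   time) and `p_value` (Welch t-test; `NA` with fewer than two
#'   conditions).
#' @export
growth_rates <- function(truth, day_from = 0, day_to = 2) {
  a <- truth[truth$day == day_from, c("droplet_id", "condition", "cell_count")]
  b <- truth[truth$day == day_to, c("droplet_id", "cell_count")]
  mg <- merge(a, b, by = "droplet_id", suffixes = c("_from", "_to"))
  mg <- mg[mg$cell_count_from > 0 & mg$cell_count_to > 0, , drop = FALSE]
  span <- day_to - day_from
  rates <- data.frame(
    droplet_id = mg$droplet_id,
    condition = mg$condition,
    rate_per_day = log(mg$cell_count_to / mg$cell_count_from) / span
  )
  rates$doubling_time_h <- 24 * log(2) / rates$rate_per_day
  conds <- unique(rates$condition)
  smry <- if (length(conds)) do.call(rbind, lapply(conds, function(cc) {
    r <- rates$rate_per_day[rates$condition == cc]
    data.frame(condition = cc, n = length(r), mean_rate_per_day = mean(r),
               doubling_time_h = 24 * log(2) / mean(r))
  })) else data.frame(condition = character(), n = integer(),
                      mean_rate_per_day = numeric(),
                      doubling_time_h = numeric())
  p <- NA_real_
  if (length(conds) == 2) {
    g1 <- rates$rate_per_day[rates$condition == conds[1]]
    g2 <- rates$rate_per_day[rates$condition == conds[2]]
    if (length(g1) >= 2 && length(g2) >= 2) {
      p <- if (isTRUE(all.equal(g1[order(g1)], g2[order(g2)]))) 1 else
        t.test(g1, g2)$p.value
    }
  }
  list(rates = rates, summary = smry, p_value = p)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples: the U statistic for the first group
#' and a two-sided p-value, computed exactly when the combined sample size
#' is at most 20 and tie-free, and by the tie-corrected normal
#' approximation (with continuity correction) otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list with `U`, `p_value` and `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = min(1, wt$p.value),
       method = if (exact) "exact enumeration" else
         "tie-corrected normal approximation")
}

#' Day-to-day fold change with Mann-Whitney significance
#'
#' The fold change of a target between two culture days is the ratio of the
#' mean per-cell normalized abundances,
#' `FC = mean(day_to) / mean(day_from)`.  A change is called significant
#' when the two-sided Mann-Whitney p-value is at or below `p_threshold`
#' (statistical significance) and the fold change exceeds `fc_bounds[2]` or
#' falls below `fc_bounds[1]` (biological relevance).  When the day-from
#' mean is zero the fold change is undefined (`defined = FALSE`) and no
#' call is made.
#'
#' @param matrix A gated, normalized `abundance_matrix` containing both
#'   days.
#' @param target Target column to analyze (one of `ALL_TARGETS`).
#' @param condition Optional condition filter (e.g. `"curcumin"`).
#' @param day_from,day_to Days compared (defaults 1 and 2).
#' @param p_threshold Mann-Whitney significance threshold (default 0.01).
#' @param fc_bounds Biological-relevance bounds (default `c(0.5, 2)`).
#' @return A `fold_change_result` one-row data frame: `target`,
#'   `condition`, `n_day1`, `n_day2`, `mean_day1`, `mean_day2`,
#'   `fold_change`, `mw_u`, `mw_p`, `significant`, `defined`.
#' @export
fold_change_analysis <- function(matrix, target, condition = NULL,
                                 day_from = 1, day_to = 2,
                                 p_threshold = 0.01, fc_bounds = c(0.5, 2)) {
  if (!(target %in% names(matrix)))
    stop("unknown target: ", target, call. = FALSE)
  if (!is.null(condition))
    matrix <- matrix[matrix$condition == condition, , drop = FALSE]
  x1 <- matrix[matrix$day == day_from, target]
  x2 <- matrix[matrix$day == day_to, target]
  m1 <- if (length(x1)) mean(x1) else 0
  m2 <- if (length(x2)) mean(x2) else 0
  defined <- length(x1) > 0 && m1 > 0
  fc <- if (defined) m2 / m1 else NA_real_
  if (length(x1) && length(x2)) {
    mw <- mann_whitney_u(x1, x2)
  } else {
    mw <- list(U = NA_real_, p_value = NA_real_)
  }
  significant <- isTRUE(defined && !is.na(mw$p_value) &&
                          mw$p_value <= p_threshold &&
                          (fc > fc_bounds[2] || fc < fc_bounds[1]))
  out <- data.frame(
    target = target,
    condition = if (is.null(condition)) "all" else condition,
    n_day1 = length(x1), n_day2 = length(x2),
    mean_day1 = m1, mean_day2 = m2,
    fold_change = fc,
    mw_u = mw$U, mw_p = mw$p_value,
    significant = significant,
    defined = defined
  )
  class(out) <- c("fold_change_result", "data.frame")
  out
}

#' Squared Pearson correlation between two targets across colonies
#'
#' Used to verify the independence of co-amplified targets (e.g. hTR vs
#' total hTERT, where minimal correlation indicates no amplification
#' competition).
#'
#' @param matrix A gated, normalized `abundance_matrix` (>= 3 samples).
#' @param target_x,target_y Target columns, or `"total_hTERT"` for the sum
#'   of the four splice variants.
#' @return Squared Pearson correlation, or `NA` when either target has
#'   zero variance.
#' @export
expression_correlation <- function(matrix, target_x = "hTR",
                                   target_y = "total_hTERT") {
  get_col <- function(tg)
    if (tg == "total_hTERT") total_htert(matrix) else {
      if (!(tg %in% names(matrix))) stop("unknown target: ", tg, call. = FALSE)
      matrix[[tg]]
    }
  x <- get_col(target_x); y <- get_col(target_y)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}
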