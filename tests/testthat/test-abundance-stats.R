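toy_matrix <- function(rows) {
  out <- do.call(rbind, lapply(rows, function(r) {
    base <- data.frame(sample_id = r$id, day = r$day %||% 0,
                       condition = r$condition %||% "control",
                       cells = r$cells %||% 1L)
    areas <- setNames(rep(0, length(ALL_TARGETS)), ALL_TARGETS)
    areas[names(r$areas)] <- r$areas
    cbind(base, as.data.frame(as.list(areas), check.names = FALSE))
  }))
  class(out) <- c("abundance_matrix", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("GAPDH gating and per-cell normalization", {
  m <- toy_matrix(list(
    list(id = "a", cells = 4L, areas = c(GAPDH = 200, hTR = 1000)),
    list(id = "b", cells = 2L, areas = c(hTR = 500)),      # GAPDH-negative
    list(id = "c", cells = 1L, areas = c(GAPDH = 50, `a+b-` = 120))))
  g <- gate_and_normalize(m)
  expect_setequal(g$sample_id, c("a", "c"))
  expect_equal(g$hTR[g$sample_id == "a"], 1000 / 4)
  expect_equal(g$GAPDH[g$sample_id == "a"], 50)
  expect_equal(g$`a+b-`[g$sample_id == "c"], 120)
  expect_true(all(g$gapdh_positive))

  # all GAPDH-negative: empty matrix, downstream ops work without error
  m2 <- toy_matrix(list(list(id = "a", areas = c(hTR = 10))))
  g2 <- gate_and_normalize(m2)
  expect_equal(nrow(g2), 0)
  expect_equal(nrow(cooccurrence(g2)), 0)
  fc <- fold_change_analysis(g2, "hTR")
  expect_false(fc$defined)

  m3 <- toy_matrix(list(list(id = "a", cells = 0L, areas = c(GAPDH = 10))))
  expect_error(gate_and_normalize(m3), "zero cells")
})

test_that("co-occurrence summarizes dominant variants", {
  m <- toy_matrix(list(
    list(id = "a", areas = c(GAPDH = 10, `a+b-` = 300)),
    list(id = "b", areas = c(GAPDH = 10, `a+b-` = 100, `a-b-` = 100)),
    list(id = "c", areas = c(GAPDH = 10))))
  co <- cooccurrence(gate_and_normalize(m))
  expect_equal(nrow(co), 2)            # hTERT-negative sample dropped
  expect_equal(co$dominant_fraction[co$sample_id == "a"], 1)
  expect_equal(co$n_variants[co$sample_id == "a"], 1)
  expect_equal(co$dominant_fraction[co$sample_id == "b"], 0.5)
  expect_equal(co$n_variants[co$sample_id == "b"], 2)
  # ordered by decreasing total hTERT
  expect_equal(co$sample_id, c("a", "b"))
})

test_that("simulated day-0 single cells express predominantly one variant", {
  co <- cooccurrence(cached_gated(1)$gated, day = 0)
  expect_gte(median(co$dominant_fraction), 0.9)
  expect_equal(median(co$n_variants), 1)
})

test_that("growth rates and doubling times", {
  tr <- data.frame(droplet_id = c(1, 1), condition = "control",
                   day = c(0, 2), cell_count = c(1, 4))
  gr <- growth_rates(tr)
  expect_equal(gr$rates$doubling_time_h, 24)
  # identical rate vectors in both conditions -> p = 1
  tr2 <- rbind(
    data.frame(droplet_id = 1:4, condition = "control", day = 0, cell_count = 1),
    data.frame(droplet_id = 1:4, condition = "control", day = 2,
               cell_count = c(2, 4, 4, 8)),
    data.frame(droplet_id = 5:8, condition = "curcumin", day = 0, cell_count = 1),
    data.frame(droplet_id = 5:8, condition = "curcumin", day = 2,
               cell_count = c(2, 4, 4, 8)))
  expect_equal(growth_rates(tr2)$p_value, 1)
})

test_that("curcumin at unit growth multiplier leaves growth unchanged", {
  ps <- vapply(1:8, function(seed) {
    t1 <- cached_gated(seed, n_droplets = 500)$truth
    t2 <- cached_gated(seed + 50, n_droplets = 500, curcumin = TRUE)$truth
    growth_rates(rbind(t1, t2))$p_value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.85)
})

test_that("Mann-Whitney U: exact enumeration and approximations", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)     # 2/C(6,3) * ... exact two-sided
  expect_match(r$method, "exact")

  a <- c(1, 2, 3, 4)
  r2 <- mann_whitney_u(a, a)
  expect_equal(r2$U, length(a)^2 / 2)
  expect_equal(r2$p_value, 1)

  set.seed(8)
  r3 <- mann_whitney_u(rnorm(50), rnorm(50) + 3)
  expect_lt(r3$p_value, 1e-6)
  expect_match(r3$method, "normal")

  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
})

test_that("fold-change calls combine the P and FC rules", {
  mk <- function(v1, v2) toy_matrix(c(
    lapply(seq_along(v1), function(i)
      list(id = paste0("d1_", i), day = 1, areas = c(GAPDH = 1, hTR = v1[i]))),
    lapply(seq_along(v2), function(i)
      list(id = paste0("d2_", i), day = 2, areas = c(GAPDH = 1, hTR = v2[i])))))
  set.seed(2)
  base <- rlnorm(30, log(10), 0.05)
  up3 <- rlnorm(30, log(30), 0.05)
  up15 <- rlnorm(30, log(15), 0.05)
  fc3 <- fold_change_analysis(gate_and_normalize(mk(base, up3)), "hTR")
  expect_true(fc3$significant)
  expect_equal(fc3$fold_change, 3, tolerance = 0.05)
  # FC 1.5 is below the biological-relevance bound even at tiny p
  fc15 <- fold_change_analysis(gate_and_normalize(mk(base, up15)), "hTR")
  expect_lt(fc15$mw_p, 0.001)
  expect_false(fc15$significant)
  # day-1 mean zero: undefined, no call
  fc0 <- fold_change_analysis(gate_and_normalize(mk(rep(0, 30), up3)), "hTR")
  expect_false(fc0$defined)
  expect_false(fc0$significant)
})

test_that("fold-change analysis is scale invariant", {
  g <- cached_gated(1)$gated
  f1 <- fold_change_analysis(g, "a+b-")
  g2 <- g
  g2[, ALL_TARGETS] <- g2[, ALL_TARGETS] * 137
  f2 <- fold_change_analysis(g2, "a+b-")
  expect_equal(f2$fold_change, f1$fold_change)
  expect_equal(f2$mw_p, f1$mw_p)
  expect_equal(f2$significant, f1$significant)
})

test_that("expression correlation handles exact and degenerate cases", {
  m <- toy_matrix(lapply(1:5, function(i)
    list(id = paste0("s", i), areas = c(GAPDH = 1, hTR = i * 10,
                                        `a+b-` = i * 20))))
  g <- gate_and_normalize(m)
  expect_equal(expression_correlation(g, "hTR", "a+b-"), 1)
  g$hTR <- 5
  expect_true(is.na(expression_correlation(g, "hTR", "a+b-")))
  expect_error(expression_correlation(g[1:2, ], "hTR", "a+b-"), "3 samples")
})

test_that("curcumin pipeline flags both alpha-minus variants and only them", {
  g <- cached_gated(1, curcumin = TRUE)$gated
  fc <- do.call(rbind, lapply(ALL_TARGETS, function(tg)
    fold_change_analysis(g, tg)))
  am <- fc[fc$target %in% ALPHA_MINUS_VARIANTS, ]
  expect_true(all(am$significant))
  expect_true(all(am$fold_change > 100))
  rest <- fc[!fc$target %in% ALPHA_MINUS_VARIANTS, ]
  expect_false(any(rest$significant))   # incl. GAPDH and the beta-minus variant
})
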