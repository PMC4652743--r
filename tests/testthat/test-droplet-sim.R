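test_that("encapsulation is Poisson: empty and multi-cell fractions", {
  cfg <- sim_config(n_droplets = 1e5, seed = 42)
  founding <- encapsulate(cfg)$droplets$founding_cells
  # closed form: P(empty) = exp(-0.1) = 0.9048
  expect_equal(mean(founding == 0), exp(-0.1), tolerance = 0.005)
  # conditional Poisson: P(>=2 | >=1) = (1 - e^-m - m e^-m) / (1 - e^-m)
  frac2 <- mean(founding[founding > 0] >= 2)
  expect_lt(abs(frac2 - (1 - exp(-0.1) - 0.1 * exp(-0.1)) / (1 - exp(-0.1))),
            0.008)

  cfg0 <- sim_config(n_droplets = 1000, mean_cells_per_droplet = 0, seed = 1)
  expect_true(all(encapsulate(cfg0)$droplets$founding_cells == 0))

  expect_error(sim_config(n_droplets = 0), "n_droplets")
  expect_error(sim_config(n_droplets = -5), "n_droplets")
})

test_that("encapsulation occupancy passes a Poisson goodness-of-fit check", {
  cfg <- sim_config(n_droplets = 1e4, seed = 7)
  cnt <- encapsulate(cfg)$droplets$founding_cells
  tab <- table(factor(pmin(cnt, 3), levels = 0:3))
  p <- c(dpois(0:2, 0.1), 1 - ppois(2, 0.1))
  expect_gt(suppressWarnings(chisq.test(tab, p = p)$p.value), 0.01)
})

test_that("effective concentration arithmetic", {
  expect_equal(effective_concentration(5.9), 1e6 / 5.9)
  expect_equal(effective_concentration(1), 1e6)
  expect_equal(effective_concentration(11.4), 87719.3, tolerance = 1e-5)
  expect_equal(effective_concentration(5.9, 3), 3e6 / 5.9)
  expect_error(effective_concentration(0), "positive")
  expect_error(effective_concentration(-2), "positive")
})

test_that("deterministic doubling: 1 cell at 24 h CV 0 gives 4 cells in 2 days", {
  cfg <- sim_config(n_droplets = 50, mean_cells_per_droplet = 0.5,
                    doubling_time_h = 24, division_cv = 0,
                    capacity_cells_per_nl = 1e6, seed = 3)
  col <- encapsulate(cfg)
  col <- grow(grow(col))
  single <- col$droplets$founding_cells == 1
  expect_true(any(single))
  expect_true(all(col$droplets$cell_count[single] == 4))
  expect_equal(col$day, 2L)
})

test_that("colonies undergo 2-4 divisions by days 2-3 at default settings", {
  cfg <- sim_config(n_droplets = 3000, seed = 8, days = 3)
  sim <- simulate_colony_experiment(cfg)
  for (d in 2:3) {
    cc <- sim$truth[sim$truth$day == d, ]
    divs <- log2(cc$cell_count / cc$founding_cells)
    expect_gte(median(divs), 2)
    expect_lte(median(divs), 4)
  }
})

test_that("carrying capacity halts growth and forces decline (small droplets)", {
  # 3.4 nl with capacity < 8 cells: reached by day 2, declining on day 3
  cfg <- sim_config(droplet_volume = 3.4, capacity_cells_per_nl = 1.1,
                    n_droplets = 400, division_cv = 0, seed = 5, days = 3)
  col <- encapsulate(cfg)
  col1 <- grow(col); col2 <- grow(col1); col3 <- grow(col2)
  single <- col$droplets$founding_cells == 1
  d2 <- col2$droplets$cell_count[single]
  d3 <- col3$droplets$cell_count[single]
  expect_true(all(d3 < d2))
  expect_true(all(!col3$droplets$viable[single]))
  # empty droplets pass through untouched
  empty <- col$droplets$founding_cells == 0
  expect_true(all(col3$droplets$cell_count[empty] == 0))
})

test_that("bursting is exclusive and rare per variant", {
  cfg <- sim_config(n_droplets = 8000, seed = 2)
  col <- transcribe(encapsulate(cfg))
  dominant_ok <- c(); burst_n <- setNames(numeric(4), hTERT_VARIANTS)
  n_cells <- 0
  for (e in Filter(Negate(is.null), col$expression)) {
    m <- e$molecules[, hTERT_VARIANTS, drop = FALSE]
    n_cells <- n_cells + nrow(m)
    tot <- rowSums(m)
    pos <- tot > 0
    dominant_ok <- c(dominant_ok, apply(m[pos, , drop = FALSE], 1, max) /
                       tot[pos] > 0.9)
    for (v in hTERT_VARIANTS)
      burst_n[v] <- burst_n[v] +
        sum(!is.na(e$per_cell_variant) & e$per_cell_variant == v)
  }
  # >90% of a positive cell's hTERT molecules come from its dominant variant
  expect_gte(mean(dominant_ok), 0.9)
  # fewer than 25% of cells in high-burst state for any given variant
  expect_true(all(burst_n / n_cells < 0.25))
})

test_that("no bursting means baseline-only hTERT", {
  cfg <- sim_config(n_droplets = 2000, seed = 4,
                    variant_burst_rates = c("a+b+" = 0, "a-b+" = 0,
                                            "a+b-" = 0, "a-b-" = 0))
  col <- transcribe(encapsulate(cfg))
  for (e in Filter(Negate(is.null), col$expression)) {
    expect_true(all(e$molecules[, hTERT_VARIANTS] <= 1))
    expect_true(all(is.na(e$per_cell_variant)))
  }
})

test_that("noiseless readout scales areas exactly and drops zero targets", {
  cfg <- sim_config(n_droplets = 1, detection_prob = 1,
                    molecule_noise_cv = 0, area_noise_cv = 0, seed = 1)
  col <- fixed_colonies(cfg, molecule_matrix(c(hTR = 10, GAPDH = 3)))
  pk <- readout(col)
  expect_setequal(pk$target, c("hTR", "GAPDH"))
  expect_equal(pk$area[pk$target == "hTR"], 10 * 100)
  expect_equal(pk$area[pk$target == "GAPDH"], 3 * 100)
  # zero-molecule targets are negative calls: no rows
  expect_false("a+b+" %in% pk$target)
})

test_that("readout detection follows the Poisson thinning identity", {
  # P(positive) = 1 - exp(-lambda*d*p) when detection_prob = p
  lam <- 3; p <- 0.5
  s <- simulate_dilution_series(lam, dilutions = c(1, 0.5), n_reactions = 4000,
                                detection_prob = p, seed = 10)
  expect_equal(s$k / s$N, 1 - exp(-lam * s$d * p), tolerance = 0.03)
})

test_that("dilution series edge cases and expected counts", {
  s0 <- simulate_dilution_series(0, seed = 1)
  expect_true(all(s0$k == 0))
  k1 <- mean(vapply(1:50, function(i)
    simulate_dilution_series(12.5, dilutions = 1, seed = i)$k, 0))
  expect_equal(k1, 18 * (1 - exp(-12.5)), tolerance = 0.01)
  k2 <- mean(vapply(1:400, function(i)
    simulate_dilution_series(0.16, dilutions = 1, seed = i)$k, 0))
  expect_equal(k2, 18 * (1 - exp(-0.16)), tolerance = 0.1)
  expect_error(simulate_dilution_series(1, dilutions = numeric()), "empty")
  expect_error(simulate_dilution_series(1, dilutions = c(1, 2)), "0, 1")
})

test_that("same seed gives byte-identical simulation output", {
  cfg <- sim_config(n_droplets = 300, seed = 99)
  s1 <- simulate_colony_experiment(cfg)
  s2 <- simulate_colony_experiment(cfg)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth, s2$truth)
})

test_that("hTR per-cell variability shrinks with colony size", {
  g <- rbind(cached_gated(1)$gated, cached_gated(2)$gated,
             cached_gated(12)$gated)
  sds <- vapply(list(1, 2, 3:8), function(b) sd(g$hTR[g$cells %in% b]), 0)
  expect_true(all(diff(sds) < 0))
})

test_that("hTR and hTERT abundances are independent", {
  g <- cached_gated(1)$gated
  expect_gte(nrow(g), 300)
  expect_lt(expression_correlation(g, "hTR", "total_hTERT"), 0.05)
})

test_that("config validation rejects bad values", {
  expect_error(sim_config(mean_cells_per_droplet = 1.2), "dilute")
  expect_error(sim_config(detection_prob = 0), "detection_prob")
  expect_error(sim_config(detection_prob = 1.5), "detection_prob")
  expect_error(sim_config(variant_burst_rates = c("a+b+" = 0.5, "a-b+" = 0.5,
                                                  "a+b-" = 0.1, "a-b-" = 0)),
               "sum")
  expect_error(sim_config(curcumin = list(bogus = 1)), "bogus")
  expect_error(sim_config(droplet_volume = -1), "droplet_volume")
})

test_that("YAML round trip preserves the configuration", {
  cfg <- sim_config(n_droplets = 123, seed = 77,
                    curcumin = list(enabled = TRUE))
  path <- tempfile(fileext = ".yaml")
  cl <- unclass(cfg)
  cl$variant_burst_rates <- as.list(cl$variant_burst_rates)
  yaml::write_yaml(cl, path)
  cfg2 <- read_sim_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
  writeLines("n_droplets: 10\nnot_a_key: 1", path)
  expect_error(read_sim_config(path), "not_a_key")
})
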