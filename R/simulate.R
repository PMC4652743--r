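#' Effective cell concentration of a droplet culture
#'
#' A single cell confined in a droplet of volume V experiences the same
#' cell density as a bulk culture at 1/V cells per unit volume.  This
#' converts a droplet volume (nl) and cell count into the equivalent bulk
#' concentration in cells/ml; e.g. one cell in 5.9 nl corresponds to about
#' 170,000 cells/ml.
#'
#' @param droplet_volume_nl Droplet volume in nanoliters (> 0).
#' @param cells Number of cells in the droplet (default 1).
#' @return Effective concentration in cells per ml.
#' @export
#' @examples
#' effective_concentration(5.9)    # ~170,000 cells/ml
#' effective_concentration(3.4, 2)
effective_concentration <- function(droplet_volume_nl, cells = 1) {
  if (!is.numeric(droplet_volume_nl) || any(!is.finite(droplet_volume_nl)) ||
      any(droplet_volume_nl <= 0))
    stop("'droplet_volume_nl' must be positive", call. = FALSE)
  if (any(cells < 0)) stop("'cells' must be >= 0", call. = FALSE)
  cells / droplet_volume_nl * 1e6   # nl -> ml
}

condition_label <- function(config)
  if (isTRUE(config$curcumin$enabled)) "curcumin" else "control"

# one generation time draw per cell (hours); truncated to stay positive
sample_generation_times <- function(n, config) {
  cv <- config$division_cv
  if (isTRUE(config$curcumin$enabled))
    cv <- cv * config$curcumin$division_cv_multiplier
  tt <- rnorm(n, mean = config$doubling_time_h,
              sd = cv * config$doubling_time_h)
  tt <- pmax(tt, 0.05 * config$doubling_time_h)
  if (isTRUE(config$curcumin$enabled))
    tt <- tt / config$curcumin$growth_rate_multiplier
  tt
}

#' Encapsulate cells into droplets (day 0)
#'
#' Loads cells into `n_droplets` droplets by i.i.d. Poisson sampling with
#' mean `mean_cells_per_droplet`; empty droplets are retained.  At fewer
#' than 0.1 cells per droplet about 90% of droplets are empty and fewer
#' than 5% of occupied droplets carry more than one founding cell.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `droplet_colonies` holding, per droplet, the
#'   founding cell count, current cell count, viability flag and per-cell
#'   division clocks; expression state is filled in by [transcribe()].
#' @export
encapsulate <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "encapsulate"))
  n <- as.integer(config$n_droplets)
  founding <- rpois(n, config$mean_cells_per_droplet)
  division_next <- vector("list", n)
  for (i in which(founding > 0))
    division_next[[i]] <- sample_generation_times(founding[i], config)
  structure(list(
    config = config,
    day = 0L,
    droplets = data.frame(
      droplet_id = seq_len(n),
      founding_cells = founding,
      cell_count = founding,
      viable = founding > 0
    ),
    division_next = division_next,
    expression = NULL
  ), class = "droplet_colonies")
}

#' @export
print.droplet_colonies <- function(x, ...) {
  occ <- x$droplets$cell_count > 0
  cat(sprintf("<droplet_colonies> day %d: %d droplets, %d occupied, median colony size %s\n",
              x$day, nrow(x$droplets), sum(occ),
              if (any(occ)) stats::median(x$droplets$cell_count[occ]) else NA))
  invisible(x)
}

#' Advance colonies by one day of growth
#'
#' Each cell divides when its sampled generation time elapses (mean
#' `doubling_time_h`, CV `division_cv`); daughters draw fresh generation
#' times.  A colony stops dividing once its cell count reaches the nutrient
#' carrying capacity `capacity_cells_per_nl * droplet_volume`; from the next
#' day it is flagged non-viable and its cell count declines, mirroring
#' nutrient exhaustion in small droplets.
#'
#' @param colonies A `droplet_colonies` object.
#' @param config Configuration; defaults to the one stored in `colonies`.
#' @return The updated `droplet_colonies` object, with `day` incremented.
#' @export
grow <- function(colonies, config = colonies$config) {
  stopifnot(inherits(colonies, "droplet_colonies"))
  day <- colonies$day
  set.seed(stage_seed(config$seed, "grow") + day)
  capacity <- config$capacity_cells_per_nl * config$droplet_volume
  t_end <- (day + 1) * 24
  dr <- colonies$droplets
  for (i in which(dr$cell_count > 0)) {
    cnt <- dr$cell_count[i]
    if (!dr$viable[i] || cnt >= capacity) {
      # nutrient-exhausted colony: frozen clocks, declining viable count
      dr$viable[i] <- FALSE
      dr$cell_count[i] <- floor(cnt * 0.7)
      next
    }
    clocks <- colonies$division_next[[i]]
    while (cnt < capacity && length(clocks) && min(clocks) <= t_end) {
      j <- which.min(clocks)
      tdiv <- clocks[j]
      clocks <- clocks[-j]
      clocks <- c(clocks, tdiv + sample_generation_times(2L, config))
      cnt <- cnt + 1L
    }
    dr$cell_count[i] <- cnt
    colonies$division_next[[i]] <- clocks
  }
  colonies$droplets <- dr
  colonies$day <- day + 1L
  colonies$expression <- NULL   # stale after growth
  colonies
}

#' Draw a transcription snapshot for every colony
#'
#' Per live cell, at most one hTERT splice variant is sampled into a
#' high-burst state (categorical draw weighted by `variant_burst_rates`);
#' burst sizes are negative-binomial with mean `burst_size_mean`.
#' Non-bursting variants emit 0 or 1 baseline molecules.  hTR and GAPDH are
#' Poisson around their per-cell means (hTR with an additional between-cell
#' lognormal factor), independent of hTERT.  With curcumin enabled and from
#' day 2 onward, cells additionally burst each alpha-minus variant with
#' probability `curcumin$alpha_minus_burst_prob` and all alpha-minus burst
#' output is multiplied by `curcumin$alpha_minus_fold`.
#'
#' Non-viable (nutrient-exhausted) colonies transcribe nothing and will be
#' removed downstream by GAPDH gating.
#'
#' @inheritParams grow
#' @return `colonies` with an `expression` field: per droplet a cells-by-
#'   target molecule matrix and the per-cell dominant-variant label.
#' @export
transcribe <- function(colonies, config = colonies$config) {
  stopifnot(inherits(colonies, "droplet_colonies"))
  set.seed(stage_seed(config$seed, "transcribe") + colonies$day)
  rates <- config$variant_burst_rates[hTERT_VARIANTS]
  p_total <- sum(rates)
  curc <- isTRUE(config$curcumin$enabled) && colonies$day >= 2
  fold <- if (curc) config$curcumin$alpha_minus_fold else 1

  expression <- vector("list", nrow(colonies$droplets))
  for (i in seq_len(nrow(colonies$droplets))) {
    k <- colonies$droplets$cell_count[i]
    if (k < 1) next
    if (!colonies$droplets$viable[i]) {
      # dying colony: no productive transcription
      expression[[i]] <- list(
        molecules = matrix(0, nrow = k, ncol = length(ALL_TARGETS),
                           dimnames = list(NULL, ALL_TARGETS)),
        per_cell_variant = rep(NA_character_, k))
      next
    }
    m <- matrix(0, nrow = k, ncol = length(ALL_TARGETS),
                dimnames = list(NULL, ALL_TARGETS))
    # exclusive burst draw: one categorical sample per cell
    u <- runif(k)
    edges <- cumsum(rates)
    burst_variant <- rep(NA_character_, k)
    for (ci in seq_len(k)) {
      if (u[ci] < p_total)
        burst_variant[ci] <- hTERT_VARIANTS[findInterval(u[ci], c(0, edges),
                                                         rightmost.closed = TRUE)]
    }
    for (v in hTERT_VARIANTS) {
      bursting <- !is.na(burst_variant) & burst_variant == v
      nb <- sum(bursting)
      if (nb > 0) {
        sz <- 1 + rnbinom(nb, size = config$burst_size_shape,
                          mu = config$burst_size_mean - 1)
        if (v %in% ALPHA_MINUS_VARIANTS) sz <- sz * fold
        m[bursting, v] <- sz
      }
      base <- !bursting
      if (any(base))
        m[base, v] <- rbinom(sum(base), 1L, config$baseline_expr_prob)
    }
    if (curc) {
      # constitutive alpha-minus upregulation on top of the exclusive draw
      for (v in ALPHA_MINUS_VARIANTS) {
        on <- runif(k) < config$curcumin$alpha_minus_burst_prob
        if (any(on)) {
          sz <- 1 + rnbinom(sum(on), size = config$burst_size_shape,
                            mu = config$burst_size_mean - 1)
          m[on, v] <- m[on, v] + sz * fold
        }
      }
    }
    htr_cell_mean <- config$htr_mean *
      rlnorm(k, meanlog = -log(1 + config$htr_cell_cv^2) / 2,
             sdlog = sqrt(log(1 + config$htr_cell_cv^2)))
    m[, "hTR"] <- rpois(k, htr_cell_mean)
    m[, "GAPDH"] <- rpois(k, config$gapdh_mean)
    expression[[i]] <- list(molecules = m, per_cell_variant = burst_variant)
  }
  colonies$expression <- expression
  colonies
}

#' Colony molecule totals (ground truth)
#'
#' @param colonies A transcribed `droplet_colonies` object.
#' @return Data frame with one row per occupied droplet: droplet id, day,
#'   condition, founding cells, cell count, viability and true molecule
#'   totals per target.
#' @export
colony_truth <- function(colonies) {
  stopifnot(inherits(colonies, "droplet_colonies"))
  if (is.null(colonies$expression))
    stop("call transcribe() before colony_truth()", call. = FALSE)
  occ <- which(colonies$droplets$cell_count > 0)
  if (!length(occ)) {
    out <- data.frame(droplet_id = integer(), day = integer(),
                      condition = character(), founding_cells = integer(),
                      cell_count = integer(), viable = logical())
    for (tg in ALL_TARGETS) out[[tg]] <- numeric()
    return(out)
  }
  tot <- t(vapply(occ, function(i)
    colSums(colonies$expression[[i]]$molecules),
    setNames(numeric(length(ALL_TARGETS)), ALL_TARGETS)))
  out <- data.frame(
    droplet_id = colonies$droplets$droplet_id[occ],
    day = colonies$day,
    condition = condition_label(colonies$config),
    founding_cells = colonies$droplets$founding_cells[occ],
    cell_count = colonies$droplets$cell_count[occ],
    viable = colonies$droplets$viable[occ]
  )
  cbind(out, as.data.frame(tot))
}

#' Simulate the RT-PCR/CE readout of transcribed colonies
#'
#' Each true molecule is detected with probability `detection_prob`
#' (binomial thinning, so a target diluted to mean `lambda * d` molecules is
#' read positive with probability `1 - exp(-lambda * d * detection_prob)`).
#' Detected molecules produce a fragment peak with
#' `area = detected * area_per_molecule * lognormal(1, area_noise_cv)`; a
#' target is called positive iff at least one molecule is detected, and only
#' positive targets emit peak rows (as in a peak-caller export).
#'
#' @inheritParams grow
#' @param target_map Target-to-(dye, fragment size) map, see
#'   [default_target_map()].
#' @return A `peak_table` data frame with columns `sample_id`, `day`,
#'   `condition`, `cells`, `dye`, `size_bp`, `height`, `area`, `target`.
#' @export
readout <- function(colonies, config = colonies$config,
                    target_map = default_target_map()) {
  stopifnot(inherits(colonies, "droplet_colonies"))
  if (is.null(colonies$expression))
    stop("call transcribe() before readout()", call. = FALSE)
  validate_target_map(target_map)
  if (!all(ALL_TARGETS %in% target_map$target))
    stop("target_map is missing targets: ",
         paste(setdiff(ALL_TARGETS, target_map$target), collapse = ", "),
         call. = FALSE)
  set.seed(stage_seed(config$seed, "readout") + colonies$day)
  cond <- condition_label(config)
  sdlog <- sqrt(log(1 + config$area_noise_cv^2))
  sdmol <- sqrt(log(1 + config$molecule_noise_cv^2))
  # summed mean-1 lognormal amplification yield of k detected molecules;
  # normal approximation once per-molecule variability has averaged out
  mol_yield <- function(k) {
    if (sdmol == 0) return(as.numeric(k))
    vapply(k, function(ki) {
      if (ki <= 30)
        sum(rlnorm(ki, meanlog = -sdmol^2 / 2, sdlog = sdmol))
      else
        max(0, rnorm(1, mean = ki,
                     sd = sqrt(ki) * config$molecule_noise_cv))
    }, 0)
  }
  rows <- list()
  occ <- which(colonies$droplets$cell_count > 0)
  for (i in occ) {
    mol <- colSums(colonies$expression[[i]]$molecules)
    detected <- rbinom(length(mol), size = mol, prob = config$detection_prob)
    names(detected) <- names(mol)
    pos <- names(detected)[detected >= 1]
    if (!length(pos)) next
    map <- target_map[match(pos, target_map$target), ]
    noise <- if (config$area_noise_cv > 0)
      rlnorm(length(pos), meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
    area <- mol_yield(detected[pos]) * config$area_per_molecule * noise
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("s%06d_d%d", colonies$droplets$droplet_id[i],
                          colonies$day),
      day = colonies$day,
      condition = cond,
      cells = colonies$droplets$cell_count[i],
      dye = map$dye,
      size_bp = map$size_bp + rnorm(length(pos), sd = 0.15),
      height = area * 0.12,
      area = area,
      target = pos,
      row.names = NULL
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), day = integer(),
               condition = character(), cells = integer(), dye = character(),
               size_bp = numeric(), height = numeric(), area = numeric(),
               target = character())
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Run a full droplet-culture simulation over several days
#'
#' Encapsulates cells, then for each culture day advances growth, draws a
#' transcription snapshot and reads out every occupied droplet.  Day 0 is
#' sampled immediately after encapsulation.
#'
#' @param config A [sim_config()] object.
#' @param target_map Target-to-(dye, size) map used by the readout.
#' @return A list with elements `peaks` (combined `peak_table` across days),
#'   `truth` (ground-truth colony table across days) and `config`.
#' @export
simulate_colony_experiment <- function(config,
                                       target_map = default_target_map()) {
  validate_sim_config(config)
  colonies <- encapsulate(config)
  peaks <- list(); truth <- list()
  colonies <- transcribe(colonies)
  peaks[[1]] <- readout(colonies, target_map = target_map)
  truth[[1]] <- colony_truth(colonies)
  for (d in seq_len(config$days)) {
    colonies <- grow(colonies)
    colonies <- transcribe(colonies)
    peaks[[d + 1L]] <- readout(colonies, target_map = target_map)
    truth[[d + 1L]] <- colony_truth(colonies)
  }
  peaks <- do.call(rbind, peaks)
  class(peaks) <- c("peak_table", "data.frame")
  list(peaks = peaks, truth = do.call(rbind, truth), config = config)
}

#' Simulate a limiting-dilution digital RT-PCR series
#'
#' For each dilution factor `d`, draws the number of positive reactions
#' `k ~ Binomial(N, 1 - exp(-lambda * d))`: a reaction is positive iff at
#' least one template molecule is present, with molecule counts Poisson at
#' mean `lambda * d` per reaction.  An imperfect detection probability `p`
#' thins the Poisson mean to `lambda * d * p`.
#'
#' @param lambda_per_cell True template copies per undiluted cell-equivalent.
#' @param dilutions Dilution factors in (0, 1]; default a 2-fold ladder from
#'   1 to 1/256.
#' @param n_reactions Replicate reactions per dilution (default 18).
#' @param detection_prob Per-molecule detection probability (default 1).
#' @param target Optional target label attached to the series.
#' @param seed Optional integer seed.
#' @return A `dilution_series` data frame with columns `target`, `d`, `k`,
#'   `N`.
#' @export
#' @examples
#' simulate_dilution_series(12.5, seed = 1)
simulate_dilution_series <- function(lambda_per_cell,
                                     dilutions = 2^-(0:8),
                                     n_reactions = 18,
                                     detection_prob = 1,
                                     target = "target",
                                     seed = NULL) {
  if (!is.numeric(lambda_per_cell) || length(lambda_per_cell) != 1L ||
      !is.finite(lambda_per_cell) || lambda_per_cell < 0)
    stop("'lambda_per_cell' must be a single number >= 0", call. = FALSE)
  if (!length(dilutions))
    stop("'dilutions' must be a non-empty vector", call. = FALSE)
  if (any(dilutions <= 0 | dilutions > 1))
    stop("'dilutions' must lie in (0, 1]", call. = FALSE)
  if (n_reactions < 1)
    stop("'n_reactions' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p_pos <- 1 - exp(-lambda_per_cell * dilutions * detection_prob)
  out <- data.frame(
    target = target,
    d = dilutions,
    k = rbinom(length(dilutions), size = n_reactions, prob = p_pos),
    N = as.integer(n_reactions)
  )
  class(out) <- c("dilution_series", "data.frame")
  out
}
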