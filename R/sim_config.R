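#' Simulation configuration for droplet single-cell culture experiments
#'
#' Builds and validates the configuration object consumed by the synthetic
#' data generator ([encapsulate()], [grow()], [transcribe()], [readout()] and
#' [simulate_colony_experiment()]).  Defaults encode the study conditions of
#' the emulated droplet-culture experiment: 5.9 nl droplets loaded at fewer
#' than 0.1 cells per droplet, a ~20 h doubling time with tightly synchronized
#' division (generation-time CV 0.1), a nutrient carrying capacity
#' proportional to droplet volume, exclusive per-cell hTERT splice-variant
#' bursting, high-copy stable hTR and GAPDH, and a curcumin perturbation that
#' strongly upregulates the alpha-minus variants from day 2 while
#' desynchronizing division.
#'
#' @param droplet_volume Droplet volume in nanoliters.
#' @param mean_cells_per_droplet Poisson mean of cells loaded per droplet;
#'   must be < 1 (statistically dilute loading).
#' @param n_droplets Number of droplets to generate.
#' @param days Number of culture days to simulate after encapsulation.
#' @param doubling_time_h Mean cell generation time in hours (default 20,
#'   a typical lymphoblast doubling time).
#' @param division_cv Coefficient of variation of the generation time
#'   (dimensionless); small values give synchronized 1/2/4/8-cell colonies.
#' @param capacity_cells_per_nl Nutrient carrying capacity density in
#'   cells/nl; a colony stops growing (and loses viability) once its cell
#'   count reaches `capacity_cells_per_nl * droplet_volume`.
#' @param variant_burst_rates Named numeric vector: per-day probability that
#'   a cell is in a high-burst state for each hTERT splice variant
#'   (`"a+b+"`, `"a-b+"`, `"a+b-"`, `"a-b-"`).  At most one variant bursts
#'   per cell at a sampling time (exclusive bursting); the sum must be < 1.
#' @param burst_size_mean Mean molecules per transcriptional burst.
#' @param burst_size_shape Negative-binomial shape (size) of the burst;
#'   larger values concentrate burst sizes around the mean.
#' @param baseline_expr_prob Probability that a non-bursting variant emits a
#'   single baseline molecule in a cell.
#' @param htr_mean,gapdh_mean Mean hTR and GAPDH molecules per cell.
#' @param htr_cell_cv Between-cell lognormal CV of the hTR mean, giving
#'   single cells visible hTR heterogeneity that averages out in colonies.
#' @param curcumin List with elements `enabled`, `alpha_minus_fold`
#'   (multiplier on alpha-minus burst output from day 2), `alpha_minus_burst_prob`
#'   (per-cell probability of constitutive alpha-minus bursting from day 2),
#'   `division_cv_multiplier` and `growth_rate_multiplier`.
#' @param detection_prob Probability that a molecule is reverse transcribed
#'   and detected; in (0, 1].
#' @param area_per_molecule CE peak-area units per detected molecule.
#' @param molecule_noise_cv Per-molecule lognormal CV of amplification yield:
#'   each detected template contributes its own lognormal area factor, so
#'   single-molecule peaks vary strongly while large bursts average out
#'   (relative spread `molecule_noise_cv / sqrt(k)` for k molecules).
#' @param area_noise_cv Lognormal CV of multiplicative per-peak readout
#'   noise applied on top of the molecule-level variability.
#' @param seed Integer master seed; all stochastic operations derive their
#'   RNG streams from it, so equal seeds give bit-identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_droplets = 100, seed = 7)
#' cfg$droplet_volume
sim_config <- function(droplet_volume = 5.9,
                       mean_cells_per_droplet = 0.1,
                       n_droplets = 2000,
                       days = 2,
                       doubling_time_h = 20,
                       division_cv = 0.1,
                       capacity_cells_per_nl = 2.5,
                       variant_burst_rates = c("a+b+" = 0.05, "a-b+" = 0.04,
                                               "a+b-" = 0.15, "a-b-" = 0.08),
                       burst_size_mean = 50,
                       burst_size_shape = 40,
                       baseline_expr_prob = 0.05,
                       htr_mean = 1000,
                       htr_cell_cv = 0.5,
                       gapdh_mean = 500,
                       curcumin = list(),
                       detection_prob = 0.5,
                       area_per_molecule = 100,
                       molecule_noise_cv = 0.8,
                       area_noise_cv = 0.3,
                       seed = 1L) {
  curc_default <- list(enabled = FALSE, alpha_minus_fold = 300,
                       alpha_minus_burst_prob = 0.95,
                       division_cv_multiplier = 3,
                       growth_rate_multiplier = 1)
  if (!is.list(curcumin))
    stop("'curcumin' must be a list", call. = FALSE)
  unknown <- setdiff(names(curcumin), names(curc_default))
  if (length(unknown))
    stop("unknown curcumin option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  curc_default[names(curcumin)] <- curcumin

  cfg <- structure(list(
    droplet_volume = droplet_volume,
    mean_cells_per_droplet = mean_cells_per_droplet,
    n_droplets = n_droplets,
    days = days,
    doubling_time_h = doubling_time_h,
    division_cv = division_cv,
    capacity_cells_per_nl = capacity_cells_per_nl,
    variant_burst_rates = variant_burst_rates,
    burst_size_mean = burst_size_mean,
    burst_size_shape = burst_size_shape,
    baseline_expr_prob = baseline_expr_prob,
    htr_mean = htr_mean,
    htr_cell_cv = htr_cell_cv,
    gapdh_mean = gapdh_mean,
    curcumin = curc_default,
    detection_prob = detection_prob,
    area_per_molecule = area_per_molecule,
    molecule_noise_cv = molecule_noise_cv,
    area_noise_cv = area_noise_cv,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object (or plain list with the same fields).
#' @return `cfg`, invisibly, if valid; otherwise an error describing the
#'   offending field.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  chk(num1(cfg$droplet_volume) && cfg$droplet_volume > 0,
      "'droplet_volume' must be a positive number (nl)")
  chk(num1(cfg$mean_cells_per_droplet) && cfg$mean_cells_per_droplet >= 0,
      "'mean_cells_per_droplet' must be >= 0")
  chk(cfg$mean_cells_per_droplet < 1,
      "'mean_cells_per_droplet' must be < 1 (statistically dilute loading)")
  chk(num1(cfg$n_droplets) && cfg$n_droplets >= 1 &&
        cfg$n_droplets == round(cfg$n_droplets),
      "'n_droplets' must be a positive integer")
  chk(num1(cfg$days) && cfg$days >= 0, "'days' must be >= 0")
  chk(num1(cfg$doubling_time_h) && cfg$doubling_time_h > 0,
      "'doubling_time_h' must be positive")
  chk(num1(cfg$division_cv) && cfg$division_cv >= 0,
      "'division_cv' must be >= 0")
  chk(num1(cfg$capacity_cells_per_nl) && cfg$capacity_cells_per_nl > 0,
      "'capacity_cells_per_nl' must be positive")
  chk(is.numeric(cfg$variant_burst_rates) &&
        setequal(names(cfg$variant_burst_rates), hTERT_VARIANTS),
      "'variant_burst_rates' must be named with the four hTERT variants")
  chk(all(cfg$variant_burst_rates >= 0) && sum(cfg$variant_burst_rates) < 1,
      "'variant_burst_rates' must be >= 0 and sum to < 1")
  chk(num1(cfg$burst_size_mean) && cfg$burst_size_mean > 0,
      "'burst_size_mean' must be positive")
  chk(num1(cfg$burst_size_shape) && cfg$burst_size_shape > 0,
      "'burst_size_shape' must be positive")
  chk(num1(cfg$baseline_expr_prob) && cfg$baseline_expr_prob >= 0 &&
        cfg$baseline_expr_prob <= 1,
      "'baseline_expr_prob' must be in [0, 1]")
  chk(num1(cfg$htr_mean) && cfg$htr_mean >= 0, "'htr_mean' must be >= 0")
  chk(num1(cfg$htr_cell_cv) && cfg$htr_cell_cv >= 0,
      "'htr_cell_cv' must be >= 0")
  chk(num1(cfg$gapdh_mean) && cfg$gapdh_mean >= 0,
      "'gapdh_mean' must be >= 0")
  chk(num1(cfg$detection_prob) && cfg$detection_prob > 0 &&
        cfg$detection_prob <= 1,
      "'detection_prob' must be in (0, 1]")
  chk(num1(cfg$area_per_molecule) && cfg$area_per_molecule > 0,
      "'area_per_molecule' must be positive")
  chk(num1(cfg$molecule_noise_cv) && cfg$molecule_noise_cv >= 0,
      "'molecule_noise_cv' must be >= 0")
  chk(num1(cfg$area_noise_cv) && cfg$area_noise_cv >= 0,
      "'area_noise_cv' must be >= 0")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L && is.finite(cfg$seed),
      "'seed' must be a single integer")
  cc <- cfg$curcumin
  chk(is.logical(cc$enabled) && length(cc$enabled) == 1L,
      "'curcumin$enabled' must be TRUE or FALSE")
  chk(num1(cc$alpha_minus_fold) && cc$alpha_minus_fold >= 1,
      "'curcumin$alpha_minus_fold' must be >= 1")
  chk(num1(cc$alpha_minus_burst_prob) && cc$alpha_minus_burst_prob >= 0 &&
        cc$alpha_minus_burst_prob <= 1,
      "'curcumin$alpha_minus_burst_prob' must be in [0, 1]")
  chk(num1(cc$division_cv_multiplier) && cc$division_cv_multiplier > 0,
      "'curcumin$division_cv_multiplier' must be positive")
  chk(num1(cc$growth_rate_multiplier) && cc$growth_rate_multiplier > 0,
      "'curcumin$growth_rate_multiplier' must be positive")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Reads a YAML file whose keys mirror the arguments of [sim_config()] and
#' returns a validated configuration; unknown keys raise a config error.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$variant_burst_rates))
    raw$variant_burst_rates <- unlist(raw$variant_burst_rates)
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d droplets of %.1f nl, %.3g cells/droplet, %d day(s)\n",
              x$n_droplets, x$droplet_volume, x$mean_cells_per_droplet,
              as.integer(x$days)))
  cat(sprintf("  doubling %.1f h (CV %.2f), capacity %.1f cells\n",
              x$doubling_time_h, x$division_cv,
              x$capacity_cells_per_nl * x$droplet_volume))
  cat(sprintf("  burst rates: %s\n",
              paste(sprintf("%s=%.2f", names(x$variant_burst_rates),
                            x$variant_burst_rates), collapse = " ")))
  cat(sprintf("  curcumin: %s\n",
              if (x$curcumin$enabled) "enabled" else "disabled"))
  invisible(x)
}
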