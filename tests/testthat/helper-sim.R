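# shared simulation helpers; heavier runs are cached per session so several
# test files can reuse the same seeded experiment

.sim_cache <- new.env(parent = emptyenv())

cached_gated <- function(seed = 1, n_droplets = 2000, curcumin = FALSE) {
  key <- sprintf("g_%d_%d_%d", seed, n_droplets, curcumin)
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(n_droplets = n_droplets, seed = seed,
                      curcumin = list(enabled = curcumin))
    sim <- simulate_colony_experiment(cfg)
    .sim_cache[[key]] <- list(
      gated = gate_and_normalize(collapse_to_matrix(sim$peaks)),
      truth = sim$truth, config = cfg)
  }
  .sim_cache[[key]]
}

# a hand-built colonies object with known molecule counts, for readout tests
fixed_colonies <- function(config, molecules) {
  structure(list(
    config = config,
    day = 0L,
    droplets = data.frame(droplet_id = 1L, founding_cells = 1L,
                          cell_count = nrow(molecules), viable = TRUE),
    division_next = list(numeric(nrow(molecules))),
    expression = list(list(molecules = molecules,
                           per_cell_variant = rep(NA_character_,
                                                  nrow(molecules))))
  ), class = "droplet_colonies")
}

molecule_matrix <- function(counts, cells = 1) {
  m <- matrix(0, nrow = cells, ncol = length(ALL_TARGETS),
              dimnames = list(NULL, ALL_TARGETS))
  m[1, names(counts)] <- counts
  m
}
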