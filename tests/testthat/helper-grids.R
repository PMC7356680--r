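# Hand-built miniature grids for oracle tests: a solid cube of one species
# bathed in liquid, with optional random pores.

cube_species <- function(resistance, solubility = "soluble", role = "api") {
  tibble::tibble(
    species_id = 1L, layer = 1L, layer_label = "cube", name = "X",
    true_density = 1.5, solubility_class = solubility,
    dissolution_resistance = if (solubility == "insoluble") Inf else
      as.numeric(resistance),
    role = role, volume_fraction = 1
  )
}

make_cube_grid <- function(W, resistance = 1, porosity = 0,
                           solubility = "soluble", seed = 1,
                           margin = 1L) {
  dims <- rep(W + 2L * margin, 3L)
  state <- array(0L, dims)
  layer <- array(0L, dims)
  core <- (margin + 1L):(margin + W)
  layer[core, core, core] <- 1L
  state[core, core, core] <- 1L
  if (porosity > 0) {
    set.seed(seed)
    idx <- which(layer == 1L)
    state[idx[stats::runif(length(idx)) < porosity]] <- -1L
  }
  structure(
    list(state = state, layer = layer, pitch_um = 100,
         species = cube_species(resistance, solubility),
         spec = NULL, layer_labels = "cube", seed = seed),
    class = "voxel_grid"
  )
}

# A soluble voxel sealed inside a closed insoluble 3x3x3 shell.
make_sealed_grid <- function() {
  dims <- rep(5L, 3L)
  state <- array(0L, dims)
  layer <- array(0L, dims)
  layer[2:4, 2:4, 2:4] <- 1L
  state[2:4, 2:4, 2:4] <- 2L # insoluble shell
  state[3, 3, 3] <- 1L       # soluble core
  sp <- dplyr::bind_rows(
    cube_species(1, "soluble"),
    dplyr::mutate(cube_species(1, "insoluble", role = "inert_separator"),
                  species_id = 2L, name = "shell")
  )
  structure(
    list(state = state, layer = layer, pitch_um = 100, species = sp,
         spec = NULL, layer_labels = "cube", seed = 1L),
    class = "voxel_grid"
  )
}

# Independent brute-force erosion-front oracle: with unit resistance, unit
# ingress and no detachment, every solid voxel with a non-solid face
# neighbour leaves at each step. Counts steps until nothing solid remains.
erosion_front_steps <- function(W) {
  solid <- array(TRUE, dim = rep(W, 3L))
  steps <- 0L
  while (any(solid)) {
    d <- dim(solid)
    exposed <- array(FALSE, d)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!solid[x, y, z]) next
      nb <- 0L
      for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
        p <- c(x, y, z) + off
        if (any(p < 1) || any(p > d) || !solid[p[1], p[2], p[3]]) nb <- nb + 1L
      }
      if (nb > 0L) exposed[x, y, z] <- TRUE
    }
    solid[exposed] <- FALSE
    steps <- steps + 1L
  }
  steps
}

# Rules used by the oracle comparisons: deterministic ingress, no erosion.
oracle_rules <- function(seconds_per_step = 1) {
  ca_rules(ingress_probability = 1, detachment_threshold = 0L,
           disintegrant_burst = FALSE, seconds_per_step = seconds_per_step)
}
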