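#' Cellular-automaton rule set
#'
#' The automaton is synchronous on the 6-neighbour (von Neumann) lattice and
#' runs three phases per step, all evaluated against the state at the start
#' of the step:
#'
#' 1. *Ingress*: a pore voxel with at least one liquid face-neighbour becomes
#'    liquid with its layer's `ingress_probability` — the discrete proxy for
#'    capillary imbibition rate (faster-wicking granulates get larger
#'    probabilities).
#' 2. *Dissolution*: a soluble solid voxel with at least one liquid
#'    face-neighbour loses one unit of its dissolution resistance; at zero it
#'    becomes liquid and its mass is credited to that species' release.
#'    Insoluble voxels never dissolve and never transmit liquid.
#' 3. *Erosion / detachment*: a solid voxel with fewer than
#'    `detachment_threshold` solid face-neighbours and at least one liquid
#'    neighbour detaches: soluble material is released immediately, insoluble
#'    material moves to the detached-insoluble ledger.
#'
#' With `disintegrant_burst = TRUE`, a wetted disintegrant voxel converts to
#' liquid in one step regardless of its remaining resistance, mimicking a
#' swelling superdisintegrant opening the pore network.
#'
#' @param ingress_probability Named numeric vector of per-layer ingress
#'   probabilities in `(0, 1]` (names = layer labels), or a single number
#'   applied to all layers.
#' @param detachment_threshold Integer `k`: solid voxels with `< k` solid
#'   neighbours and a liquid neighbour detach. `0` disables erosion.
#' @param disintegrant_burst Logical; see above.
#' @param seconds_per_step Calibration factor mapping automaton steps to
#'   seconds (see [calibrate_seconds_per_step()]).
#' @param resistance_override Optional named numeric vector overriding
#'   per-component dissolution resistances (names = component names).
#' @return A `ca_rules` list.
#' @export
ca_rules <- function(ingress_probability = 1,
                     detachment_threshold = 2L,
                     disintegrant_burst = TRUE,
                     seconds_per_step = 1,
                     resistance_override = NULL) {
  if (any(ingress_probability <= 0 | ingress_probability > 1)) {
    stop("Ingress probabilities must lie in (0, 1].", call. = FALSE)
  }
  if (seconds_per_step <= 0) stop("`seconds_per_step` must be > 0.", call. = FALSE)
  if (!is.null(resistance_override)) {
    if (is.null(names(resistance_override)) ||
        any(!nzchar(names(resistance_override)))) {
      stop("`resistance_override` must be named by component.", call. = FALSE)
    }
    if (any(resistance_override < 1 & is.finite(resistance_override))) {
      stop("Resistance overrides must be >= 1.", call. = FALSE)
    }
  }
  structure(
    list(ingress_probability = ingress_probability,
         detachment_threshold = as.integer(detachment_threshold),
         disintegrant_burst = isTRUE(disintegrant_burst),
         seconds_per_step = seconds_per_step,
         resistance_override = resistance_override),
    class = "ca_rules"
  )
}

#' Default rules for the study tablets
#'
#' Ingress probabilities follow the measured capillary constants of the two
#' granulates (ASA : MA about 8.84 : 1.81, i.e. roughly a five-fold faster
#' imbibition into the ASA material), scaled so the faster layer sits near
#' 0.9 per step. The polycaprolactone layer gets a nominal small value; with
#' its porosity of ~0 and insoluble voxels blocking transport, it admits no
#' liquid in practice.
#'
#' @inheritParams ca_rules
#' @return A `ca_rules` list with per-layer ingress for labels
#'   `"ASA layer"`, `"PCL layer"`, `"MA layer"`.
#' @export
default_rules <- function(seconds_per_step = 1,
                          detachment_threshold = 2L,
                          disintegrant_burst = TRUE) {
  ca_rules(
    ingress_probability = c("ASA layer" = 0.884, "PCL layer" = 0.05,
                            "MA layer" = 0.181),
    detachment_threshold = detachment_threshold,
    disintegrant_burst = disintegrant_burst,
    seconds_per_step = seconds_per_step
  )
}

#' Initialize the automaton on an assigned grid
#'
#' Exterior voxels are liquid at time zero; every solid voxel receives its
#' species' dissolution resistance as a countdown counter (infinite for
#' insoluble species); the per-species mass ledger starts with everything in
#' the solid phase and nothing released.
#'
#' @param grid An assigned `voxel_grid` (see [assign_components()]).
#' @param rules A [ca_rules()] object.
#' @param seed Integer seed governing all stochastic draws of the run.
#' @return A `ca_state` list.
#' @export
ca_initialize <- function(grid, rules, seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(rules, "ca_rules"))
  if (any(grid$state == VX_UNASSIGNED)) {
    stop("Grid has unassigned voxels; run assign_components() first.",
         call. = FALSE)
  }
  sp <- grid$species
  res <- sp$dissolution_resistance
  if (!is.null(rules$resistance_override)) {
    hit <- match(sp$name, names(rules$resistance_override))
    res[!is.na(hit)] <- rules$resistance_override[hit[!is.na(hit)]]
    res[sp$solubility_class == "insoluble"] <- Inf
  }
  p <- rules$ingress_probability
  if (is.null(names(p))) {
    if (length(p) != 1L && length(p) != length(grid$layer_labels)) {
      stop("Unnamed ingress probabilities must have length 1 or one per layer.",
           call. = FALSE)
    }
    p_layer <- rep_len(unname(p), length(grid$layer_labels))
  } else {
    p_layer <- p[grid$layer_labels]
    if (anyNA(p_layer)) {
      stop("Ingress probabilities missing for layer(s): ",
           paste(grid$layer_labels[is.na(p_layer)], collapse = ", "),
           call. = FALSE)
    }
    p_layer <- unname(p_layer)
  }

  counters <- array(0, dim = dim(grid$state))
  solid <- grid$state > 0L
  counters[solid] <- res[grid$state[solid]]

  ledger <- sp |>
    dplyr::mutate(
      initial_voxels = vapply(sp$species_id, function(id)
        sum(grid$state == id), integer(1)),
      dissolved_voxels = 0L,
      detached_voxels = 0L
    )

  structure(
    list(grid = grid, counters = counters, rules = rules,
         resistance = res, p_layer = p_layer,
         step_index = 0L, seed = as.integer(seed),
         ledger = ledger),
    class = "ca_state"
  )
}

# Per-step uniform field with state-independent consumption: every step draws
# one uniform for every voxel from a seed derived from (run seed, step), so
# two runs differing only in rule constants share identical random fields
# (common random numbers) and any run replays bit-for-bit.
step_uniforms <- function(seed, step, dims) {
  set.seed((seed + 1000003L * step) %% 2147483647L)
  array(stats::runif(prod(dims)), dim = dims)
}

#' Advance the automaton one step
#'
#' Applies the three phases described in [ca_rules()] synchronously (double
#' buffered: all phases read the start-of-step state). The per-species voxel
#' ledger `initial = remaining + dissolved + detached` holds exactly after
#' every step.
#'
#' @param state A `ca_state`.
#' @return The advanced `ca_state`.
#' @export
ca_step <- function(state) {
  stopifnot(inherits(state, "ca_state"))
  g <- state$grid
  st <- g$state
  dims <- dim(st)
  step <- state$step_index + 1L

  liquid <- st == VX_LIQUID
  solid <- st > 0L
  insoluble_id <- state$ledger$species_id[
    state$ledger$solubility_class == "insoluble"]
  is_insoluble <- array(st %in% insoluble_id, dim = dims)
  nb_liq <- neighbor_count6(liquid)

  u <- step_uniforms(state$seed, step, dims)

  # phase 1: ingress into wetted pores
  p_arr <- array(0, dim = dims)
  in_tab <- g$layer > 0L
  p_arr[in_tab] <- state$p_layer[g$layer[in_tab]]
  ingress <- (st == VX_PORE) & (nb_liq > 0L) & (u < p_arr)

  # phase 2: dissolution countdown of wetted soluble solids
  wetted <- solid & !is_insoluble & (nb_liq > 0L)
  counters <- state$counters
  counters[wetted] <- counters[wetted] - 1
  dissolved <- wetted & (counters <= 0)

  # disintegrant burst: wetted disintegrant converts in one step
  if (state$rules$disintegrant_burst) {
    dis_id <- state$ledger$species_id[state$ledger$role == "disintegrant" &
                                      state$ledger$solubility_class != "insoluble"]
    if (length(dis_id)) {
      burst <- array(st %in% dis_id, dim = dims) & (nb_liq > 0L)
      dissolved <- dissolved | burst
    }
  }

  # phase 3: erosion of under-coordinated surface voxels
  detached <- array(FALSE, dim = dims)
  if (state$rules$detachment_threshold > 0L) {
    nb_solid <- neighbor_count6(solid)
    loose <- solid & (nb_solid < state$rules$detachment_threshold) &
      (nb_liq > 0L) & !dissolved
    detached <- loose
  }
  eroded_soluble <- detached & !is_insoluble
  detached_insoluble <- detached & is_insoluble

  # commit: soluble erosion counts as instantaneous release
  released_mask <- dissolved | eroded_soluble
  gone <- ingress | released_mask | detached_insoluble

  led <- state$ledger
  if (any(released_mask)) {
    rel_ids <- st[released_mask]
    cnt <- tabulate(rel_ids, nbins = nrow(led))
    led$dissolved_voxels <- led$dissolved_voxels + cnt
  }
  if (any(detached_insoluble)) {
    det_ids <- st[detached_insoluble]
    cnt <- tabulate(det_ids, nbins = nrow(led))
    led$detached_voxels <- led$detached_voxels + cnt
  }

  st[gone] <- VX_LIQUID
  counters[gone] <- 0
  state$grid$state <- st
  state$counters <- counters
  state$ledger <- led
  state$step_index <- step
  state
}

# Per-species remaining voxel counts; used for ledger assertions.
remaining_voxels <- function(state) {
  vapply(state$ledger$species_id, function(id)
    sum(state$grid$state == id), integer(1))
}

ledger_balanced <- function(state) {
  all(remaining_voxels(state) + state$ledger$dissolved_voxels +
        state$ledger$detached_voxels == state$ledger$initial_voxels)
}

#' Run the automaton to completion
#'
#' Steps until all soluble solid has left the lattice or `max_steps` is
#' reached (with a warning). Release of each species is its dissolved voxel
#' count over its initial count, as a percent of dose; the time axis is
#' `step * seconds_per_step`.
#'
#' @param state An initialized `ca_state`.
#' @param max_steps Step cap.
#' @param record_interval Record the release curve every this many steps.
#' @return A `ca_result`: list with `profile` (tibble `time_s`, `species`,
#'   `released_pct`), `soluble_frac` (per-step remaining soluble solid
#'   fraction), `steps`, `seconds_per_step`, `ledger`, `seed`, and
#'   `ledger_ok` (TRUE when the mass ledger balanced at every step).
#' @export
ca_run <- function(state, max_steps = 5000L, record_interval = 1L) {
  stopifnot(inherits(state, "ca_state"))
  spp <- state$rules$seconds_per_step
  led0 <- state$ledger
  soluble <- led0$solubility_class != "insoluble"
  soluble_initial <- sum(led0$initial_voxels[soluble])
  api_tbl <- led0 |>
    dplyr::filter(.data$role == "api") |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(initial = sum(.data$initial_voxels), .groups = "drop")

  rec_times <- numeric(0)
  rec_rel <- list()
  soluble_frac <- numeric(0)
  ledger_ok <- TRUE

  record <- function(s, t) {
    rel <- s$ledger |>
      dplyr::filter(.data$role == "api") |>
      dplyr::group_by(.data$name) |>
      dplyr::summarise(dissolved = sum(.data$dissolved_voxels),
                       .groups = "drop") |>
      dplyr::left_join(api_tbl, by = "name") |>
      dplyr::mutate(released_pct = ifelse(.data$initial > 0,
                                          100 * .data$dissolved / .data$initial,
                                          0))
    tibble::tibble(time_s = t, species = rel$name,
                   released_pct = rel$released_pct)
  }

  rec_rel[[1]] <- record(state, 0)
  rec_times <- 0

  for (k in seq_len(max_steps)) {
    state <- ca_step(state)
    if (!ledger_balanced(state)) ledger_ok <- FALSE
    rem_sol <- sum(remaining_voxels(state)[soluble])
    # with no soluble phase at all, the compact can never disintegrate
    soluble_frac <- c(soluble_frac,
                      if (soluble_initial > 0) rem_sol / soluble_initial else 1)
    complete <- soluble_initial > 0L && rem_sol == 0L
    if (k %% record_interval == 0L || complete) {
      rec_rel[[length(rec_rel) + 1L]] <- record(state, k * spp)
      rec_times <- c(rec_times, k * spp)
    }
    if (complete) break
  }
  if (state$step_index == max_steps &&
      (soluble_initial == 0L ||
         sum(remaining_voxels(state)[soluble]) > 0L)) {
    warning("Run capped at max_steps before complete release.", call. = FALSE)
  }

  structure(
    list(profile = dplyr::bind_rows(rec_rel),
         soluble_frac = soluble_frac,
         steps = state$step_index,
         seconds_per_step = spp,
         ledger = state$ledger,
         final_state = state,
         seed = state$seed,
         ledger_ok = ledger_ok),
    class = "ca_result"
  )
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result> %d steps (%g s/step), seed %d\n",
              x$steps, x$seconds_per_step, x$seed))
  fin <- x$profile |>
    dplyr::group_by(.data$species) |>
    dplyr::slice_max(.data$time_s, n = 1) |>
    dplyr::ungroup()
  print(fin)
  dt <- disintegration_time(x)
  cat(if (is.na(dt)) "Not disintegrated within the run.\n" else
    sprintf("Disintegration time: %g s\n", dt))
  invisible(x)
}

#' Simulated disintegration time
#'
#' First time at which less than `threshold` (default 1%) of the initial
#' soluble solid remains undissolved and undetached. Insoluble material
#' (e.g. an inert separation layer) is excluded from the criterion, matching
#' the practical endpoint of a disintegration tester where an inert slab may
#' persist.
#'
#' @param result A `ca_result`.
#' @param threshold Remaining soluble solid fraction defining the endpoint.
#' @return Time in seconds, or `NA` (with attribute `max_time_s`) when the
#'   endpoint was never reached.
#' @export
disintegration_time <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "ca_result"))
  hit <- which(result$soluble_frac < threshold)
  if (!length(hit)) {
    return(structure(NA_real_,
                     max_time_s = result$steps * result$seconds_per_step))
  }
  hit[1] * result$seconds_per_step
}

#' Time to reach a release threshold
#'
#' First recorded time at which a species' cumulative release meets
#' `threshold` percent, linearly interpolated between recorded points.
#'
#' @param result A `ca_result` (or any tibble with `time_s`, `species`,
#'   `released_pct`).
#' @param species Species name.
#' @param threshold Release percent (default 80).
#' @return Time in seconds (`NA` when never reached).
#' @export
time_to_release <- function(result, species, threshold = 80) {
  prof <- if (inherits(result, "ca_result")) result$profile else result
  p <- prof[prof$species == species, , drop = FALSE]
  p <- p[order(p$time_s), ]
  i <- which(p$released_pct >= threshold)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  if (i == 1L) return(p$time_s[1])
  t0 <- p$time_s[i - 1]; t1 <- p$time_s[i]
  y0 <- p$released_pct[i - 1]; y1 <- p$released_pct[i]
  if (y1 == y0) return(t1)
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Calibrate the step-to-seconds factor
#'
#' Maps automaton steps to wall-clock seconds by pinning the time at which a
#' reference species of a reference run reaches a release threshold to a
#' target time. This is a pure rescaling of the time axis; it does not touch
#' the rule constants.
#'
#' @param result A reference `ca_result` run with `seconds_per_step = 1`.
#' @param species Reference species.
#' @param target_time_s Desired time (s) for that species to reach
#'   `threshold` percent release.
#' @param threshold Release percent used as the anchor (default 80).
#' @return The calibrated seconds-per-step factor.
#' @export
calibrate_seconds_per_step <- function(result, species, target_time_s,
                                       threshold = 80) {
  anchor <- time_to_release(result, species, threshold)
  if (is.na(anchor) || anchor <= 0) {
    stop("Reference run never reached the anchor release threshold.",
         call. = FALSE)
  }
  target_time_s / (anchor / result$seconds_per_step)
}
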