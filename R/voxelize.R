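# Voxel state codes. Pores become LIQUID on ingress; dissolved solids become
# LIQUID; species ids are positive integers into the grid's species table.
VX_LIQUID <- 0L
VX_PORE <- -1L
VX_UNASSIGNED <- -9L

# Shift a 3D array by one voxel along `axis` in direction `dir` (+1/-1),
# padding with `fill`. Core primitive behind all neighbourhood operations.
shift3 <- function(arr, axis, dir, fill = 0L) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- lapply(d, seq_len)
  dst <- src
  if (dir > 0) {
    src[[axis]] <- seq_len(d[axis] - 1L)
    dst[[axis]] <- 2:d[axis]
  } else {
    src[[axis]] <- 2:d[axis]
    dst[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Count of TRUE face-neighbours (6-neighbourhood, von Neumann) per voxel.
neighbor_count6 <- function(mask) {
  m <- array(as.integer(mask), dim = dim(mask))
  shift3(m, 1, +1) + shift3(m, 1, -1) +
    shift3(m, 2, +1) + shift3(m, 2, -1) +
    shift3(m, 3, +1) + shift3(m, 3, -1)
}

#' Discretize a tablet into a cubic voxel grid
#'
#' Voxel centres falling inside the oval prism of each layer receive that
#' layer's id; everything else is exterior liquid. The compression axis is z,
#' with layer 1 at low z. Grid dimensions are `ceil(extent / pitch)` plus a
#' margin of exterior voxels on every side, so the finished grid is always
#' bathed in medium.
#'
#' @param spec A [tablet_spec()].
#' @param pitch_um Voxel edge length in micrometres (default 74).
#' @param margin_voxels Exterior voxels added on each side (default 1).
#' @param max_dim Safety cap on any single grid dimension.
#' @return A `voxel_grid`: list with `state` (3D integer array), `layer`
#'   (3D integer array, 0 outside the tablet), `pitch_um`, `species`
#'   (tibble mapping species ids to components and layers), and `spec`.
#' @export
#' @examples
#' f <- formulation(component("ASA", 1, 1.3928, "soluble", 2, "api", "paper"))
#' tb <- tablet_spec(list(layer_spec(f, 200, 0.07, "ASA")), 8, 4)
#' g <- voxelize(tb, pitch_um = 500)
#' dim(g$state)
voxelize <- function(spec, pitch_um = 74, margin_voxels = 1L, max_dim = 400L) {
  stopifnot(inherits(spec, "vx_tablet"), pitch_um > 0, margin_voxels >= 0)
  pitch_mm <- pitch_um / 1000
  a <- spec$punch_major_mm
  b <- spec$punch_minor_mm
  th <- vapply(seq_along(spec$layers), function(i) layer_thickness(spec, i),
               numeric(1))
  if (any(th == 0)) {
    warning("Zero-thickness layer(s): ",
            paste(which(th == 0), collapse = ", "),
            " contribute no voxels.", call. = FALSE)
  }
  height <- sum(th)
  dims <- as.integer(ceiling(c(a, b, height) / pitch_mm)) + 2L * margin_voxels
  if (any(dims > max_dim)) {
    stop(sprintf("Tablet needs grid %s at pitch %g um; exceeds max_dim = %d.",
                 paste(dims, collapse = "x"), pitch_um, max_dim), call. = FALSE)
  }
  # voxel centre coordinates relative to the tablet's bounding box origin
  cx <- (seq_len(dims[1]) - 0.5 - margin_voxels) * pitch_mm
  cy <- (seq_len(dims[2]) - 0.5 - margin_voxels) * pitch_mm
  cz <- (seq_len(dims[3]) - 0.5 - margin_voxels) * pitch_mm
  inside_xy <- footprint_mask(spec, cx, cy)

  layer_of_z <- integer(dims[3])
  bounds <- cumsum(c(0, th))
  for (i in seq_along(th)) {
    layer_of_z[cz >= bounds[i] & cz < bounds[i + 1]] <- i
  }
  layer_arr <- array(0L, dim = dims)
  for (k in seq_len(dims[3])) {
    if (layer_of_z[k] > 0L) {
      layer_arr[, , k] <- inside_xy * layer_of_z[k]
    }
  }
  state <- array(VX_LIQUID, dim = dims)
  state[layer_arr > 0L] <- VX_UNASSIGNED

  structure(
    list(state = state, layer = layer_arr, pitch_um = pitch_um,
         species = species_table(spec), spec = spec,
         layer_labels = vapply(spec$layers, `[[`, character(1), "label"),
         seed = NULL),
    class = "voxel_grid"
  )
}

# Logical matrix: which (x, y) voxel centres fall inside the punch footprint.
footprint_mask <- function(spec, cx, cy) {
  a <- spec$punch_major_mm
  b <- spec$punch_minor_mm
  X <- outer(cx - a / 2, rep(1, length(cy)))
  Y <- outer(rep(1, length(cx)), cy - b / 2)
  m <- switch(spec$shape,
    ellipse = (X / (a / 2))^2 + (Y / (b / 2))^2 <= 1,
    stadium = {
      half_len <- (a - b) / 2
      Xc <- pmax(abs(X) - half_len, 0)
      Xc^2 + Y^2 <= (b / 2)^2
    },
    stop("Unknown shape model: ", spec$shape, call. = FALSE)
  )
  array(as.integer(m), dim = c(length(cx), length(cy)))
}

# One species per (layer, component): keeps per-layer dose ledgers separate
# even when the same material occurs in several layers.
species_table <- function(spec) {
  purrr::imap_dfr(spec$layers, function(ly, i) {
    f <- ly$formulation
    vol <- f$weight_fraction / f$true_density
    tibble::tibble(
      layer = i,
      layer_label = ly$label,
      name = f$name,
      true_density = f$true_density,
      solubility_class = f$solubility_class,
      dissolution_resistance = ifelse(f$solubility_class == "insoluble",
                                      Inf, as.numeric(f$dissolution_resistance)),
      role = f$role,
      volume_fraction = vol / sum(vol)
    )
  }) |>
    dplyr::mutate(species_id = dplyr::row_number(), .before = 1)
}

#' Assign components and pores to a layer's voxels
#'
#' Each voxel of the layer independently becomes a pore with probability
#' equal to the layer's target porosity, otherwise a pure-component voxel
#' with probability proportional to the component's solid volume fraction
#' `(X_k / rho_k) / sum(X_j / rho_j)`. One uniform draw per voxel against
#' fixed cut-points makes the assignment reproducible bit-for-bit per seed.
#'
#' @param grid A `voxel_grid` from [voxelize()].
#' @param layer_index Layer to assign (1 = bottom).
#' @param seed Integer RNG seed for this layer's placement.
#' @return The grid with that layer's voxels assigned.
#' @export
assign_layer_components <- function(grid, layer_index, seed) {
  stopifnot(inherits(grid, "voxel_grid"))
  ly <- grid$spec$layers[[layer_index]]
  eps <- ly$porosity
  if (eps < 0 || eps >= 1) stop("Porosity must lie in [0, 1).", call. = FALSE)
  sp <- dplyr::filter(grid$species, .data$layer == layer_index)
  idx <- which(grid$layer == layer_index)
  if (!length(idx)) return(grid)
  cuts <- cumsum(c(eps, (1 - eps) * sp$volume_fraction))
  cuts[length(cuts)] <- 1  # guard against rounding
  set.seed(seed)
  u <- stats::runif(length(idx))
  bin <- findInterval(u, cuts, left.open = FALSE) # 0 = pore
  val <- c(VX_PORE, sp$species_id)[bin + 1L]
  grid$state[idx] <- val
  grid
}

#' Assign every layer of a grid
#'
#' Convenience wrapper calling [assign_layer_components()] per layer with
#' per-layer seeds derived from `seed`.
#'
#' @inheritParams assign_layer_components
#' @param seed Base seed; layer `i` uses `seed + i`.
#' @return Fully assigned `voxel_grid` (records `seed`).
#' @export
assign_components <- function(grid, seed) {
  for (i in seq_along(grid$spec$layers)) {
    grid <- assign_layer_components(grid, i, seed + i)
  }
  grid$seed <- seed
  grid
}

#' Summarise a voxel grid
#'
#' @param grid A `voxel_grid`.
#' @return A list of two tibbles: `states` (count per state over the whole
#'   grid) and `layers` (per layer: voxel counts, pore count, achieved
#'   porosity vs target).
#' @export
grid_summary <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  st <- as.vector(grid$state)
  states <- tibble::as_tibble(table(state = st), .name_repair = "minimal")
  names(states) <- c("state", "count")
  states$state <- as.integer(states$state)
  states$count <- as.integer(states$count)

  layers <- purrr::map_dfr(seq_along(grid$layer_labels), function(i) {
    idx <- grid$layer == i
    n <- sum(idx)
    pores <- sum(grid$state[idx] == VX_PORE)
    tibble::tibble(
      layer = i,
      label = grid$layer_labels[i],
      voxels = n,
      pore_voxels = pores,
      achieved_porosity = if (n > 0) pores / n else NA_real_,
      target_porosity = if (is.null(grid$spec)) NA_real_ else
        grid$spec$layers[[i]]$porosity
    )
  })
  list(states = states, layers = layers)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$state)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels at %g um pitch\n",
              d[1], d[2], d[3], x$pitch_um))
  print(grid_summary(x)$layers)
  invisible(x)
}

#' Does a layer's pore network span to its mid-plane?
#'
#' Flood-fills the pore phase of one layer from its end faces along the
#' compression axis and reports whether the fill reaches the layer's
#' mid-plane. This is the operational percolation check: below the simple
#' cubic site-percolation threshold (~0.3116) pore clusters are finite and
#' the answer is almost surely FALSE for layers of meaningful thickness;
#' well above it the pore space spans. The lateral band is deliberately not
#' used as a source so that a single surface pore at mid-height does not
#' count as a spanning path.
#'
#' @param grid An assigned `voxel_grid`.
#' @param layer Layer index or layer label.
#' @return TRUE if a face-connected pore path joins an end face to the
#'   mid-plane of the layer.
#' @export
percolation_check <- function(grid, layer) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.character(layer)) {
    layer <- match(layer, grid$layer_labels)
    if (is.na(layer)) stop("Unknown layer label.", call. = FALSE)
  }
  if (layer < 1 || layer > length(grid$layer_labels)) {
    stop("Unknown layer index.", call. = FALSE)
  }
  in_layer <- grid$layer == layer
  if (!any(in_layer)) return(FALSE)
  pores <- (grid$state == VX_PORE) & in_layer
  if (!any(pores)) return(FALSE)

  zs <- which(apply(in_layer, 3, any))
  z_lo <- min(zs); z_hi <- max(zs)
  z_mid <- floor((z_lo + z_hi) / 2)

  reached <- array(FALSE, dim = dim(grid$state))
  reached[, , z_lo] <- pores[, , z_lo]
  reached[, , z_hi] <- pores[, , z_hi]
  repeat {
    if (any(reached[, , z_mid])) return(TRUE)
    grown <- (neighbor_count6(reached) > 0L) & pores
    grown <- grown | reached
    if (identical(grown, reached)) return(FALSE)
    reached <- grown
  }
}
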