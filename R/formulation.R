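#' Define a formulation component
#'
#' A component is one raw material in a layer formulation: an API, diluent,
#' disintegrant, binder, lubricant or inert separator. Weight fractions are
#' fractions of the layer mass; true densities are helium-pycnometry solid
#' densities (pores excluded).
#'
#' @param name Component name (unique within a formulation).
#' @param weight_fraction Mass fraction of the layer, in `[0, 1]`.
#' @param true_density True (pore-free) density in g/cm^3. Must be positive.
#' @param solubility_class One of `"soluble"`, `"sparingly_soluble"`,
#'   `"insoluble"`. Insoluble components never dissolve in the cellular
#'   automaton and never transmit liquid.
#' @param dissolution_resistance Positive integer: the number of automaton
#'   steps a wetted voxel of this component survives before dissolving.
#'   Ignored (treated as infinite) for insoluble components.
#' @param role One of `"api"`, `"diluent"`, `"disintegrant"`, `"binder"`,
#'   `"lubricant"`, `"inert_separator"`.
#' @param density_source Provenance flag for `true_density`: `"paper"` for
#'   values taken from the study report, `"placeholder"` for documented
#'   literature stand-ins.
#'
#' @return A one-row tibble.
#' @export
#' @examples
#' component("ASA", 0.5, 1.3928, "soluble", 2, "api")
component <- function(name, weight_fraction, true_density,
                      solubility_class = c("soluble", "sparingly_soluble", "insoluble"),
                      dissolution_resistance = 1L,
                      role = c("api", "diluent", "disintegrant", "binder",
                               "lubricant", "inert_separator"),
                      density_source = "placeholder") {
  solubility_class <- match.arg(solubility_class)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(true_density) || true_density <= 0) {
    stop("`true_density` must be a positive number (g/cm^3).", call. = FALSE)
  }
  if (!is.numeric(weight_fraction) || weight_fraction < 0 || weight_fraction > 1) {
    stop("`weight_fraction` must lie in [0, 1].", call. = FALSE)
  }
  dissolution_resistance <- as.integer(dissolution_resistance)
  if (is.na(dissolution_resistance) || dissolution_resistance < 1L) {
    stop("`dissolution_resistance` must be an integer >= 1.", call. = FALSE)
  }
  tibble::tibble(
    name = name,
    weight_fraction = as.numeric(weight_fraction),
    true_density = as.numeric(true_density),
    solubility_class = solubility_class,
    dissolution_resistance = dissolution_resistance,
    role = role,
    density_source = density_source
  )
}

#' Assemble and validate a layer formulation
#'
#' Binds component rows into a formulation table and checks the invariants:
#' unique component names, positive densities, and weight fractions summing
#' to 1 within 1e-9.
#'
#' @param ... One-row tibbles from [component()], or data frames of such rows.
#' @return A tibble with one row per component.
#' @export
#' @examples
#' formulation(
#'   component("ASA", 0.5, 1.3928, "soluble", 2, "api", "paper"),
#'   component("d-mannitol", 0.5, 1.49, "soluble", 1, "diluent")
#' )
formulation <- function(...) {
  tbl <- dplyr::bind_rows(...)
  validate_formulation(tbl)
  tbl
}

validate_formulation <- function(tbl) {
  req <- c("name", "weight_fraction", "true_density", "solubility_class",
           "dissolution_resistance", "role")
  missing <- setdiff(req, names(tbl))
  if (length(missing)) {
    stop("Formulation is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tbl$name)) {
    stop("Component names must be unique within a formulation.", call. = FALSE)
  }
  if (any(tbl$true_density <= 0)) {
    stop("All true densities must be positive.", call. = FALSE)
  }
  s <- sum(tbl$weight_fraction)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("Weight fractions must sum to 1 (got %.12f).", s),
         call. = FALSE)
  }
  invisible(tbl)
}

#' True density of a layer from its formulation
#'
#' The layer's pore-free density is the harmonic mean of component densities
#' weighted by mass fraction: `rho_layer = 1 / sum(X_i / rho_i)`. It always
#' lies between the smallest and largest component density.
#'
#' @param formulation A formulation tibble (see [formulation()]).
#' @return Layer true density in g/cm^3 (scalar).
#' @export
#' @examples
#' f <- formulation(
#'   component("a", 0.5, 1.0, "soluble", 1, "diluent"),
#'   component("b", 0.5, 2.0, "soluble", 1, "diluent")
#' )
#' layer_true_density(f) # 4/3
layer_true_density <- function(formulation) {
  validate_formulation(formulation)
  1 / sum(formulation$weight_fraction / formulation$true_density)
}

#' Porosity of a compacted layer
#'
#' `eps = 1 - m / (V * rho)`: the void volume fraction of a compact of mass
#' `m`, envelope volume `V` and true density `rho`. A negative result means
#' the stated mass cannot fit in the stated volume (inconsistent geometry);
#' a result of 1 or more means an empty compact — both are rejected.
#'
#' @param mass_mg Layer mass in mg.
#' @param volume_cm3 Layer envelope volume in cm^3.
#' @param true_density Layer true density in g/cm^3.
#' @return Porosity as a fraction in `[0, 1)`.
#' @export
#' @examples
#' layer_porosity(1200, 1, 1.5) # 0.2
layer_porosity <- function(mass_mg, volume_cm3, true_density) {
  if (!all(mass_mg > 0, volume_cm3 > 0, true_density > 0)) {
    stop("mass, volume and true density must all be positive.", call. = FALSE)
  }
  eps <- 1 - (mass_mg / 1000) / (volume_cm3 * true_density)
  if (eps < 0) {
    stop(sprintf(
      "Inconsistent geometry: mass %.1f mg exceeds solid capacity of %.4f cm^3 at %.4f g/cm^3 (porosity %.4f).",
      mass_mg, volume_cm3, true_density, eps), call. = FALSE)
  }
  if (eps >= 1 - 1e-12) {
    stop("Porosity >= 1: mass is negligible relative to volume.", call. = FALSE)
  }
  eps
}

#' Effective compressive stress
#'
#' Compaction force divided by the horizontal cross-section of the tablet:
#' `P = F * 1000 / S`, giving MPa from kN and mm^2.
#'
#' @param force_kN Resultant compressive force in kN.
#' @param area_mm2 Horizontal cross-section area in mm^2.
#' @return Effective compressive stress in MPa.
#' @export
#' @examples
#' effective_compressive_stress(26, 167.74) # ~155 MPa
effective_compressive_stress <- function(force_kN, area_mm2) {
  if (!is.numeric(force_kN) || any(force_kN <= 0)) {
    stop("`force_kN` must be positive.", call. = FALSE)
  }
  if (!is.numeric(area_mm2) || any(area_mm2 <= 0)) {
    stop("`area_mm2` must be positive.", call. = FALSE)
  }
  force_kN * 1000 / area_mm2
}

#' Specify one tablet layer
#'
#' @param formulation A formulation tibble.
#' @param mass_mg Layer mass in mg.
#' @param porosity Target porosity fraction in `[0, 1)`.
#' @param label Layer label (e.g. `"ASA layer"`).
#' @param thickness_mm Optional measured thickness. When `NULL` the thickness
#'   is derived from mass, porosity, true density and the tablet
#'   cross-section (`t = m / ((1 - eps) * rho * A)`).
#' @return A `vx_layer` list.
#' @export
layer_spec <- function(formulation, mass_mg, porosity, label,
                       thickness_mm = NULL) {
  validate_formulation(formulation)
  if (mass_mg < 0) stop("`mass_mg` must be >= 0.", call. = FALSE)
  if (porosity < 0 || porosity >= 1) {
    stop("`porosity` must lie in [0, 1).", call. = FALSE)
  }
  structure(
    list(formulation = formulation, mass_mg = mass_mg, porosity = porosity,
         label = label, thickness_mm = thickness_mm),
    class = "vx_layer"
  )
}

#' Specify a layered tablet on an oval punch
#'
#' Layers are ordered bottom to top along the compression (z) axis. The oval
#' punch footprint is modelled either as an ellipse (default) or a stadium
#' (rectangle capped by two half-discs); "oval" tooling drawings are
#' ambiguous between the two, and the ellipse reproduces the reported
#' compressive stresses within about 2%.
#'
#' @param layers A list of [layer_spec()] objects, bottom first.
#' @param punch_major_mm Major axis of the punch footprint, mm.
#' @param punch_minor_mm Minor axis, mm.
#' @param shape `"ellipse"` or `"stadium"`.
#' @return A `vx_tablet` list.
#' @export
tablet_spec <- function(layers, punch_major_mm, punch_minor_mm,
                        shape = c("ellipse", "stadium")) {
  shape <- match.arg(shape)
  if (!length(layers)) stop("A tablet needs at least one layer.", call. = FALSE)
  if (inherits(layers, "vx_layer")) layers <- list(layers)
  stopifnot(all(vapply(layers, inherits, logical(1), "vx_layer")))
  if (punch_major_mm <= 0 || punch_minor_mm <= 0) {
    stop("Punch axes must be positive.", call. = FALSE)
  }
  structure(
    list(layers = layers, punch_major_mm = punch_major_mm,
         punch_minor_mm = punch_minor_mm, shape = shape),
    class = "vx_tablet"
  )
}

#' @export
print.vx_tablet <- function(x, ...) {
  cat(sprintf("<vx_tablet> %d layer(s), %s %.1f x %.1f mm footprint\n",
              length(x$layers), x$shape, x$punch_major_mm, x$punch_minor_mm))
  print(layer_table(x))
  invisible(x)
}

#' Horizontal cross-section area of a tablet
#'
#' Ellipse model: `pi * (a/2) * (b/2)`. Stadium model: a rectangle of length
#' `a - b` and width `b`, capped by two half-discs of diameter `b`:
#' `(a - b) * b + pi * (b/2)^2`.
#'
#' @param spec A [tablet_spec()].
#' @return Area in mm^2.
#' @export
#' @examples
#' cross_section_area(tablet_spec(list(
#'   layer_spec(formulation(component("x", 1, 1.3928, "soluble", 1, "api")),
#'              1000, 0.071, "x")), 21.5, 10))
cross_section_area <- function(spec) {
  stopifnot(inherits(spec, "vx_tablet"))
  a <- spec$punch_major_mm
  b <- spec$punch_minor_mm
  switch(spec$shape,
    ellipse = pi * (a / 2) * (b / 2),
    stadium = (a - b) * b + pi * (b / 2)^2,
    stop("Unknown shape model: ", spec$shape, call. = FALSE)
  )
}

#' Cross-section perimeter of a tablet footprint
#'
#' Ellipse perimeter uses Ramanujan's second approximation (relative error
#' below 1e-6 for the aspect ratios of pharmaceutical punches); the stadium
#' perimeter is exact: `2 * (a - b) + pi * b`.
#'
#' @inheritParams cross_section_area
#' @return Perimeter in mm.
#' @export
cross_section_perimeter <- function(spec) {
  stopifnot(inherits(spec, "vx_tablet"))
  a <- spec$punch_major_mm / 2
  b <- spec$punch_minor_mm / 2
  switch(spec$shape,
    ellipse = {
      h <- ((a - b) / (a + b))^2
      pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    },
    stadium = 2 * (spec$punch_major_mm - spec$punch_minor_mm) +
      pi * spec$punch_minor_mm,
    stop("Unknown shape model: ", spec$shape, call. = FALSE)
  )
}

#' Resolved thickness of one layer
#'
#' Uses the supplied measured thickness when present, otherwise derives the
#' flat-faced prism thickness `t = m / ((1 - eps) * rho * A)` (mm from mg,
#' g/cm^3 and mm^2 — the unit factors cancel).
#'
#' @param spec A [tablet_spec()].
#' @param layer_index 1-based layer index (bottom = 1).
#' @return Thickness in mm.
#' @export
layer_thickness <- function(spec, layer_index) {
  stopifnot(inherits(spec, "vx_tablet"))
  ly <- spec$layers[[layer_index]]
  if (!is.null(ly$thickness_mm)) return(ly$thickness_mm)
  if (ly$mass_mg == 0) return(0)
  rho <- layer_true_density(ly$formulation)
  ly$mass_mg / ((1 - ly$porosity) * rho * cross_section_area(spec))
}

#' Exposed (effective) surface area of one layer
#'
#' The lateral band (perimeter x thickness) is always exposed; each flat end
#' face counts only when it does not touch a neighbouring layer. In a stack,
#' every internal interface occludes one face of each of the two layers it
#' joins, which is how an inert middle layer cuts the dissolution-effective
#' surface of both APIs.
#'
#' @inheritParams layer_thickness
#' @return Exposed area in mm^2 (flat-face model estimate; real punches have
#'   curved cups, so absolute CAD areas will differ while ratios are
#'   comparable).
#' @export
exposed_surface_area <- function(spec, layer_index) {
  stopifnot(inherits(spec, "vx_tablet"))
  n <- length(spec$layers)
  if (layer_index < 1 || layer_index > n) {
    stop("`layer_index` out of range.", call. = FALSE)
  }
  t <- layer_thickness(spec, layer_index)
  if (is.null(t) || is.na(t)) stop("Layer thickness unresolved.", call. = FALSE)
  face <- cross_section_area(spec)
  n_free_faces <- (layer_index == 1) + (layer_index == n)
  cross_section_perimeter(spec) * t + n_free_faces * face
}

#' Layer surface area as a percentage of its single-layer control
#'
#' Reported rounded to the whole percent, the convention used for effective
#' surface comparisons between multilayer tablets and their single-layer
#' controls.
#'
#' @param layer_area_mm2 Effective area of the layer in the multilayer tablet.
#' @param control_area_mm2 Area of the corresponding single-layer control.
#' @return Whole-percent value (e.g. 83).
#' @export
#' @examples
#' surface_fraction_of_control(289.3, 350.2) # 83
surface_fraction_of_control <- function(layer_area_mm2, control_area_mm2) {
  if (!is.numeric(control_area_mm2) || any(control_area_mm2 <= 0)) {
    stop("`control_area_mm2` must be positive.", call. = FALSE)
  }
  round(100 * layer_area_mm2 / control_area_mm2)
}

#' Per-layer property table of a tablet
#'
#' @param spec A [tablet_spec()].
#' @return A tibble with one row per layer: label, mass, porosity, true
#'   density, resolved thickness, and exposed surface area (flat-face model).
#' @export
layer_table <- function(spec) {
  stopifnot(inherits(spec, "vx_tablet"))
  n <- length(spec$layers)
  tibble::tibble(
    layer = seq_len(n),
    label = vapply(spec$layers, `[[`, character(1), "label"),
    mass_mg = vapply(spec$layers, `[[`, numeric(1), "mass_mg"),
    porosity = vapply(spec$layers, `[[`, numeric(1), "porosity"),
    true_density_g_cm3 = vapply(spec$layers, function(l)
      layer_true_density(l$formulation), numeric(1)),
    thickness_mm = vapply(seq_len(n), function(i)
      layer_thickness(spec, i), numeric(1)),
    exposed_area_mm2 = vapply(seq_len(n), function(i)
      exposed_surface_area(spec, i), numeric(1))
  )
}
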