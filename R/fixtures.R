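# Literature placeholder true densities (g/cm^3) for excipients whose
# pycnometric values were not printed with the study formulations. Flagged
# "placeholder" in fixture provenance; override by editing the formulations.
PLACEHOLDER_DENSITY <- c(
  "MA" = 1.30, "d-mannitol" = 1.49, "Microcrystalline cellulose" = 1.56,
  "Croscarmellose sodium" = 1.59, "Hydroxypropyl cellulose" = 1.22,
  "Magnesium stearate" = 1.09
)

asa_layer_formulation <- function() {
  formulation(
    component("ASA", 0.50, 1.3928, "soluble", 4L, "api", "paper"),
    component("d-mannitol", 0.33, PLACEHOLDER_DENSITY[["d-mannitol"]],
              "soluble", 1L, "diluent"),
    component("Microcrystalline cellulose", 0.10,
              PLACEHOLDER_DENSITY[["Microcrystalline cellulose"]],
              "insoluble", 1L, "diluent"),
    component("Croscarmellose sodium", 0.03,
              PLACEHOLDER_DENSITY[["Croscarmellose sodium"]],
              "soluble", 1L, "disintegrant"),
    component("Hydroxypropyl cellulose", 0.03,
              PLACEHOLDER_DENSITY[["Hydroxypropyl cellulose"]],
              "soluble", 3L, "binder"),
    component("Magnesium stearate", 0.01,
              PLACEHOLDER_DENSITY[["Magnesium stearate"]],
              "insoluble", 1L, "lubricant")
  )
}

ma_layer_formulation <- function() {
  f <- asa_layer_formulation()
  f$name[1] <- "MA"
  f$true_density[1] <- PLACEHOLDER_DENSITY[["MA"]]
  f$solubility_class[1] <- "sparingly_soluble"
  f$dissolution_resistance[1] <- 6L
  f$density_source[1] <- "placeholder"
  f
}

pcl_layer_formulation <- function() {
  formulation(
    component("PCL", 1.0, 1.1600, "insoluble", 1L, "inert_separator", "paper")
  )
}

#' Study dosage-form fixtures
#'
#' The four dosage forms of the study, rebuilt from the printed formulation
#' tables: a 500-mg mefenamic acid (MA) tablet, a 1000-mg acetylsalicylic
#' acid (ASA) tablet, their bilayer combination (1500 mg) and the
#' triple-layer tablet with a 300-mg polycaprolactone (PCL) separation layer
#' (1800 mg), all on the 21.5 x 10 mm oval punch. Layer order bottom-to-top
#' in the multilayer forms is ASA, (PCL,) MA.
#'
#' Masses, weight fractions, punch size, the ASA and PCL true densities and
#' the layer porosities are study values; excipient densities, the MA true
#' density, the PCL layer porosity and all automaton constants are
#' documented placeholders. The `provenance` tibble flags every numeric
#' field as `"paper"` or `"placeholder"`.
#'
#' The MA layer porosity is 13.7% when compressed alone but 11.1% inside the
#' multilayer tablets; both values are kept, each in its context.
#'
#' @return A `fixture_set` list: `ma_tablet`, `asa_tablet`, `bilayer`,
#'   `triple_layer` ([tablet_spec()] objects), `default_rules`
#'   ([ca_rules()]), and `provenance` (tibble `field`, `value`, `source`,
#'   `note`).
#' @export
#' @examples
#' fx <- paper_formulations()
#' sum(layer_table(fx$triple_layer)$mass_mg) # 1800
paper_formulations <- function() {
  asa_f <- asa_layer_formulation()
  ma_f <- ma_layer_formulation()
  pcl_f <- pcl_layer_formulation()

  punch <- c(21.5, 10)
  ma_tablet <- tablet_spec(
    list(layer_spec(ma_f, 500, 0.137, "MA layer")),
    punch[1], punch[2])
  asa_tablet <- tablet_spec(
    list(layer_spec(asa_f, 1000, 0.071, "ASA layer")),
    punch[1], punch[2])
  bilayer <- tablet_spec(
    list(layer_spec(asa_f, 1000, 0.074, "ASA layer"),
         layer_spec(ma_f, 500, 0.111, "MA layer")),
    punch[1], punch[2])
  triple_layer <- tablet_spec(
    list(layer_spec(asa_f, 1000, 0.074, "ASA layer"),
         layer_spec(pcl_f, 300, 0.0, "PCL layer"),
         layer_spec(ma_f, 500, 0.111, "MA layer")),
    punch[1], punch[2])

  prov <- tibble::tribble(
    ~field, ~value, ~source, ~note,
    "punch_major_mm", 21.5, "paper", "oval punch set",
    "punch_minor_mm", 10.0, "paper", "oval punch set",
    "ASA layer mass_mg", 1000.0, "paper", "formulation table",
    "MA layer mass_mg", 500.0, "paper", "formulation table",
    "PCL layer mass_mg", 300.0, "paper", "separation layer",
    "ASA weight_fraction", 0.50, "paper", "of layer mass",
    "MA weight_fraction", 0.50, "paper", "of layer mass",
    "ASA true_density", 1.3928, "paper", "helium pycnometry",
    "PCL true_density", 1.1600, "paper", "helium pycnometry",
    "MA true_density", PLACEHOLDER_DENSITY[["MA"]], "placeholder",
    "literature value",
    "d-mannitol true_density", PLACEHOLDER_DENSITY[["d-mannitol"]],
    "placeholder", "literature value",
    "Microcrystalline cellulose true_density",
    PLACEHOLDER_DENSITY[["Microcrystalline cellulose"]], "placeholder",
    "literature value",
    "Croscarmellose sodium true_density",
    PLACEHOLDER_DENSITY[["Croscarmellose sodium"]], "placeholder",
    "literature value",
    "Hydroxypropyl cellulose true_density",
    PLACEHOLDER_DENSITY[["Hydroxypropyl cellulose"]], "placeholder",
    "literature value",
    "Magnesium stearate true_density",
    PLACEHOLDER_DENSITY[["Magnesium stearate"]], "placeholder",
    "literature value",
    "ASA layer porosity (multilayer)", 0.074, "paper", "tablet properties",
    "ASA tablet porosity (single)", 0.071, "paper", "tablet properties",
    "MA layer porosity (multilayer)", 0.111, "paper", "tablet properties",
    "MA tablet porosity (single)", 0.137, "paper", "tablet properties",
    "PCL layer porosity", 0.0, "placeholder",
    "melt-compressible wax, effectively nonporous",
    "ingress ASA layer", 0.884, "derived",
    "scaled from measured capillary constants (8.84 : 1.81)",
    "ingress MA layer", 0.181, "derived",
    "scaled from measured capillary constants (8.84 : 1.81)",
    "ingress PCL layer", 0.05, "placeholder", "no pores at 0 porosity",
    "dissolution_resistance ASA", 4, "placeholder", "model constant",
    "dissolution_resistance MA", 6, "placeholder", "model constant",
    "seconds_per_step", 1, "placeholder",
    "calibrate with calibrate_seconds_per_step()"
  )

  structure(
    list(ma_tablet = ma_tablet, asa_tablet = asa_tablet, bilayer = bilayer,
         triple_layer = triple_layer, default_rules = default_rules(),
         provenance = prov),
    class = "fixture_set"
  )
}

#' Synthetic noisy release profile
#'
#' A Noyes-Whitney curve with independent Gaussian noise added per sample,
#' clipped to `[0, 105]` (assay values slightly above 100% are tolerated as
#' noise). Stands in for experimental dissolution curves when only figures,
#' not tables, of the real data exist.
#'
#' @param params An [nw_params()] object.
#' @param times Sampling times in s (default every 5 min over 60 min).
#' @param sigma_abs Absolute noise standard deviation in % of dose
#'   (default 1).
#' @param seed RNG seed; the profile is deterministic per seed.
#' @param species Species label for the output column.
#' @return A tibble `time_s`, `species`, `released_pct`.
#' @export
#' @examples
#' noisy_profile(nw_params(S = 180), seed = 1)
noisy_profile <- function(params, times = seq(300, 3600, by = 300),
                          sigma_abs = 1, seed = 1L, species = "API") {
  stopifnot(inherits(params, "nw_params"), sigma_abs >= 0)
  clean <- nw_release(times, params)
  set.seed(seed)
  noisy <- clean + stats::rnorm(length(times), sd = sigma_abs)
  tibble::tibble(
    time_s = times,
    species = species,
    released_pct = pmin(pmax(noisy, 0), 105)
  )
}

#' Miniature voxel tablets for fast simulation
#'
#' Voxelizes the four study dosage forms at a coarse pitch chosen so the
#' punch major axis spans `scale` voxels, preserving the layer stacking
#' order (ASA bottom, PCL middle, MA top) and the derived layer thickness
#' ratios of the real tablets. Intended for tests and mechanism studies
#' where the full 74-um grid would be needlessly large.
#'
#' @param scale Voxels across the major axis (maximum 50).
#' @param seed Seed for component placement.
#' @return Named list of assigned `voxel_grid`s: `ma`, `asa`, `bilayer`,
#'   `triple`.
#' @export
#' @examples
#' toys <- toy_tablets(scale = 12, seed = 1)
#' dim(toys$triple$state)
toy_tablets <- function(scale = 24, seed = 1L) {
  if (scale > 50) stop("`scale` is capped at 50 voxels.", call. = FALSE)
  fx <- paper_formulations()
  pitch <- 21.5 * 1000 / scale
  vox <- function(spec) {
    assign_components(voxelize(spec, pitch_um = pitch, margin_voxels = 1L),
                      seed = seed)
  }
  list(ma = vox(fx$ma_tablet), asa = vox(fx$asa_tablet),
       bilayer = vox(fx$bilayer), triple = vox(fx$triple_layer))
}
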