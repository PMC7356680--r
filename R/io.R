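# Release-profile CSV dialect: comment header lines starting with '#'
# (provenance: package version, seed, free-form notes), then
# time_s,species,released_pct with period decimal separator, UTF-8.

#' Write a release profile CSV
#'
#' @param profile Tibble with `time_s`, `species`, `released_pct`.
#' @param path Output file.
#' @param seed Optional seed recorded in the provenance header.
#' @param note Optional free-form provenance note.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(profile, path, seed = NULL, note = NULL) {
  prof <- tibble::as_tibble(profile)
  stopifnot(all(c("time_s", "species", "released_pct") %in% names(prof)))
  hdr <- c(
    sprintf("# voxtab release profile v%s",
            as.character(utils::packageVersion("voxtab"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    if (!is.null(note)) paste0("# note: ", note)
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,species,released_pct", con)
  writeLines(sprintf("%s,%s,%s",
                     format(prof$time_s, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     prof$species,
                     format(prof$released_pct, digits = 17, trim = TRUE,
                            scientific = FALSE)), con)
  invisible(path)
}

#' Read a release profile CSV
#'
#' @param path File written by [write_release_csv()] (comment lines starting
#'   with `#` are skipped).
#' @return Tibble `time_s`, `species`, `released_pct`.
#' @export
read_release_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  stopifnot(all(c("time_s", "species", "released_pct") %in% names(df)))
  tibble::as_tibble(df)
}

#' Export a voxel grid as text
#'
#' Writes two files: `<path>.json` (pitch, dimensions, species table, layer
#' labels, placement seed — the provenance sidecar) and `<path>.tsv` (the
#' flattened `state` and `layer` arrays in R column-major order).
#'
#' @param grid A `voxel_grid`.
#' @param path Output path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  meta <- list(
    format = "voxtab-grid",
    version = as.character(utils::packageVersion("voxtab")),
    pitch_um = grid$pitch_um,
    dims = dim(grid$state),
    layer_labels = grid$layer_labels,
    seed = grid$seed,
    species = grid$species
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(
    data.frame(state = as.vector(grid$state), layer = as.vector(grid$layer)),
    paste0(path, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a voxel grid written by [write_grid()]
#'
#' The tablet spec itself is not serialized; re-imported grids carry the
#' species table and arrays needed to run the automaton, and `$spec` is NULL.
#'
#' @param path Path stem used at export.
#' @return A `voxel_grid`.
#' @export
read_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.delim(paste0(path, ".tsv"))
  dims <- as.integer(meta$dims)
  sp <- tibble::as_tibble(meta$species)
  # JSON cannot carry Inf: insoluble resistances come back as NA
  sp$dissolution_resistance[sp$solubility_class == "insoluble"] <- Inf
  structure(
    list(state = array(as.integer(tab$state), dim = dims),
         layer = array(as.integer(tab$layer), dim = dims),
         pitch_um = meta$pitch_um,
         species = sp,
         spec = NULL,
         layer_labels = as.character(meta$layer_labels),
         seed = meta$seed),
    class = "voxel_grid"
  )
}

#' Write a tablet specification as a JSON config document
#'
#' Schema (units fixed by field names): `punch_major_mm`, `punch_minor_mm`,
#' `shape`, and `layers`, a bottom-to-top array of objects with `label`,
#' `mass_mg`, `porosity`, optional `thickness_mm`, and `formulation` — an
#' array of component records (`name`, `weight_fraction`,
#' `true_density_g_cm3`, `solubility_class`, `dissolution_resistance`,
#' `role`, `density_source`).
#'
#' @param spec A [tablet_spec()].
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_tablet_json <- function(spec, path) {
  stopifnot(inherits(spec, "vx_tablet"))
  doc <- list(
    format = "voxtab-tablet",
    version = as.character(utils::packageVersion("voxtab")),
    punch_major_mm = spec$punch_major_mm,
    punch_minor_mm = spec$punch_minor_mm,
    shape = spec$shape,
    layers = purrr::map(spec$layers, function(ly) {
      f <- ly$formulation
      list(label = ly$label, mass_mg = ly$mass_mg, porosity = ly$porosity,
           thickness_mm = ly$thickness_mm,
           formulation = purrr::map(seq_len(nrow(f)), function(i) list(
             name = f$name[i], weight_fraction = f$weight_fraction[i],
             true_density_g_cm3 = f$true_density[i],
             solubility_class = f$solubility_class[i],
             dissolution_resistance = f$dissolution_resistance[i],
             role = f$role[i],
             density_source = f$density_source[i])))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a tablet specification config
#'
#' Accepts the JSON schema of [write_tablet_json()]; `.yaml`/`.yml` files
#' with the same structure are read when the yaml package is installed.
#'
#' @param path Config file path.
#' @return A validated [tablet_spec()].
#' @export
read_tablet_json <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("Reading YAML configs needs the yaml package.", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  layers <- purrr::map(doc$layers, function(ly) {
    f <- dplyr::bind_rows(purrr::map(ly$formulation, function(cm)
      component(cm$name, cm$weight_fraction, cm$true_density_g_cm3,
                cm$solubility_class, cm$dissolution_resistance, cm$role,
                cm$density_source %||% "placeholder")))
    validate_formulation(f)
    th <- ly$thickness_mm
    if (length(th) == 0) th <- NULL # JSON null round-trips as empty
    layer_spec(f, ly$mass_mg, ly$porosity, ly$label, thickness_mm = th)
  })
  tablet_spec(layers, doc$punch_major_mm, doc$punch_minor_mm,
              shape = doc$shape)
}

#' Build an assigned voxel grid from a tablet spec
#'
#' Orchestration wrapper: voxelize, place components, optionally export,
#' return the grid with a porosity summary printed to the console.
#'
#' @param spec A [tablet_spec()].
#' @param pitch_um Voxel pitch in micrometres.
#' @param seed Placement seed (mandatory: the run is stochastic).
#' @param margin_voxels Exterior margin.
#' @param path Optional export path stem for [write_grid()].
#' @param quiet Suppress the summary printout.
#' @return An assigned `voxel_grid`.
#' @export
build_grid <- function(spec, pitch_um, seed, margin_voxels = 1L,
                       path = NULL, quiet = FALSE) {
  grid <- voxelize(spec, pitch_um = pitch_um, margin_voxels = margin_voxels)
  grid <- assign_components(grid, seed = seed)
  if (!quiet) print(grid_summary(grid)$layers)
  if (!is.null(path)) write_grid(grid, path)
  grid
}

#' Simulate release from an assigned grid
#'
#' Orchestration wrapper over [ca_initialize()] and [ca_run()], optionally
#' writing the release profile CSV with its provenance header.
#'
#' @param grid An assigned `voxel_grid`.
#' @param rules A [ca_rules()] object.
#' @param seed Simulation seed (mandatory).
#' @param max_steps,record_interval Passed to [ca_run()].
#' @param csv Optional output CSV path.
#' @return A `ca_result`.
#' @export
simulate_release <- function(grid, rules, seed, max_steps = 5000L,
                             record_interval = 1L, csv = NULL) {
  res <- ca_run(ca_initialize(grid, rules, seed = seed),
                max_steps = max_steps, record_interval = record_interval)
  if (!is.null(csv)) {
    write_release_csv(res$profile, csv, seed = seed,
                      note = sprintf("ca_run %d steps, %g s/step",
                                     res$steps, res$seconds_per_step))
  }
  res
}

#' Fit two profiles and compare them
#'
#' Runs [fit_specific_surface()] on a reference and a test profile with the
#' same fixed constants, computes their [f2_similarity()] and the
#' [surface_reduction_ratio()], and returns a combined report.
#'
#' @param reference,test Single-species release profiles.
#' @param Cs,D,h Fixed Noyes-Whitney constants shared by both fits.
#' @param json Optional path to write the report as JSON.
#' @return A `vx_report` list: `fit_reference`, `fit_test`, `f2`,
#'   `surface_reduction_ratio`, `settings`.
#' @export
fit_and_compare <- function(reference, test, Cs = 100, D = 6e-6, h = 0.45,
                            json = NULL) {
  fr <- fit_specific_surface(reference, Cs = Cs, D = D, h = h)
  ft <- fit_specific_surface(test, Cs = Cs, D = D, h = h)
  rep <- structure(
    list(fit_reference = fr, fit_test = ft,
         f2 = f2_similarity(reference, test),
         surface_reduction_ratio = surface_reduction_ratio(fr, ft),
         settings = list(Cs = Cs, D = D, h = h)),
    class = "vx_report"
  )
  if (!is.null(json)) {
    jsonlite::write_json(
      list(version = as.character(utils::packageVersion("voxtab")),
           settings = rep$settings,
           reference = list(S_hat = fr$S_hat, k_hat = fr$k_hat,
                            r_squared = fr$r_squared, n = fr$n),
           test = list(S_hat = ft$S_hat, k_hat = ft$k_hat,
                       r_squared = ft$r_squared, n = ft$n),
           f2 = rep$f2,
           surface_reduction_ratio = rep$surface_reduction_ratio),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

#' @export
print.vx_report <- function(x, ...) {
  cat("<vx_report>\n")
  cat(sprintf("  reference: S = %.4g cm^2/g (R^2 = %.4f)\n",
              x$fit_reference$S_hat, x$fit_reference$r_squared))
  cat(sprintf("  test:      S = %.4g cm^2/g (R^2 = %.4f)\n",
              x$fit_test$S_hat, x$fit_test$r_squared))
  cat(sprintf("  f2 = %.2f, surface reduction ratio = %.3f\n",
              x$f2, x$surface_reduction_ratio))
  invisible(x)
}
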