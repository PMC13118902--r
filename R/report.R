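# Configuration loading and report assembly: the programmatic surface that
# ties the whole pipeline together. The analysis/ scripts in the repository
# are thin drivers over these functions.

default_config <- function() {
  list(
    particle = list(shape = "cylinder", width = 3.41, length = 12.12),
    material = list(crystallographic_density = 3.09, packing_fraction = 0.64,
                    reference_density_rho0 = 1.0),
    slip = list(mean_free_path_lambda = 0.066, A1 = 1.257, A2 = 0.400, A3 = 0.55),
    shape_factor = list(constant = 2.13),
    impactor = list(flow_rate_lpm = 60, size_limit_um = 5.0,
                    fpf_denominator = "emitted"),
    assay = list(viability_threshold = 80, cytotoxicity_threshold = 20),
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a single YAML or JSON file with blocks `particle`, `material`,
#' `slip`, `shape_factor`, `impactor`, `assay` and a `seed`, merges it over
#' the built-in defaults, and rejects unknown keys (top-level or within a
#' block) with an error listing them. With `path = NULL` the defaults are
#' returned unchanged.
#'
#' @param path Path to a .yaml/.yml/.json config file, or NULL for defaults.
#' @param overrides Optional named list merged on top of the file (the
#'   programmatic equivalent of command-line overrides; highest precedence).
#' @return A validated config list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  if (!is.null(overrides)) {
    user <- utils::modifyList(user, overrides)
  }

  unknown_top <- setdiff(names(user), names(cfg))
  if (length(unknown_top)) {
    stop_validation("unknown config key(s): %s", paste(unknown_top, collapse = ", "))
  }
  for (blk in names(user)) {
    if (is.list(cfg[[blk]]) && is.list(user[[blk]])) {
      # shape_factor selects a provider, so its single key replaces the default
      if (blk != "shape_factor") {
        bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
        if (length(bad)) {
          stop_validation("unknown key(s) in config block '%s': %s",
                          blk, paste(bad, collapse = ", "))
        }
        cfg[[blk]] <- utils::modifyList(cfg[[blk]], user[[blk]])
      } else {
        cfg[[blk]] <- user[[blk]]
      }
    } else {
      cfg[[blk]] <- user[[blk]]
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

config_geometry <- function(cfg) {
  particle_geometry(cfg$particle$shape, cfg$particle$width,
                    if (cfg$particle$shape == "cylinder") cfg$particle$length else NULL)
}

config_material <- function(cfg) {
  material_model(cfg$material$crystallographic_density,
                 cfg$material$packing_fraction,
                 cfg$material$reference_density_rho0)
}

config_slip <- function(cfg) {
  slip_params(cfg$slip$mean_free_path_lambda, cfg$slip$A1, cfg$slip$A2, cfg$slip$A3)
}

#' Theoretical aerodynamic-diameter comparison table
#'
#' Computes the six-row comparison of slip-corrected aerodynamic diameters
#' for a porous/non-porous microrod and the matched porous/non-porous spheres
#' with diameter equal to the rod width and to the rod's volume-equivalent
#' diameter. Rod rows use the configured dynamic shape factor; sphere rows
#' use χ = 1. Diameters are reported at 2 decimals (full precision kept in
#' `da_um`).
#'
#' @param config A `run_config` from [load_config()] (default configuration
#'   describes a 3.41 × 12.12 µm calcium-phosphate rod at packing 0.64,
#'   χ = 2.13).
#' @return Data frame with columns `particle`, `structure`, `dimension_um`,
#'   `chi`, `rho_eff`, `da_um`, `da_rounded`.
#' @export
run_table2_comparison <- function(config = load_config()) {
  geom <- config_geometry(config)
  if (geom$shape != "cylinder") {
    stop_validation("the comparison table requires a cylindrical particle")
  }
  mat <- config_material(config)
  slip <- config_slip(config)
  rho0 <- mat$reference_density_rho0
  dve <- volume_equivalent_diameter(geom)
  chi_rod <- shape_factor_provider(config$shape_factor, AR = aspect_ratio(geom))

  rows <- list(
    list("microrod",      "porous",     dve,        chi_rod),
    list("microrod",      "non-porous", dve,        chi_rod),
    list("sphere (d=w)",   "porous",     geom$width, 1),
    list("sphere (d=w)",   "non-porous", geom$width, 1),
    list("sphere (d=dve)", "porous",     dve,        1),
    list("sphere (d=dve)", "non-porous", dve,        1)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    porous <- r[[2]] == "porous"
    rho <- effective_density(mat, porous)
    sol <- aerodynamic_diameter(r[[3]], rho, r[[4]], slip, rho0)
    data.frame(particle = r[[1]], structure = r[[2]],
               dimension_um = r[[3]], chi = r[[4]], rho_eff = rho,
               da_um = sol$aerodynamic_diameter_da,
               da_rounded = round(sol$aerodynamic_diameter_da, 2))
  }))
  out
}

#' Run the full synthetic pipeline and assemble a consolidated report
#'
#' Executes every stage on synthetic inputs generated under the configured
#' seed: the theoretical aerodynamic prediction for the configured particle,
#' an impactor reduction (MMAD/GSD/FPF/mass balance), MTT and LDH plate
#' reductions, and a disintegration summary. Each stage failure aborts with
#' an error naming the stage. The returned list is deterministic for a fixed
#' config and seed.
#'
#' @param config A `run_config` from [load_config()].
#' @param impactor_csv,mtt_csv,ldh_csv,disintegration_csv Optional paths to
#'   real input files; when NULL (default) the corresponding synthetic
#'   generator supplies the input.
#' @return Nested list (report) with elements `config`, `aero`, `impactor`,
#'   `assays`, `disintegration`.
#' @export
run_full_pipeline <- function(config = load_config(), impactor_csv = NULL,
                              mtt_csv = NULL, ldh_csv = NULL,
                              disintegration_csv = NULL) {
  seed <- as.integer(config$seed)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_validation("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  aero <- with_stage("aero", {
    geom <- config_geometry(config)
    mat <- config_material(config)
    slip <- config_slip(config)
    dve <- volume_equivalent_diameter(geom)
    chi <- if (geom$shape == "sphere") 1 else {
      shape_factor_provider(config$shape_factor, AR = aspect_ratio(geom))
    }
    sol <- aerodynamic_diameter(dve, effective_density(mat, TRUE), chi, slip,
                                mat$reference_density_rho0)
    list(dve_um = dve, chi = chi,
         da_um = sol$aerodynamic_diameter_da,
         Cc_at_dve = sol$Cc_at_dve, Cc_at_da = sol$Cc_at_da,
         iterations = sol$iterations, converged = sol$converged)
  })

  impactor <- with_stage("impactor", {
    run <- if (is.null(impactor_csv)) {
      gen_impactor_run(noise = "multinomial", seed = seed,
                       cutoffs = ngi_cutoffs(config$impactor$flow_rate_lpm))
    } else {
      read_impactor_csv(impactor_csv, ngi_cutoffs(config$impactor$flow_rate_lpm))
    }
    unclass(aerosol_summary(run, config$impactor$size_limit_um,
                            config$impactor$fpf_denominator))
  })

  assays <- with_stage("bioassay", {
    mtt <- if (is.null(mtt_csv)) gen_plate(assay = "MTT", seed = seed)
           else read_plate_csv(mtt_csv, "MTT")
    ldh <- if (is.null(ldh_csv)) {
      gen_plate(assay = "LDH", v_min = 85, seed = seed + 1L)
    } else read_plate_csv(ldh_csv, "LDH")
    list(mtt = reduce_plate(mtt, config$assay$viability_threshold,
                            config$assay$cytotoxicity_threshold),
         ldh = reduce_plate(ldh, config$assay$viability_threshold,
                            config$assay$cytotoxicity_threshold))
  })

  disintegration <- with_stage("disintegration", {
    series <- if (is.null(disintegration_csv)) {
      gen_disintegration("acidic_fast", seed = seed)
    } else read_disintegration_csv(disintegration_csv)
    remaining_fraction(series)
  })

  list(config = unclass(config), aero = aero, impactor = impactor,
       assays = assays, disintegration = disintegration)
}

#' Serialize a pipeline report to JSON
#'
#' Fixed-precision, key-ordered JSON so identical runs are byte-identical
#' (no timestamps are embedded).
#'
#' @param report A report list from [run_full_pipeline()].
#' @param path Optional output file; when NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "columns", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
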