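#' Particle geometry
#'
#' Describes a single particle as either a right circular cylinder (a
#' microrod) or a sphere. For a cylinder, `width` is the diameter of the
#' circular cross-section and `length` the rod length; for a sphere the
#' `width` field is reused as the sphere diameter and `length` is ignored.
#' All lengths are in micrometres.
#'
#' @param shape "cylinder" or "sphere".
#' @param width Cylinder diameter, or sphere diameter, in µm.
#' @param length Cylinder length in µm; ignored for spheres.
#' @return An object of class `particle_geometry`.
#' @examples
#' rod <- particle_geometry("cylinder", width = 3.41, length = 12.12)
#' particle_volume(rod)
#' @export
particle_geometry <- function(shape = c("cylinder", "sphere"), width, length = NULL) {
  shape <- match.arg(shape)
  check_positive(width, "width")
  if (shape == "cylinder") {
    if (is.null(length)) stop_validation("cylinder geometry requires `length`")
    check_positive(length, "length")
  } else {
    length <- NA_real_
  }
  structure(list(shape = shape, width = width, length = length),
            class = "particle_geometry")
}

#' @export
print.particle_geometry <- function(x, ...) {
  if (x$shape == "cylinder") {
    cat(sprintf("cylinder: w = %g um, l = %g um\n", x$width, x$length))
  } else {
    cat(sprintf("sphere: d = %g um\n", x$width))
  }
  invisible(x)
}

#' Material model for porous particles
#'
#' Bundles the crystallographic (skeletal) density of the particle material,
#' the packing fraction of the porous framework, and the reference density of
#' the aerodynamic-diameter convention. The default packing fraction 0.64 is
#' the random-close-packing limit of equal spheres; the effective density of
#' a porous particle is the crystallographic density scaled by this fraction.
#'
#' @param crystallographic_density Skeletal density in g/cm³.
#' @param packing_fraction Solid volume fraction in (0, 1].
#' @param reference_density_rho0 Unit-density convention, g/cm³ (default 1).
#' @return An object of class `material_model`.
#' @examples
#' cap <- material_model(3.09, packing_fraction = 0.64)
#' effective_density(cap, porous = TRUE)
#' @export
material_model <- function(crystallographic_density,
                           packing_fraction = 0.64,
                           reference_density_rho0 = 1.0) {
  check_positive(crystallographic_density, "crystallographic_density")
  check_positive(reference_density_rho0, "reference_density_rho0")
  if (!is.numeric(packing_fraction) || length(packing_fraction) != 1L ||
      !is.finite(packing_fraction) ||
      packing_fraction <= 0 || packing_fraction > 1) {
    stop_validation("`packing_fraction` must lie in (0, 1], got %s",
                    format(packing_fraction))
  }
  structure(list(crystallographic_density = crystallographic_density,
                 packing_fraction = packing_fraction,
                 reference_density_rho0 = reference_density_rho0),
            class = "material_model")
}

#' Particle volume
#'
#' Volume of a cylinder (pi/4 w² l) or sphere (pi/6 d³), in µm³.
#'
#' @param geometry A [particle_geometry()].
#' @return Volume in µm³.
#' @export
particle_volume <- function(geometry) {
  stopifnot(inherits(geometry, "particle_geometry"))
  if (geometry$shape == "cylinder") {
    pi / 4 * geometry$width^2 * geometry$length
  } else {
    pi / 6 * geometry$width^3
  }
}

#' Volume-equivalent diameter
#'
#' Diameter of the sphere with the same volume as the particle. For a
#' cylinder this is (3/2 w² l)^(1/3); for a sphere it is the diameter itself.
#'
#' @param geometry A [particle_geometry()].
#' @return dve in µm.
#' @examples
#' volume_equivalent_diameter(particle_geometry("cylinder", 3.41, 12.12)) # 5.96
#' @export
volume_equivalent_diameter <- function(geometry) {
  stopifnot(inherits(geometry, "particle_geometry"))
  (6 * particle_volume(geometry) / pi)^(1 / 3)
}

#' Aspect ratio of a cylindrical particle
#'
#' Length over width. Undefined for spheres.
#'
#' @param geometry A cylinder [particle_geometry()].
#' @return Dimensionless length/width ratio.
#' @export
aspect_ratio <- function(geometry) {
  stopifnot(inherits(geometry, "particle_geometry"))
  if (geometry$shape != "cylinder") {
    stop_validation("aspect ratio undefined for shape '%s'", geometry$shape)
  }
  geometry$length / geometry$width
}

#' Effective particle density
#'
#' For a porous particle the framework occupies only `packing_fraction` of
#' the envelope volume, so the envelope (effective) density is the
#' crystallographic density times that fraction; a non-porous particle keeps
#' the full crystallographic density.
#'
#' @param material A [material_model()].
#' @param porous Logical; apply the packing correction?
#' @return Density in g/cm³.
#' @export
effective_density <- function(material, porous = TRUE) {
  stopifnot(inherits(material, "material_model"))
  if (isTRUE(porous)) {
    material$crystallographic_density * material$packing_fraction
  } else {
    material$crystallographic_density
  }
}

#' Particle number per milligram of powder
#'
#' Count of particles in 1 mg given the per-particle envelope volume and the
#' effective density: 1 mg / (rho_eff × V), with the µm³ → cm³ conversion
#' handled internally.
#'
#' @param geometry A [particle_geometry()].
#' @param material A [material_model()].
#' @param porous Passed to [effective_density()].
#' @return Particles per milligram.
#' @export
particles_per_milligram <- function(geometry, material, porous = TRUE) {
  rho <- effective_density(material, porous)          # g/cm3
  vol_cm3 <- particle_volume(geometry) / UM3_PER_CM3  # cm3
  mass_mg <- rho * vol_cm3 * MG_PER_G                 # mg per particle
  if (mass_mg <= 0) stop_validation("per-particle mass must be positive")
  1 / mass_mg
}

#' Rod-to-cell dosing ratio
#'
#' Number of microrods dosed per cell in a culture well:
#' concentration × well volume × rods per mg / cell count.
#'
#' @param concentration_mg_ml Particle concentration, mg/mL.
#' @param well_volume_ml Well volume, mL.
#' @param cells Number of cells in the well.
#' @param rods_per_mg Particle count per mg, e.g. from
#'   [particles_per_milligram()].
#' @return Dimensionless particles-per-cell ratio.
#' @export
rod_to_cell_ratio <- function(concentration_mg_ml, well_volume_ml, cells,
                              rods_per_mg) {
  check_nonnegative(concentration_mg_ml, "concentration_mg_ml")
  check_positive(well_volume_ml, "well_volume_ml")
  check_positive(cells, "cells")
  check_positive(rods_per_mg, "rods_per_mg")
  concentration_mg_ml * well_volume_ml * rods_per_mg / cells
}
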