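#' Physical properties of the mobile phase
#'
#' Density and dynamic viscosity of the (aqueous) mobile phase. Defaults are
#' water at 20 degrees C.
#'
#' @param density Mass density in kg/m^3.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return An object of class `fluid_props`.
#' @examples
#' fluid_props()           # water at 20 C
#' fluid_props(1000, 1e-3) # round numbers
#' @export
fluid_props <- function(density = 998, viscosity = 1.002e-3) {
  stopifnot(is.numeric(density), is.numeric(viscosity))
  if (density <= 0 || viscosity <= 0)
    stop("fluid density and viscosity must be strictly positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Chromatographic / MS species parameters
#'
#' One tracked species with its molar mass, pore-access (size-exclusion
#' distribution) coefficient, feed concentration, and optional diffusivity.
#' `pore_access` is the fraction of particle pore volume accessible to the
#' species: 1 for a fully permeating small solute (acetone, Tris), 0 for a
#' fully excluded macromolecule (blue dextran, myoglobin on a desalting
#' resin).
#'
#' @param name Species label.
#' @param molar_mass Molar mass in g/mol.
#' @param pore_access Distribution coefficient K_d in \[0, 1\].
#' @param feed_conc Feed concentration (mM for small solutes, g/L for
#'   proteins; the transport model is linear so the unit is a label).
#' @param conc_unit Concentration unit label, `"mM"` or `"g/L"`.
#' @param diffusivity Molecular diffusivity in m^2/s. If `NULL`, computed
#'   on demand from the molar mass by [molecular_diffusivity()].
#' @return An object of class `species_params`.
#' @examples
#' species_params("tris", molar_mass = 121.14, pore_access = 1, feed_conc = 100)
#' @export
species_params <- function(name, molar_mass, pore_access, feed_conc = 0,
                           conc_unit = "mM", diffusivity = NULL) {
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be > 0", call. = FALSE)
  if (!is.numeric(pore_access) || pore_access < 0 || pore_access > 1)
    stop("pore_access (K_d) must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(feed_conc) || feed_conc < 0)
    stop("feed_conc must be >= 0", call. = FALSE)
  if (!is.null(diffusivity) && diffusivity <= 0)
    stop("diffusivity, when given, must be > 0", call. = FALSE)
  structure(list(name = name, molar_mass = molar_mass,
                 pore_access = pore_access, feed_conc = feed_conc,
                 conc_unit = conc_unit, diffusivity = diffusivity),
            class = "species_params")
}

#' Column geometry and packing parameters
#'
#' Geometry and packing of one size-exclusion column. Defaults describe a
#' 3 x 50 mm microbore column (approx. 353 uL) packed with a dextran
#' desalting resin of 80 um mean particle diameter.
#'
#' @param length Bed length in mm.
#' @param inner_diameter Column inner diameter in mm.
#' @param particle_diameter Mean particle diameter in um.
#' @param interstitial_porosity Interstitial (inter-particle) porosity.
#' @param particle_porosity Intra-particle porosity.
#' @param n_cells Number of axial finite-volume cells (>= 10).
#' @param dead_time Extra-column (system) delay contribution in s.
#' @return An object of class `column_params`.
#' @examples
#' col <- column_params()
#' column_volume(col)  # uL
#' @export
column_params <- function(length = 50, inner_diameter = 3,
                          particle_diameter = 80,
                          interstitial_porosity = 0.38,
                          particle_porosity = 0.6,
                          n_cells = 60, dead_time = 0) {
  if (length <= 0 || inner_diameter <= 0 || particle_diameter <= 0)
    stop("column dimensions must be strictly positive", call. = FALSE)
  if (interstitial_porosity <= 0 || interstitial_porosity >= 1)
    stop("interstitial_porosity must lie in (0, 1)", call. = FALSE)
  if (particle_porosity <= 0 || particle_porosity >= 1)
    stop("particle_porosity must lie in (0, 1)", call. = FALSE)
  if (n_cells < 10) stop("n_cells must be >= 10", call. = FALSE)
  if (dead_time < 0) stop("dead_time must be >= 0", call. = FALSE)
  structure(list(length = length, inner_diameter = inner_diameter,
                 particle_diameter = particle_diameter,
                 interstitial_porosity = interstitial_porosity,
                 particle_porosity = particle_porosity,
                 n_cells = as.integer(n_cells), dead_time = dead_time),
            class = "column_params")
}

#' Column volume in microlitres
#'
#' @param col A [column_params()] object.
#' @return Empty-column volume pi (d/2)^2 L in uL.
#' @export
column_volume <- function(col) {
  stopifnot(inherits(col, "column_params"))
  # mm^3 == uL
  pi * (col$inner_diameter / 2)^2 * col$length
}

# --- unit boundary -----------------------------------------------------------
# External configuration uses bench units (mm, um, uL/min, s); all transport
# arithmetic is SI. Conversion happens only through these helpers.

#' Unit conversions at the configuration boundary
#'
#' The package accepts bench units in configuration (mm, um, uL/min) and
#' computes in SI internally. These helpers are the single conversion
#' boundary.
#'
#' @param x Numeric value(s) in the source unit.
#' @return Value(s) in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
ul_min_to_m3_s <- function(x) x * 1e-9 / 60

#' Interstitial velocity from a volumetric flow rate
#'
#' u_int = Q / (A eps_int) with A the empty-column cross section. This is the
#' standard interstitial convention for packed beds.
#'
#' @param flow_rate Volumetric flow rate in uL/min.
#' @param col A [column_params()] object.
#' @return Interstitial velocity in m/s.
#' @export
interstitial_velocity <- function(flow_rate, col) {
  stopifnot(inherits(col, "column_params"))
  if (flow_rate < 0) stop("flow_rate must be >= 0", call. = FALSE)
  area <- pi * (mm_to_m(col$inner_diameter) / 2)^2
  ul_min_to_m3_s(flow_rate) / (area * col$interstitial_porosity)
}
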