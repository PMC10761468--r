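#' Particle Reynolds number
#'
#' Re_p = u_int d_p rho / eta, with the interstitial velocity as the
#' characteristic velocity and the mean particle diameter as the length
#' scale.
#'
#' @param u_int Interstitial velocity in m/s (>= 0).
#' @param col A [column_params()] object (supplies d_p).
#' @param fluid A [fluid_props()] object.
#' @return Dimensionless particle Reynolds number.
#' @examples
#' particle_reynolds(6.2e-4, column_params(), fluid_props(1000, 1e-3))
#' @export
particle_reynolds <- function(u_int, col, fluid = fluid_props()) {
  stopifnot(inherits(col, "column_params"), inherits(fluid, "fluid_props"))
  if (!is.numeric(u_int) || u_int < 0)
    stop("u_int must be a nonnegative velocity", call. = FALSE)
  u_int * um_to_m(col$particle_diameter) * fluid$density / fluid$viscosity
}

#' Molecular diffusivity from molar mass (Polson correlation)
#'
#' D_m = 2.74e-9 Mw^(-1/3) m^2/s, an empirical correlation adequate for
#' globular solutes from small buffer molecules to proteins. A diffusivity
#' stored on the species overrides the correlation.
#'
#' @param species A [species_params()] object.
#' @return Molecular diffusivity in m^2/s.
#' @examples
#' molecular_diffusivity(species_params("mb", 17566, 0))
#' @export
molecular_diffusivity <- function(species) {
  stopifnot(inherits(species, "species_params"))
  if (!is.null(species$diffusivity)) return(species$diffusivity)
  if (species$molar_mass <= 0)
    stop("molar_mass must be > 0 to evaluate the diffusivity correlation",
         call. = FALSE)
  2.74e-9 * species$molar_mass^(-1 / 3)
}

#' Axial dispersion coefficient (Chung-Wen correlation)
#'
#' D_ax = u_int d_p eps_int / (0.2 + 0.011 (eps_int Re_p)^0.48). By
#' convention a zero velocity returns exactly 0, so SMB zones with
#' momentarily zero flow remain representable.
#'
#' @inheritParams particle_reynolds
#' @return Axial dispersion coefficient in m^2/s.
#' @export
axial_dispersion <- function(u_int, col, fluid = fluid_props()) {
  stopifnot(inherits(col, "column_params"))
  if (!is.numeric(u_int) || u_int < 0)
    stop("u_int must be a nonnegative velocity", call. = FALSE)
  if (u_int == 0) return(0)
  re <- particle_reynolds(u_int, col, fluid)
  eps <- col$interstitial_porosity
  u_int * um_to_m(col$particle_diameter) * eps /
    (0.2 + 0.011 * (eps * re)^0.48)
}

#' Film mass-transfer coefficient (Wilson-Geankoplis correlation)
#'
#' k_film = 1.09 D_m / (2 r_p eps_int) * (eps_int u_int d_p / D_m)^0.33,
#' valid for the low-Reynolds creeping flow typical of microbore SEC.
#'
#' @param species A [species_params()] object (supplies D_m).
#' @param u_int Interstitial velocity in m/s (> 0).
#' @param col A [column_params()] object.
#' @return Film transfer coefficient in m/s.
#' @export
film_transfer <- function(species, u_int, col) {
  stopifnot(inherits(species, "species_params"), inherits(col, "column_params"))
  if (!is.numeric(u_int) || u_int <= 0)
    stop("u_int must be > 0 for the film-transfer correlation", call. = FALSE)
  dm <- molecular_diffusivity(species)
  if (!is.finite(dm) || dm <= 0)
    stop("species diffusivity must be positive and finite", call. = FALSE)
  eps <- col$interstitial_porosity
  dp <- um_to_m(col$particle_diameter)
  rp <- dp / 2
  (1.09 * dm) / (2 * rp * eps) * (eps * u_int * dp / dm)^0.33
}
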