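# Near-cell (proximal) [H+]: per-cell solute fluxes set up diffusion
# gradients around a spherical cell; the steady-state surface offset of
# each solute follows the Sherwood-corrected spherical-diffusion solution
# offset = -F / (4 pi D r Sh).  Surface DIC and TA offsets are then fed
# back through the speciation solver to give [H+] at the cell surface.
# This is the pure-diffusion Sherwood formulation: boundary-layer reaction
# kinetics (CO2 hydration) are not modelled.

# Solute diffusivities in seawater at ~15 degC (m2 s-1).  DIC uses a single
# effective value dominated by bicarbonate.
.default_diffusivities <- c(DIC = 1.2e-9, NH4 = 1.7e-9,
                            NO3 = 1.6e-9, PO4 = 0.6e-9)

# Fixed C-per-biovolume density used to convert population biomass into
# cell abundance (pg C um-3; protist plankton are taken as sharing similar
# C-biovolume densities across sizes).
.c_density_pg_um3 <- 0.2

#' Concentration offset at the surface of a spherical cell
#'
#' Steady-state diffusion to/from a sphere, with a Sherwood-number factor
#' for transport enhancement by motility or turbulence: uptake (positive
#' flux) depletes the surface, release enriches it, and the offset vanishes
#' as `Sh` grows.
#'
#' @param flux_per_cell Solute flux, mol cell-1 s-1, uptake positive.
#' @param D Solute diffusivity, m2 s-1.
#' @param r Cell radius, m.
#' @param Sh Sherwood number (>= 1; 1 = pure diffusion).
#' @return Concentration offset at the cell surface, mol m-3.
#' @export
surface_offset <- function(flux_per_cell, D, r, Sh = 1) {
  stopifnot(D > 0, r > 0, Sh >= 1)
  -flux_per_cell / (4 * pi * D * r * Sh)
}

#' Cell abundance implied by a population biomass
#'
#' Converts population C biomass into cells per litre using a fixed
#' C-per-biovolume density, so per-cell C content scales with cell volume.
#'
#' @param C_biomass Population biomass, ug atom C L-1.
#' @param ESD Cell equivalent spherical diameter, um.
#' @return Cells per litre.
#' @export
cells_per_litre <- function(C_biomass, ESD) {
  stopifnot(C_biomass >= 0, ESD > 0)
  vol_um3 <- pi / 6 * ESD^3
  c_per_cell_umol <- .c_density_pg_um3 * vol_um3 * 1e-12 / 12.011 * 1e6
  C_biomass / c_per_cell_umol
}

#' Convert volumetric fluxes to per-cell fluxes
#'
#' @param volumetric_fluxes Named list/vector (`DIC`, `NH4`, `NO3`, `PO4`)
#'   of population fluxes, ug atom L-1 d-1, uptake positive.
#' @param C_biomass Population biomass, ug atom C L-1.
#' @param ESD Cell ESD, um.
#' @return Named numeric of per-cell fluxes, mol cell-1 s-1 (zero when the
#'   population is empty).
#' @export
per_cell_fluxes <- function(volumetric_fluxes, C_biomass, ESD) {
  f <- unlist(volumetric_fluxes)
  cells <- cells_per_litre(C_biomass, ESD)
  if (cells <= 0) return(f * 0)
  f * 1e-6 / 86400 / cells
}

#' Parameters of the proximal [H+] calculation
#'
#' @param ESD Cell ESD, um.
#' @param fluxes_per_cell Named numeric (`DIC`, `NH4`, `NO3`, `PO4`),
#'   mol cell-1 s-1, uptake positive.
#' @param Sh Sherwood number (>= 1).
#' @param diffusivities Named numeric of solute diffusivities, m2 s-1.
#' @return A `proximal_params` list.
#' @export
proximal_params <- function(ESD, fluxes_per_cell, Sh = 1,
                            diffusivities = .default_diffusivities) {
  stopifnot(ESD > 0, Sh >= 1, all(diffusivities > 0))
  need <- c("DIC", "NH4", "NO3", "PO4")
  if (!all(need %in% names(fluxes_per_cell))) {
    stop("fluxes_per_cell must name ", paste(need, collapse = ", "))
  }
  structure(list(radius_m = ESD * 1e-6 / 2,
                 fluxes = fluxes_per_cell[need],
                 Sh = Sh, diffusivities = diffusivities[need]),
            class = "proximal_params")
}

#' [H+] and pH at the cell surface
#'
#' Applies the per-solute surface offsets to the bulk DIC and (via the
#' standard charge-balance stoichiometry of nitrate, ammonium and
#' phosphate) to the bulk TA, then re-solves the speciation at the surface
#' values.  Zero fluxes return the bulk state; net DIC uptake in the light
#' gives a proximal [H+] below bulk, net respiration in the dark above it.
#'
#' @param bulk A `carbonate_state` (or any list with `DIC` and `TA`,
#'   umol kg-1).
#' @param params A [proximal_params()].
#' @param constants An [equilibrium_constants()] object.
#' @return A `carbonate_state` at the cell surface.
#' @export
proximal_H <- function(bulk, params, constants = equilibrium_constants()) {
  stopifnot(inherits(params, "proximal_params"))
  off <- vapply(c("DIC", "NH4", "NO3", "PO4"), function(sol) {
    surface_offset(params$fluxes[[sol]], params$diffusivities[[sol]],
                   params$radius_m, params$Sh)
  }, numeric(1))
  off_umol <- off * 1000  # mol m-3 -> umol kg-1 (density taken as 1 kg L-1)
  surf_DIC <- bulk$DIC + off_umol[["DIC"]]
  surf_TA <- bulk$TA + alkalinity_increment(
    net_flux_NH4 = -off_umol[["NH4"]],
    net_flux_NO3 = -off_umol[["NO3"]],
    net_flux_PO4 = -off_umol[["PO4"]])
  if (surf_DIC <= 0 || surf_TA <= 0) {
    stop("unphysical flux/size combination: surface DIC = ",
         signif(surf_DIC, 5), ", surface TA = ", signif(surf_TA, 5))
  }
  solve_speciation(surf_DIC, surf_TA, constants)
}
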