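# Scenario configuration: the closed batch-culture study conditions.
# Defaults are the study conditions: DIN/DIP at Redfield (NH4 10 uM, NO3
# 10 uM, PO4 1.25 uM), non-growing Redfield prey with 20 ug atom N L-1
# (hence 132.5 ug atom C L-1), saturating light (PFD 500) in a 0.7:0.3
# light:dark cycle, 15 degC, salinity 35, TA 2300 umol kg-1, and both the
# early-industrial (300 uatm) and end-of-century (600 uatm) pCO2 variants.

#' Build the default (Redfield) prey field
#'
#' Prey carbon follows from the target prey nitrogen by Redfield
#' stoichiometry (C:N:P = 106:16:1), optionally degraded in quality:
#' `quality = 0.5` halves the prey N:C and P:C (same N and P spread over
#' twice the C).  Prey are 5 um ESD, non-growing, and carry chloroplast
#' material equal to 10% of prey C (as C-equivalent Chl) to support
#' acquired phototrophy.
#'
#' @param N_target Prey nitrogen, ug atom N L-1 (default 20, matching the
#'   dissolved inorganic N supply).
#' @param quality Relative prey N:C and P:C (1 = Redfield).
#' @param chl_frac Prey chloroplast content as a fraction of prey C.
#' @return A [prey_field()].
#'
#' @examples
#' build_default_prey(20)$prey_C                  # 132.5
#' build_default_prey(40)$prey_C                  # 265 (doubled abundance)
#' build_default_prey(20, quality = 0.5)$prey_C   # 265, N and P unchanged
#' @export
build_default_prey <- function(N_target = 20, quality = 1, chl_frac = 0.1) {
  stopifnot(N_target > 0, quality > 0, chl_frac >= 0)
  prey_C <- N_target * (106 / 16) / quality
  prey_field(prey_C = prey_C,
             prey_N = N_target,
             prey_P = N_target / 16,
             prey_Chl = chl_frac * prey_C,
             prey_ESD = 5)
}

#' Define a closed batch-culture scenario
#'
#' @param config A [make_config()] functional-type configuration.
#' @param initial_biomass_C Inoculum, ug atom C L-1; N and P follow at
#'   Redfield, Chl at half the ceiling for constitutive phototrophs and 0
#'   for acquired/none modes.
#' @param prey A [prey_field()] (set `prey_C = 0` for no prey).
#' @param NH4,NO3,PO4 Initial inorganic nutrients, uM.
#' @param PFD_light Photon flux density in the light phase,
#'   umol photons m-2 s-1.
#' @param light_fraction Fraction of each day in the light (first part of
#'   the day); the remainder is dark.
#' @param pCO2_init Atmospheric pCO2 values (uatm) for the initial air-sea
#'   equilibrium; each becomes one chemistry variant of the run (the
#'   biology is identical across variants).
#' @param TA_init Initial total alkalinity, umol kg-1.
#' @param temperature,salinity Water properties for the carbonate system.
#' @param duration Run length, days.
#' @param dt_out Output timestep, days.
#' @param rtol,atol Integrator tolerances.
#' @param proximal Compute near-cell (proximal) [H+] columns?
#' @param Sh Sherwood-number transport enhancement for the proximal
#'   calculation (1 = pure diffusion around a non-motile cell; the motile
#'   default is 2).
#' @param label Optional scenario label.
#' @return A `scenario` list.
#' @export
make_scenario <- function(config = make_config("CM"),
                          initial_biomass_C = 0.2,
                          prey = build_default_prey(),
                          NH4 = 10, NO3 = 10, PO4 = 1.25,
                          PFD_light = 500, light_fraction = 0.7,
                          pCO2_init = c(300, 600), TA_init = 2300,
                          temperature = 15, salinity = 35,
                          duration = 20, dt_out = 0.02,
                          rtol = 1e-8, atol = 1e-10,
                          proximal = FALSE, Sh = 2,
                          label = NULL) {
  stopifnot(inherits(config, "protist_config"), inherits(prey, "prey_field"))
  if (light_fraction <= 0 || light_fraction >= 1) {
    stop("light_fraction must lie strictly between 0 and 1")
  }
  if (duration <= 0) stop("duration must be positive")
  if (any(c(initial_biomass_C, NH4, NO3, PO4) < 0)) {
    stop("initial pools must be non-negative")
  }
  if (any(pCO2_init <= 0) || TA_init <= 0) {
    stop("pCO2_init and TA_init must be positive")
  }
  structure(list(
    config = config, initial_biomass_C = initial_biomass_C, prey = prey,
    NH4 = NH4, NO3 = NO3, PO4 = PO4,
    PFD_light = PFD_light, light_fraction = light_fraction,
    pCO2_init = pCO2_init, TA_init = TA_init,
    temperature = temperature, salinity = salinity,
    duration = duration, dt_out = dt_out, rtol = rtol, atol = atol,
    proximal = proximal, Sh = Sh,
    label = if (is.null(label)) config$name else label
  ), class = "scenario")
}

#' Irradiance forcing
#'
#' Square-wave light:dark cycle: `PFD_light` while the day fraction is
#' below `light_fraction`, zero (dark) for the remainder of each day.
#'
#' @param t Time, days.
#' @param scenario A [make_scenario()].
#' @return PFD, umol photons m-2 s-1 (vectorised over `t`).
#' @export
irradiance <- function(t, scenario) {
  stopifnot(all(t >= 0))
  ifelse((t - floor(t)) < scenario$light_fraction, scenario$PFD_light, 0)
}
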