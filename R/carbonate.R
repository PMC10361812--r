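# Seawater CO2-system speciation.
#
# The carbonate chemistry runs strictly downstream of the biology: the
# physiology model produces cumulative DIC and total-alkalinity changes, and
# this module re-solves the speciation (and hence [H+]/pH) of the water
# parcel at those values.  There is no feedback from chemistry to physiology.
#
# Constant formulations (all on the total pH scale, mol kg-1):
#   K0  CO2 solubility, Weiss (1974)
#   K1, K2  carbonic acid, Lueker et al. (2000)
#   KB  boric acid, Dickson (1990)
#   KW  water, Millero (1995)
#   BT  total borate from salinity, Uppstrom (1974)

#' Equilibrium constants for the seawater CO2 system
#'
#' Computes the thermodynamic constants needed to speciate the carbonate
#' system at a given temperature and salinity, on the total pH scale.
#' Deterministic: repeated calls with the same inputs give identical values.
#'
#' @param temperature Temperature in degrees Celsius; must lie in `[0, 40]`,
#'   the validity range of the chosen formulations.
#' @param salinity Practical salinity; must lie in `[20, 40]`.
#'
#' @return An object of class `carb_constants`: a list with elements `K0`
#'   (mol kg-1 atm-1), `K1`, `K2`, `KB`, `KW` (mol kg-1 scales), `BT`
#'   (total borate, mol kg-1), and the input `temperature` and `salinity`.
#'
#' @examples
#' k <- equilibrium_constants(15, 35)
#' k$K1 > k$K2
#' @export
equilibrium_constants <- function(temperature = 15, salinity = 35) {
  if (!is.finite(temperature) || temperature < 0 || temperature > 40) {
    stop("temperature must be in [0, 40] degC (validity range of the ",
         "constant formulations); got ", temperature)
  }
  if (!is.finite(salinity) || salinity < 20 || salinity > 40) {
    stop("salinity must be in [20, 40] (validity range of the constant ",
         "formulations); got ", salinity)
  }
  TK <- temperature + 273.15
  S <- salinity
  sqS <- sqrt(S)

  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)

  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * log(TK) -
    0.01781 * S + 0.0001122 * S^2

  lnKB <- (-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * S +
    (-24.4344 - 25.085 * sqS - 0.2474 * S) * log(TK) +
    0.053105 * sqS * TK

  lnKW <- 148.9652 - 13847.26 / TK - 23.6521 * log(TK) +
    (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqS - 0.01615 * S

  structure(list(
    K0 = exp(lnK0),
    K1 = 10^-pK1,
    K2 = 10^-pK2,
    KB = exp(lnKB),
    KW = exp(lnKW),
    BT = 0.0004157 * S / 35,
    temperature = temperature,
    salinity = salinity
  ), class = "carb_constants")
}

# Total alkalinity (mol kg-1) implied by [H+] at a given DIC (mol kg-1):
# TA = [HCO3] + 2[CO3] + [B(OH)4] + [OH] - [H]
.ta_from_h <- function(h, dic, k) {
  denom <- h * h + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  hco3 + 2 * co3 + k$BT * k$KB / (k$KB + h) + k$KW / h - h
}

.carbonate_state <- function(h, dic, ta, k) {
  denom <- h * h + k$K1 * h + k$K1 * k$K2
  co2aq <- dic * h * h / denom
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  structure(list(
    DIC = dic * 1e6,
    TA = ta * 1e6,
    H = h,
    pH = -log10(h),
    CO2aq = co2aq * 1e6,
    HCO3 = hco3 * 1e6,
    CO3 = co3 * 1e6,
    pCO2 = co2aq / k$K0 * 1e6
  ), class = "carbonate_state")
}

#' @export
print.carbonate_state <- function(x, ...) {
  cat(sprintf(
    "carbonate state: pH %.4f  [H+] %.4g mol/kg  DIC %.1f  TA %.1f  pCO2 %.1f uatm\n",
    x$pH, x$H, x$DIC, x$TA, x$pCO2))
  invisible(x)
}

#' Solve the CO2-system speciation from DIC and total alkalinity
#'
#' Finds the unique physically meaningful `[H+]` root of the alkalinity
#' balance `TA = [HCO3] + 2[CO3] + [B(OH)4] + [OH] - [H]` on the fixed pH
#' bracket `[2, 12]`, then speciates DIC at that `[H+]`.
#'
#' @param DIC Dissolved inorganic carbon, umol kg-1 (> 0).
#' @param TA Total alkalinity, umol kg-1 (> 0).
#' @param constants A [equilibrium_constants()] object.
#'
#' @return A `carbonate_state`: list with `DIC`, `TA`, `CO2aq`, `HCO3`,
#'   `CO3` (umol kg-1), `H` (mol kg-1, total scale), `pH` and `pCO2` (uatm).
#'   The returned speciation satisfies `CO2aq + HCO3 + CO3 = DIC` and
#'   reproduces `TA` to better than 1e-9 relative.
#'
#' @examples
#' k <- equilibrium_constants(15, 35)
#' solve_speciation(2100, 2300, k)
#' @export
solve_speciation <- function(DIC, TA, constants = equilibrium_constants()) {
  stopifnot(inherits(constants, "carb_constants"))
  if (!is.finite(DIC) || DIC <= 0) stop("DIC must be positive; got ", DIC)
  if (!is.finite(TA) || TA <= 0) stop("TA must be positive; got ", TA)
  dic <- DIC * 1e-6
  ta <- TA * 1e-6
  f <- function(ph) .ta_from_h(10^-ph, dic, constants) - ta
  flo <- f(2)
  fhi <- f(12)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("no [H+] root in pH [2, 12] for DIC = ", DIC, ", TA = ", TA,
         " (f(pH=2) = ", signif(flo, 4), ", f(pH=12) = ", signif(fhi, 4), ")")
  }
  ph <- stats::uniroot(f, lower = 2, upper = 12, tol = 1e-13)$root
  h <- 10^-ph
  # Newton polish on H to drive the TA residual below 1e-9 relative
  for (i in 1:3) {
    res <- .ta_from_h(h, dic, constants) - ta
    if (abs(res) < 1e-10 * ta) break
    eps <- h * 1e-7
    dres <- (.ta_from_h(h + eps, dic, constants) -
               .ta_from_h(h - eps, dic, constants)) / (2 * eps)
    h <- h - res / dres
  }
  .carbonate_state(h, dic, ta, constants)
}

#' Equilibrate a water parcel with a stated atmospheric pCO2
#'
#' Computes the initial carbonate state of a water body at air-sea
#' equilibrium: `CO2aq = K0 * pCO2`, with DIC solved so that speciation at
#' the given total alkalinity yields exactly that `CO2aq`.  Used to
#' initialise the closed batch system before biology perturbs DIC and TA.
#'
#' @param pCO2 Atmospheric partial pressure of CO2, uatm (> 0).
#' @param TA Total alkalinity, umol kg-1 (> 0).
#' @param constants A [equilibrium_constants()] object.
#'
#' @return A `carbonate_state` (see [solve_speciation()]) whose recomputed
#'   `pCO2` equals the input to 1e-6 relative.
#'
#' @examples
#' k <- equilibrium_constants(15, 35)
#' equilibrate_with_atmosphere(300, 2300, k)
#' @export
equilibrate_with_atmosphere <- function(pCO2, TA,
                                        constants = equilibrium_constants()) {
  stopifnot(inherits(constants, "carb_constants"))
  if (!is.finite(pCO2) || pCO2 <= 0) stop("pCO2 must be positive; got ", pCO2)
  if (!is.finite(TA) || TA <= 0) stop("TA must be positive; got ", TA)
  k <- constants
  ta <- TA * 1e-6
  co2aq <- k$K0 * pCO2 * 1e-6
  f <- function(ph) {
    h <- 10^-ph
    hco3 <- co2aq * k$K1 / h
    co3 <- co2aq * k$K1 * k$K2 / (h * h)
    (hco3 + 2 * co3 + k$BT * k$KB / (k$KB + h) + k$KW / h - h) - ta
  }
  if (f(2) * f(12) > 0) {
    stop("atmospheric equilibration failed to bracket a root in pH [2, 12] ",
         "for pCO2 = ", pCO2, ", TA = ", TA)
  }
  ph <- stats::uniroot(f, lower = 2, upper = 12, tol = 1e-13)$root
  h <- 10^-ph
  dic <- co2aq * (1 + k$K1 / h + k$K1 * k$K2 / (h * h))
  st <- .carbonate_state(h, dic, ta, k)
  if (abs(st$pCO2 - pCO2) > 1e-6 * pCO2) {
    stop("atmospheric equilibration did not converge: recomputed pCO2 = ",
         st$pCO2, " vs input ", pCO2)
  }
  st
}

#' Total-alkalinity increment from net nutrient fluxes
#'
#' Standard charge-balance bookkeeping for the alkalinity effect of
#' biological nutrient use: nitrate uptake raises TA by one equivalent per
#' mole, ammonium uptake lowers it by one, phosphate uptake raises it by
#' one; release is negative uptake, so (for example) ammonium regeneration
#' by heterotrophs raises TA and damps the concurrent [H+] rise from
#' respired CO2.
#'
#' @param net_flux_NH4,net_flux_NO3,net_flux_PO4 Net uptake (positive) or
#'   release (negative) in umol kg-1 (or umol kg-1 d-1 for a rate).
#'
#' @return The TA change (or rate of change), same units as the inputs.
#'
#' @examples
#' alkalinity_increment(net_flux_NH4 = -1, 0, 0)  # NH4 release: TA +1
#' @export
alkalinity_increment <- function(net_flux_NH4 = 0, net_flux_NO3 = 0,
                                 net_flux_PO4 = 0) {
  stopifnot(is.finite(net_flux_NH4), is.finite(net_flux_NO3),
            is.finite(net_flux_PO4))
  net_flux_NO3 - net_flux_NH4 + net_flux_PO4
}
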