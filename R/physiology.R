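# The mass-conserving protist flux model: quota-controlled phototrophy,
# inorganic uptake, phagotrophy with voiding and specific dynamic action
# (SDA), internal recycling of SDA releases to concurrent photosynthetic and
# nutrient demands, acquired-phototrophy dynamics, leakage and respiration.
#
# Units: biomass and dissolved pools in ug atom L-1 (== uM atom, taken 1:1
# with umol kg-1), rates per day.  Chl is carried as a C-equivalent tracer
# attached to biomass and sits outside the elemental C budget (chloroplast
# carbon is part of biomass C; the Chl pool indexes photosystem competence).

#' Construct a protist population state
#'
#' @param C,N,P Population biomass, ug atom L-1; quotas `N/C` and `P/C`
#'   must lie within the configured Droop bounds.
#' @param Chl Photosystem content, ug atom C-equivalent L-1.
#' @param acquired_capacity Acquired-phototrophy competence in `[0, 1]`;
#'   forced to 1 for constitutively photosynthetic types and 0 for
#'   heterotrophs without acquisition.
#' @param config A [make_config()] object used to validate quotas.
#'
#' @return A `protist_state` list.
#' @export
protist_state <- function(C, N, P, Chl = 0, acquired_capacity = NULL,
                          config = NULL) {
  if (any(!is.finite(c(C, N, P, Chl))) || any(c(C, N, P, Chl) < 0)) {
    stop("biomass pools must be finite and non-negative")
  }
  if (!is.null(config)) {
    if (config$can_photosynthesize_constitutively) {
      acquired_capacity <- 1
    } else if (config$acquired_phototrophy_mode == "none") {
      acquired_capacity <- 0
    } else if (is.null(acquired_capacity)) {
      acquired_capacity <- 0
    }
    if (C > 0) .check_quotas(N / C, P / C, config)
  }
  if (is.null(acquired_capacity)) acquired_capacity <- 1
  if (acquired_capacity < 0 || acquired_capacity > 1) {
    stop("acquired_capacity must lie in [0, 1]")
  }
  structure(list(C = C, N = N, P = P, Chl = Chl,
                 acquired_capacity = acquired_capacity),
            class = "protist_state")
}

.check_quotas <- function(QN, QP, config, tol = 1e-6) {
  if (QN < config$NC_min * (1 - tol) || QN > config$NC_max * (1 + tol)) {
    stop("N:C quota ", signif(QN, 6), " outside [", config$NC_min, ", ",
         config$NC_max, "]")
  }
  if (QP < config$PC_min * (1 - tol) || QP > config$PC_max * (1 + tol)) {
    stop("P:C quota ", signif(QP, 6), " outside [", config$PC_min, ", ",
         config$PC_max, "]")
  }
  invisible(TRUE)
}

#' Construct the dissolved-pool state
#'
#' @param NH4,NO3,PO4 Inorganic nutrients, uM.
#' @param DOC,DON,DOP Leaked dissolved organics, uM atom.
#' @param VOC,VON,VOP Voided organics (micro-faeces, operationally
#'   "dissolved"), uM atom.
#' @param DIC_biological_delta Cumulative biological DIC change, umol kg-1
#'   (any sign), applied downstream by the carbonate module.
#' @return A `dissolved_pools` list.
#' @export
dissolved_pools <- function(NH4 = 10, NO3 = 10, PO4 = 1.25,
                            DOC = 0, DON = 0, DOP = 0,
                            VOC = 0, VON = 0, VOP = 0,
                            DIC_biological_delta = 0) {
  p <- list(NH4 = NH4, NO3 = NO3, PO4 = PO4, DOC = DOC, DON = DON,
            DOP = DOP, VOC = VOC, VON = VON, VOP = VOP,
            DIC_biological_delta = DIC_biological_delta)
  nn <- unlist(p[setdiff(names(p), "DIC_biological_delta")])
  if (any(!is.finite(nn)) || any(nn < 0)) {
    stop("dissolved pools must be finite and non-negative")
  }
  structure(p, class = "dissolved_pools")
}

#' Construct a prey field
#'
#' Non-growing prey of fixed stoichiometry, with associated chloroplast
#' material (as C-equivalent Chl) available for acquisition by
#' non-constitutive mixoplankton.
#'
#' @param prey_C,prey_N,prey_P Prey biomass, ug atom L-1.
#' @param prey_Chl Prey chloroplast material, ug atom C-equivalent L-1.
#' @param prey_ESD Prey cell diameter, um.
#' @return A `prey_field` list.
#' @export
prey_field <- function(prey_C, prey_N, prey_P, prey_Chl = 0.1 * prey_C,
                       prey_ESD = 5) {
  v <- c(prey_C, prey_N, prey_P, prey_Chl, prey_ESD)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("prey fields must be finite and non-negative")
  }
  structure(list(prey_C = prey_C, prey_N = prey_N, prey_P = prey_P,
                 prey_Chl = prey_Chl, prey_ESD = prey_ESD),
            class = "prey_field")
}

# De-repression sigmoid: 0 when satiated (stress 0), exactly 1 at maximal
# stress, monotone and smooth in between.  k is the half-saturation stress;
# trophic priority shifts k of the deprioritised mechanism upwards, so that
# mechanism is de-repressed (enabled) only at higher levels of stress.
.derepression <- function(stress, k, h) {
  stress <- pmin(pmax(stress, 0), 1)
  stress^h * (1 + k^h) / (stress^h + k^h)
}

#' Nutrient-status control factors for acquisition
#'
#' Phototrophy, phagotrophy and inorganic uptake are repressed when the
#' cell is nutrient-replete and de-repressed as the internal N:C / P:C
#' quotas fall towards their minima.  By default both trophic mechanisms
#' respond to the same (worst-element) nutrient stress; `priority =
#' "photo_first"` leaves phototrophy at the default threshold and
#' de-represses phagotrophy only at stronger stress, `"phago_first"` the
#' converse.  Per-nutrient uptake controls respond to that nutrient's own
#' quota.
#'
#' @param state A [protist_state()].
#' @param config A [make_config()].
#' @return List with `photo_control`, `phago_control` and `uptake_controls`
#'   (named `NH4`, `NO3`, `PO4`), all in `[0, 1]`.
#' @export
control_factors <- function(state, config) {
  if (state$C <= 0) {
    u <- c(NH4 = 0, NO3 = 0, PO4 = 0)
    return(list(photo_control = 0, phago_control = 0, uptake_controls = u))
  }
  QN <- state$N / state$C
  QP <- state$P / state$C
  .check_quotas(QN, QP, config)
  sN <- min(max((QN - config$NC_min) / (config$NC_max - config$NC_min), 0), 1)
  sP <- min(max((QP - config$PC_min) / (config$PC_max - config$PC_min), 0), 1)
  stress <- 1 - min(sN, sP)
  h <- config$control_shape
  k_photo <- config$control_k
  k_phago <- config$control_k
  if (config$priority == "photo_first") {
    k_phago <- k_phago + config$priority_shift
  } else if (config$priority == "phago_first") {
    k_photo <- k_photo + config$priority_shift
  }
  list(
    photo_control = .derepression(stress, k_photo, h),
    phago_control = .derepression(stress, k_phago, h),
    # transporters satiate faster than the trophic controls (steeper Hill),
    # giving the quota a stable interior equilibrium during replete growth
    uptake_controls = c(
      NH4 = .derepression(1 - sN, config$control_k,
                          config$uptake_control_shape),
      NO3 = .derepression(1 - sN, config$control_k,
                          config$uptake_control_shape),
      PO4 = .derepression(1 - sP, config$control_k,
                          config$uptake_control_shape)
    )
  )
}

#' Gross photosynthetic C fixation
#'
#' Exponential-saturation P-I response scaled by relative photosystem
#' content (Chl:C against its ceiling), nutrient-quota control and, for
#' non-constitutive mixoplankton, the acquired-phototrophy capacity.
#' At the default 500 umol photons m-2 s-1 the response is light-saturated
#' (> 99% of maximum); 50 umol m-2 s-1 is strongly limiting.  A C-use
#' satiation term shuts fixation down as the cell attains its maximum C:N
#' (or C:P) stoichiometry - phototrophy continues while the quota is above
#' its minimum and stops there, so stoichiometric overflow to DOC is
#' transient, not perpetual.
#'
#' @param state A [protist_state()].
#' @param PFD Photon flux density, umol photons m-2 s-1.
#' @param config A [make_config()].
#' @return Gross C fixation, ug atom C L-1 d-1.
#' @export
gross_photosynthesis <- function(state, PFD, config) {
  stopifnot(PFD >= 0)
  if (state$C <= 0 || state$Chl <= 0) return(0)
  capacity <- if (config$can_photosynthesize_constitutively) 1
              else state$acquired_capacity
  if (capacity <= 0) return(0)
  ctrl <- control_factors(state, config)$photo_control
  chl_frac <- min(state$Chl / (state$C * config$ChlC_max), 1)
  QN <- state$N / state$C
  QP <- state$P / state$C
  sN <- min(max((QN - config$NC_min) / (config$NC_max - config$NC_min), 0), 1)
  sP <- min(max((QP - config$PC_min) / (config$PC_max - config$PC_min), 0), 1)
  c_use <- 1 - (1 - min(sN, sP))^4
  config$pmax_mult * config$mu_max * ctrl * capacity * chl_frac * c_use *
    (1 - exp(-PFD / config$K_PFD)) * state$C
}

#' Inorganic nutrient uptake rates
#'
#' Michaelis-Menten uptake scaled by the per-nutrient quota controls.
#' Ammonium multiplicatively represses nitrate uptake; types lacking a
#' transporter (GNCM for nitrate; zooplankton for everything) take up
#' nothing.
#'
#' @param state A [protist_state()].
#' @param pools A [dissolved_pools()].
#' @param config A [make_config()].
#' @return Named list of volumetric uptake rates `NH4`, `NO3`, `PO4`
#'   (uM d-1).
#' @export
inorganic_uptake <- function(state, pools, config) {
  if (state$C <= 0) return(list(NH4 = 0, NO3 = 0, PO4 = 0))
  ctrl <- control_factors(state, config)$uptake_controls
  NH4 <- max(pools$NH4, 0)
  NO3 <- max(pools$NO3, 0)
  PO4 <- max(pools$PO4, 0)
  vN <- config$vmax_N_mult * config$mu_max * config$NC_max * state$C
  vP <- config$vmax_P_mult * config$mu_max * config$PC_max * state$C
  up_NH4 <- if (config$can_use_NH4) {
    vN * ctrl[["NH4"]] * NH4 / (NH4 + config$half_sat_NH4)
  } else 0
  up_NO3 <- if (config$can_use_NO3) {
    inhib <- config$NH4_inhibition / (config$NH4_inhibition + NH4)
    vN * ctrl[["NO3"]] * inhib * NO3 / (NO3 + config$half_sat_NO3)
  } else 0
  up_PO4 <- if (config$can_use_NH4 || config$can_use_NO3) {
    vP * ctrl[["PO4"]] * PO4 / (PO4 + config$half_sat_PO4)
  } else 0
  list(NH4 = up_NH4, NO3 = up_NO3, PO4 = up_PO4)
}

#' Ingestion of prey
#'
#' Type II (rectangular hyperbolic) functional response in prey C, scaled
#' by the phagotrophy control and an encounter factor proportional to
#' predator ESD (larger protists encounter more prey).  N, P and Chl are
#' ingested in prey stoichiometric proportion.
#'
#' @param state A [protist_state()].
#' @param prey A [prey_field()].
#' @param config A [make_config()].
#' @return Named list of ingestion rates `C`, `N`, `P`, `Chl`
#'   (ug atom L-1 d-1).
#' @export
ingestion <- function(state, prey, config) {
  zero <- list(C = 0, N = 0, P = 0, Chl = 0)
  if (!config$can_ingest || state$C <= 0 || prey$prey_C <= 0) return(zero)
  ctrl <- control_factors(state, config)$phago_control
  encounter <- config$ESD / 20
  preyC <- max(prey$prey_C, 0)
  ing_C <- config$g_max_mult * config$mu_max * encounter * ctrl *
    preyC / (preyC + config$grazing_half_sat) * state$C
  list(C = ing_C,
       N = ing_C * prey$prey_N / preyC,
       P = ing_C * prey$prey_P / preyC,
       Chl = ing_C * prey$prey_Chl / preyC)
}

#' Partition ingested matter into voiding, SDA release and anabolate
#'
#' A fraction `1 - AE` of ingested material is egested as voided organic
#' matter; of the retained fraction, `SDA` is lost on anabolism as CO2,
#' ammonium and phosphate equivalents (specific dynamic action) and the
#' remainder enters the metabolite pool.  Poor-quality (C-rich) food is
#' handled less efficiently, as per stoichiometric ecology: the carbon
#' assimilation efficiency is degraded by the square root of the relative
#' food quality (ingested N:C and P:C against Redfield), so an inferior
#' diet voids more carbon; N and P are always retained at `AE`.  The three
#' outputs sum exactly to the input for each element.
#'
#' @param ingested Named list/vector with elements `C`, `N`, `P` (rates).
#' @param config A [make_config()].
#' @return List of per-element rates: `voided`, `sda_gross`, `anabolate`.
#' @export
digestion_partition <- function(ingested, config) {
  ing <- c(C = ingested$C, N = ingested$N, P = ingested$P)
  stopifnot(all(ing >= 0))
  quality <- if (ing[["C"]] > 0) {
    min((ing[["N"]] / ing[["C"]]) / (16 / 106),
        (ing[["P"]] / ing[["C"]]) / (1 / 106), 1)
  } else 1
  AE <- c(C = config$AE * sqrt(quality), N = config$AE, P = config$AE)
  voided <- (1 - AE) * ing
  retained <- AE * ing
  sda <- config$SDA * retained
  list(voided = as.list(voided),
       sda_gross = as.list(sda),
       anabolate = as.list(retained - sda))
}

#' Internal recycling of SDA releases
#'
#' CO2, ammonium and phosphate released by specific dynamic action inside a
#' mixoplankton are available to concurrent photosynthetic C demand and
#' nutrient demand before anything reaches the environment: the recycled
#' share is `min(release, demand)` element-wise, and only the remainder is
#' released externally.  A zooplankton (zero photosynthetic and inorganic
#' demand) releases everything.
#'
#' @param sda_gross Named list `C`, `N`, `P` of gross SDA release rates.
#' @param photosynthetic_demand_C Gross C fixation rate (the CO2 demand).
#' @param nutrient_demand_N,nutrient_demand_P Concurrent inorganic-nutrient
#'   demand rates (the cell's uptake appetite).
#' @return List `recycled` and `net_external`, each with `C`, `N`, `P`.
#' @export
sda_recycle <- function(sda_gross, photosynthetic_demand_C,
                        nutrient_demand_N, nutrient_demand_P) {
  rel <- c(C = sda_gross$C, N = sda_gross$N, P = sda_gross$P)
  dem <- c(C = photosynthetic_demand_C, N = nutrient_demand_N,
           P = nutrient_demand_P)
  stopifnot(all(rel >= 0), all(dem >= 0))
  rec <- pmin(rel, dem)
  list(recycled = as.list(rec), net_external = as.list(rel - rec))
}

#' Acquired-phototrophy dynamics
#'
#' Non-constitutive mixoplankton gain photosynthetic competence from
#' ingested chloroplast material, saturating towards full capacity, and
#' lose it exponentially at the type's decay rate (fast for the generalist,
#' slow for the plastidic specialist).  The specialist additionally
#' photoacclimates: it can synthesise Chl on retained plastids up to the
#' Chl:C ceiling, which the generalist cannot.  Constitutive and
#' non-photosynthetic types are a no-op.
#'
#' @param state A [protist_state()].
#' @param ingested_Chl Ingestion rate of prey chloroplast material
#'   (ug atom C-equivalent L-1 d-1).
#' @param config A [make_config()].
#' @return List `dA` (d-1 rate of change of capacity) and `dChl`
#'   (ug atom C-equivalent L-1 d-1).
#' @export
acquired_phototrophy_update <- function(state, ingested_Chl, config) {
  mode <- config$acquired_phototrophy_mode
  if (mode == "none") return(list(dA = 0, dChl = 0))
  stopifnot(ingested_Chl >= 0)
  A <- state$acquired_capacity
  chl_cap <- config$ChlC_max * max(state$C, 0)
  gain <- if (chl_cap > 0) {
    config$acquired_gain_rate * ingested_Chl / chl_cap
  } else 0
  dA <- gain * (1 - A) - config$acquired_decay_rate * A
  # plastids are sequestered whole from the ingestate before digestion, so
  # chloroplast acquisition is not discounted by the assimilation efficiency
  headroom <- if (chl_cap > 0) max(1 - state$Chl / chl_cap, 0) else 0
  dChl <- ingested_Chl * headroom - config$acquired_decay_rate * state$Chl
  if (mode == "plastidic_specialist" && chl_cap > 0) {
    dChl <- dChl + config$chl_synth_rate * A * max(chl_cap - state$Chl, 0)
  }
  list(dA = dA, dChl = dChl)
}

#' Maintenance losses: respiration, allied regeneration and DOM leakage
#'
#' Basal respiration is biomass-C specific (a fixed fraction of `mu_max`)
#' and carries allied regeneration of ammonium and phosphate at the
#' current cell quota, maintaining cellular stoichiometric balance as
#' biomass C is respired.  DOC leakage is a fixed fraction of gross
#' fixation plus a share of the anabolate (metabolite-pool leak);
#' stoichiometric overflow of C when N or P limits growth, and the excess
#' regeneration that holds quotas at their maxima, are computed in
#' [protist_derivatives()] where the full flux balance is known (both are
#' zero during nutrient-replete growth).
#'
#' @param state A [protist_state()].
#' @param gross_photo Gross C fixation rate.
#' @param anabolate Named list `C`, `N`, `P` of anabolate rates (defaults 0).
#' @param config A [make_config()].
#' @return List `basal_respiration_C`, `DOC_leak`, `DON_leak`, `DOP_leak`,
#'   `regeneration_NH4`, `regeneration_PO4` (the respiration-allied share).
#' @export
maintenance_losses <- function(state, gross_photo, config,
                               anabolate = list(C = 0, N = 0, P = 0)) {
  C <- max(state$C, 0)
  basal <- config$basal_respiration * config$mu_max * C
  QN <- if (C > 0) state$N / C else 0
  QP <- if (C > 0) state$P / C else 0
  list(
    basal_respiration_C = basal,
    DOC_leak = config$DOC_leak_fraction * gross_photo +
      config$metabolite_leak * anabolate$C,
    DON_leak = config$metabolite_leak * anabolate$N,
    DOP_leak = config$metabolite_leak * anabolate$P,
    regeneration_NH4 = QN * basal,
    regeneration_PO4 = QP * basal
  )
}

# Boundary ramp: 0 well inside the quota range, 1 at (beyond) the boundary.
# Engages regeneration/overflow smoothly over the outer 5% of the range.
.ramp_hi <- function(Q, Qmax, span) pmin(pmax((Q - (Qmax - 0.05 * span)) /
                                                (0.05 * span), 0), 1)
.ramp_lo <- function(Q, Qmin, span) pmin(pmax(((Qmin + 0.05 * span) - Q) /
                                                (0.05 * span), 0), 1)

#' Assemble all physiological fluxes and state derivatives
#'
#' Combines photosynthesis, inorganic uptake, ingestion, digestion, SDA
#' recycling, acquired-phototrophy dynamics, maintenance losses,
#' stoichiometric overflow (excess C leaked as DOC when N or P limits
#' growth, and a growth cap at `mu_max`) and nutrient regeneration (NH4 and
#' PO4 released whenever quotas would exceed their maxima) into a single
#' flux vector, together with the time derivatives of the protist state,
#' dissolved pools and prey field.  Every element budget closes exactly:
#' d/dt (biomass + prey + dissolved organics + voided + inorganic) = 0 for
#' C, N and P, with the biological DIC change and the alkalinity forcing
#' (via [alkalinity_increment()]) accumulated for the downstream carbonate
#' chemistry.
#'
#' @param state A [protist_state()].
#' @param pools A [dissolved_pools()].
#' @param prey A [prey_field()].
#' @param config A [make_config()].
#' @param PFD Photon flux density, umol photons m-2 s-1.
#' @return List `fluxes` (named per-day rates for every arrow of the flux
#'   topology), `dstate`, `dpools`, `dprey` (named derivative vectors).
#' @export
protist_derivatives <- function(state, pools, prey, config, PFD) {
  ctrl <- control_factors(state, config)
  C <- max(state$C, 0)

  # --- acquisition fluxes -------------------------------------------------
  GP <- gross_photosynthesis(state, PFD, config)
  ing <- ingestion(state, prey, config)
  part <- digestion_partition(ing, config)
  anab <- part$anabolate
  void <- part$voided

  # inorganic appetite (saturation-free demand) and substrate-limited uptake
  vN <- config$vmax_N_mult * config$mu_max * config$NC_max * C
  vP <- config$vmax_P_mult * config$mu_max * config$PC_max * C
  demand_N <- if (config$can_use_NH4 || config$can_use_NO3) {
    vN * max(ctrl$uptake_controls[["NH4"]], ctrl$uptake_controls[["NO3"]])
  } else 0
  demand_P <- if (config$can_use_NH4 || config$can_use_NO3) {
    vP * ctrl$uptake_controls[["PO4"]]
  } else 0

  rec <- sda_recycle(part$sda_gross, GP, demand_N, demand_P)

  # internal recycling satisfies the appetite first; external uptake covers
  # only the remainder (scaling the substrate-limited rates down)
  up_pot <- inorganic_uptake(state, pools, config)
  fN <- if (demand_N > 0) max(1 - rec$recycled$N / demand_N, 0) else 1
  fP <- if (demand_P > 0) max(1 - rec$recycled$P / demand_P, 0) else 1
  up_NH4 <- up_pot$NH4 * fN
  up_NO3 <- up_pot$NO3 * fN
  up_PO4 <- up_pot$PO4 * fP

  ext_CO2 <- GP - rec$recycled$C

  # zooplankton recovery of leaked DOC (first order, biomass-scaled)
  reab <- config$doc_reabsorption_rate * max(pools$DOC, 0) * C / (C + 1)

  losses <- maintenance_losses(state, GP, config, anab)
  ml <- config$metabolite_leak

  # --- pre-balance biomass derivatives ------------------------------------
  # respiration-allied regeneration (at current quota) keeps catabolism
  # stoichiometrically balanced
  allied_NH4 <- losses$regeneration_NH4
  allied_PO4 <- losses$regeneration_PO4
  dC_pre <- (1 - ml) * anab$C + GP - losses$basal_respiration_C -
    config$DOC_leak_fraction * GP + reab
  dN_pre <- (1 - ml) * anab$N + rec$recycled$N + up_NH4 + up_NO3 - allied_NH4
  dP_pre <- (1 - ml) * anab$P + rec$recycled$P + up_PO4 - allied_PO4

  # --- growth cap, stoichiometric overflow, regeneration ------------------
  over_growth <- max(dC_pre - config$mu_max * C, 0)
  dC1 <- dC_pre - over_growth

  QN <- if (C > 0) state$N / C else config$NC_min
  QP <- if (C > 0) state$P / C else config$PC_min
  spanN <- config$NC_max - config$NC_min
  spanP <- config$PC_max - config$PC_min
  over_N <- .ramp_lo(QN, config$NC_min, spanN) *
    max(dC1 - dN_pre / config$NC_min, 0)
  over_P <- .ramp_lo(QP, config$PC_min, spanP) *
    max(dC1 - dP_pre / config$PC_min, 0)
  over_C <- max(over_N, over_P)
  dC <- dC1 - over_C

  excess_NH4 <- .ramp_hi(QN, config$NC_max, spanN) *
    max(dN_pre - config$NC_max * dC, 0)
  excess_PO4 <- .ramp_hi(QP, config$PC_max, spanP) *
    max(dP_pre - config$PC_max * dC, 0)
  regen_NH4 <- allied_NH4 + excess_NH4
  regen_PO4 <- allied_PO4 + excess_PO4
  dN <- dN_pre - excess_NH4
  dP <- dP_pre - excess_PO4

  doc_leak_total <- losses$DOC_leak + over_growth + over_C

  # --- acquired phototrophy / photoacclimation ----------------------------
  if (config$can_photosynthesize_constitutively) {
    dChl <- config$chl_synth_rate * (config$ChlC_max * C - state$Chl)
    dA <- 0
  } else {
    acq <- acquired_phototrophy_update(state, ing$Chl, config)
    dChl <- acq$dChl
    dA <- acq$dA
  }

  # --- downstream carbonate forcing ---------------------------------------
  dDIC <- losses$basal_respiration_C + rec$net_external$C - ext_CO2
  net_up_NH4 <- up_NH4 - regen_NH4 - rec$net_external$N
  net_up_PO4 <- up_PO4 - regen_PO4 - rec$net_external$P
  dTA <- alkalinity_increment(net_flux_NH4 = net_up_NH4,
                              net_flux_NO3 = up_NO3,
                              net_flux_PO4 = net_up_PO4)

  fluxes <- list(
    gross_photosynthesis_C = GP,
    CO2_external_uptake = ext_CO2,
    NH4_uptake = up_NH4, NO3_uptake = up_NO3, PO4_uptake = up_PO4,
    ingestion_C = ing$C, ingestion_N = ing$N, ingestion_P = ing$P,
    ingestion_Chl = ing$Chl,
    void_C = void$C, void_N = void$N, void_P = void$P,
    SDA_release_C = part$sda_gross$C, SDA_release_N = part$sda_gross$N,
    SDA_release_P = part$sda_gross$P,
    SDA_recycled_C = rec$recycled$C, SDA_recycled_N = rec$recycled$N,
    SDA_recycled_P = rec$recycled$P,
    SDA_net_external_C = rec$net_external$C,
    SDA_net_external_N = rec$net_external$N,
    SDA_net_external_P = rec$net_external$P,
    basal_respiration_C = losses$basal_respiration_C,
    DOC_leak = doc_leak_total, DON_leak = losses$DON_leak,
    DOP_leak = losses$DOP_leak,
    DOC_reabsorption = reab,
    regeneration_NH4 = regen_NH4, regeneration_PO4 = regen_PO4,
    net_growth_C = dC
  )

  dstate <- c(C = dC, N = dN, P = dP, Chl = dChl, acquired_capacity = dA)
  dprey <- if (prey$prey_C > 0) {
    c(prey_C = -ing$C, prey_N = -ing$N, prey_P = -ing$P,
      prey_Chl = -ing$Chl)
  } else c(prey_C = 0, prey_N = 0, prey_P = 0, prey_Chl = 0)
  dpools <- c(
    NH4 = -up_NH4 + regen_NH4 + rec$net_external$N,
    NO3 = -up_NO3,
    PO4 = -up_PO4 + regen_PO4 + rec$net_external$P,
    DOC = doc_leak_total - reab,
    DON = losses$DON_leak,
    DOP = losses$DOP_leak,
    VOC = void$C, VON = void$N, VOP = void$P,
    DIC_biological_delta = dDIC,
    TA_biological_delta = dTA
  )
  list(fluxes = fluxes, dstate = dstate, dprey = dprey, dpools = dpools)
}
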