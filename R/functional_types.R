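# Factory for the five protist functional-type configurations, plus the
# constitutive-mixoplankton (CM) priority variants.  The five defaults
# differ only in capability flags, trophic priority and acquired-phototrophy
# parameters; all shared physiological constants are identical so that
# cross-type comparisons isolate trophic strategy.

FUNCTIONAL_TYPES <- c("phytoplankton", "zooplankton", "GNCM", "pSNCM", "CM")
CM_VARIANTS <- c("equal", "photo_first", "phago_first")

# Shared physiological constants.  mu_max and ESD are the study conditions
# (a doubling per day at 15 degC in a motile 20 um cell); quota bounds
# bracket the Redfield composition (0.5x to 2x, the span typical of quota
# models of protists); AE and SDA sit inside the canonical ranges (20-40%
# voided, ~30% SDA) and jointly reproduce the 1.9x / 1.3x ingestion
# multiples of the balance-point analysis.
.shared_defaults <- function() {
  redfield_NC <- 16 / 106
  redfield_PC <- 1 / 106
  list(
    mu_max = 0.693,             # d-1, maximum growth rate
    ESD = 20,                   # um, equivalent spherical diameter
    AE = 0.75,                  # assimilation efficiency of ingested matter
    SDA = 0.30,                 # specific dynamic action fraction of retained
    priority = "equal",
    basal_respiration = 0.15,   # fraction of mu_max, biomass-C specific
    DOC_leak_fraction = 0.10,   # fraction of gross C fixation leaked as DOC
    metabolite_leak = 0.05,     # fraction of anabolate leaked as DOM
    NC_min = 0.5 * redfield_NC,
    NC_max = 2 * redfield_NC,
    PC_min = 0.5 * redfield_PC,
    PC_max = 2 * redfield_PC,
    ChlC_max = 0.06,            # C-equivalent Chl : biomass C ceiling
    half_sat_NH4 = 0.3,         # uM
    half_sat_NO3 = 0.5,         # uM
    half_sat_PO4 = 0.1,         # uM
    NH4_inhibition = 0.5,       # uM; NH4 level halving NO3 uptake
    grazing_half_sat = 50,      # uM prey C
    g_max_mult = 5,             # max specific ingestion, multiple of mu_max
    vmax_N_mult = 1.2,          # max N uptake = mult * mu_max * NC_max
    vmax_P_mult = 1.2,
    pmax_mult = 3,              # max gross fixation, multiple of mu_max
    K_PFD = 100,                # umol photons m-2 s-1, P-I saturation scale
    chl_synth_rate = 1,         # d-1, photoacclimation relaxation rate
    acquired_gain_rate = 6,     # scaling of capacity gain per ingested Chl
    control_shape = 2,          # Hill exponent of the de-repression sigmoid
    uptake_control_shape = 3,   # steeper satiation of inorganic transporters
    control_k = 0.5,            # half-saturation stress of the sigmoid
    priority_shift = 0.25,      # added to control_k of the deprioritised mode
    doc_reabsorption_rate = 0   # d-1; first-order DOC recovery (zooplankton)
  )
}

.type_specifics <- list(
  phytoplankton = list(
    can_photosynthesize_constitutively = TRUE,
    acquired_phototrophy_mode = "none",
    can_use_NO3 = TRUE, can_use_NH4 = TRUE, can_ingest = FALSE,
    acquired_decay_rate = 0
  ),
  zooplankton = list(
    can_photosynthesize_constitutively = FALSE,
    acquired_phototrophy_mode = "none",
    can_use_NO3 = FALSE, can_use_NH4 = FALSE, can_ingest = TRUE,
    acquired_decay_rate = 0,
    doc_reabsorption_rate = 0.1
  ),
  GNCM = list(
    can_photosynthesize_constitutively = FALSE,
    acquired_phototrophy_mode = "generalist",
    can_use_NO3 = FALSE, can_use_NH4 = TRUE, can_ingest = TRUE,
    acquired_decay_rate = 0.7
  ),
  pSNCM = list(
    can_photosynthesize_constitutively = FALSE,
    acquired_phototrophy_mode = "plastidic_specialist",
    can_use_NO3 = TRUE, can_use_NH4 = TRUE, can_ingest = TRUE,
    acquired_decay_rate = 0.1
  ),
  CM = list(
    can_photosynthesize_constitutively = TRUE,
    acquired_phototrophy_mode = "none",
    can_use_NO3 = TRUE, can_use_NH4 = TRUE, can_ingest = TRUE,
    acquired_decay_rate = 0
  )
)

#' Build a protist functional-type configuration
#'
#' Returns the full parameterisation of one of the five protist plankton
#' functional types: `phytoplankton` (phototrophy + NH4/NO3/PO4 use, no
#' ingestion), `zooplankton` (ingestion only), `GNCM` (generalist
#' non-constitutive mixoplankton: ingestion + rapidly decaying acquired
#' phototrophy + NH4 but not NO3), `pSNCM` (plastidic specialist:
#' ingestion + maintained/photoacclimated acquired phototrophy + NH4 and
#' NO3) and `CM` (constitutive mixoplankton: everything, innately).
#'
#' All types share the same physiological constants (`mu_max` = 0.693 d-1,
#' ESD = 20 um, quota bounds, AE, SDA, ...) and differ only in capability
#' flags, trophic priority and acquired-phototrophy parameters.
#'
#' @param name One of `"phytoplankton"`, `"zooplankton"`, `"GNCM"`,
#'   `"pSNCM"`, `"CM"`.
#' @param variant Trophic priority, CM only: `"equal"` (default; phototrophy
#'   and phagotrophy de-repressed at the same nutrient stress),
#'   `"photo_first"` (phagotrophy de-repressed only at stronger stress) or
#'   `"phago_first"` (the converse).
#' @param overrides Named list of parameter overrides; unknown keys error.
#'
#' @return A `protist_config` list.
#'
#' @examples
#' make_config("GNCM")$can_use_NO3          # FALSE
#' make_config("CM", variant = "phago_first")$priority
#' @export
make_config <- function(name, variant = "equal", overrides = list()) {
  if (length(name) != 1 || !name %in% FUNCTIONAL_TYPES) {
    stop("unknown functional type '", name, "'; valid names are: ",
         paste(FUNCTIONAL_TYPES, collapse = ", "))
  }
  if (length(variant) != 1 || !variant %in% CM_VARIANTS) {
    stop("unknown variant '", variant, "'; valid variants are: ",
         paste(CM_VARIANTS, collapse = ", "))
  }
  cfg <- .shared_defaults()
  cfg[names(.type_specifics[[name]])] <- .type_specifics[[name]]
  cfg$name <- name
  cfg$variant <- variant
  cfg$priority <- variant
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("overrides must be a named list")
    }
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown override key(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$AE > 0, cfg$AE <= 1, cfg$SDA >= 0, cfg$SDA < 1,
            cfg$NC_min < cfg$NC_max, cfg$PC_min < cfg$PC_max,
            cfg$mu_max > 0, cfg$ESD > 0)
  structure(cfg, class = "protist_config")
}

#' @export
print.protist_config <- function(x, ...) {
  caps <- c(if (x$can_photosynthesize_constitutively) "constitutive PS",
            if (x$acquired_phototrophy_mode != "none")
              paste0("acquired PS (", x$acquired_phototrophy_mode, ")"),
            if (x$can_ingest) "phagotrophy",
            if (x$can_use_NH4) "NH4", if (x$can_use_NO3) "NO3")
  cat("protist config:", x$name,
      if (x$name == "CM" && x$variant != "equal") paste0("[", x$variant, "]"),
      "\n  capabilities:", paste(caps, collapse = ", "),
      "\n  mu_max:", x$mu_max, "d-1  ESD:", x$ESD, "um  AE:", x$AE,
      " SDA:", x$SDA, "\n")
  invisible(x)
}
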