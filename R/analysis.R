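# Desk calculations and run summaries: the balance point between
# phagoheterotrophy and photoautotrophy, prey-capture intervals, the
# scenario preset catalogue and end-of-run summaries.

#' Ingestion multiple at the carbon balance point
#'
#' C-specific ingestion rate, expressed as a multiple of the C-specific
#' growth rate, required (i) by a purely phagotrophic consumer whose only C
#' source is assimilated post-SDA food (`pure_phagotroph`:
#' `1 / (AE * (1 - SDA))`), or (ii) by a mixoplankton at the point of zero
#' net DIC change, where gross photosynthetic fixation exactly offsets all
#' respiratory C release so growth C equals assimilated food C
#' (`mixoplankton_zero_net_DIC`: `1 / AE`).  With the default AE 0.75 and
#' SDA 0.30 these give 1.90 and 1.33: a mixoplankton needs much less
#' feeding than a zooplankton growing at the same rate.
#'
#' @param AE Assimilation efficiency, in `(0, 1]`.
#' @param SDA Specific-dynamic-action fraction of retained ingestate,
#'   in `[0, 1)`.
#' @param mode `"pure_phagotroph"` or `"mixoplankton_zero_net_DIC"`.
#' @return Ingestion rate as a multiple of the growth rate.
#'
#' @examples
#' balance_point(0.75, 0.30, "pure_phagotroph")          # 1.90
#' balance_point(0.75, 0.30, "mixoplankton_zero_net_DIC") # 1.33
#' @export
balance_point <- function(AE, SDA,
                          mode = c("pure_phagotroph",
                                   "mixoplankton_zero_net_DIC")) {
  mode <- match.arg(mode)
  if (!is.finite(AE) || AE <= 0 || AE > 1) {
    stop("AE must lie in (0, 1]; the balance point is undefined at AE = 0")
  }
  if (!is.finite(SDA) || SDA < 0 || SDA >= 1) {
    stop("SDA must lie in [0, 1)")
  }
  switch(mode,
         pure_phagotroph = 1 / (AE * (1 - SDA)),
         mixoplankton_zero_net_DIC = 1 / AE)
}

#' Phagotrophy : gross-fixation ratio at the zero-net-DIC balance point
#'
#' At the mixoplankton balance point the ingestion rate is `I = mu / AE`
#' and the gross fixation needed to offset total respiration is
#' `F = SDA * (AE * I) + basal * mu`; the ratio `I / F` is the carbon
#' brought in by phagotrophy per unit of gross C fixation.  With AE 0.75,
#' SDA 0.30 and basal respiration 0.15 mu the ratio is ~3 : 1.
#'
#' @param AE,SDA As in [balance_point()].
#' @param basal_respiration_multiple Basal respiration as a fraction of the
#'   growth rate (>= 0).
#' @return Dimensionless ratio of ingested C to gross fixed C.
#'
#' @examples
#' phago_to_fixation_ratio(0.75, 0.30, 0.15)  # ~2.96
#' @export
phago_to_fixation_ratio <- function(AE, SDA, basal_respiration_multiple) {
  I <- balance_point(AE, SDA, "mixoplankton_zero_net_DIC")
  stopifnot(basal_respiration_multiple >= 0)
  F_fix <- SDA * (AE * I) + basal_respiration_multiple
  if (F_fix <= 0) {
    stop("gross fixation is zero at this balance point; ratio undefined")
  }
  I / F_fix
}

#' Prey-capture interval at a stated ingestion rate
#'
#' Converts a C-specific ingestion rate into prey items captured per day,
#' assuming predator and prey share the same C-biovolume density so the
#' C of one prey item is `(prey_ESD / pred_ESD)^3` of the predator's, and
#' returns the mean time between captures.  By default the ingestion rate
#' is a multiple of the growth rate `mu`; set `ingestion_is_absolute` to
#' read it as an absolute specific rate (d-1) instead.
#'
#' @param pred_ESD,prey_ESD Cell diameters, um (`pred_ESD > prey_ESD`).
#' @param ingestion_multiple Ingestion as a multiple of `mu` (or an
#'   absolute d-1 rate when `ingestion_is_absolute`).
#' @param mu Growth rate, d-1.
#' @param ingestion_is_absolute Interpret `ingestion_multiple` as d-1.
#' @return Minutes per prey item.
#'
#' @examples
#' prey_capture_interval(10, 1, 4 / 3, 0.693)  # ~1.6 min
#' prey_capture_interval(20, 5, 4 / 3, 0.693)  # ~25 min
#' @export
prey_capture_interval <- function(pred_ESD, prey_ESD, ingestion_multiple,
                                  mu, ingestion_is_absolute = FALSE) {
  stopifnot(pred_ESD > 0, prey_ESD > 0, pred_ESD > prey_ESD,
            ingestion_multiple > 0, mu > 0)
  rate <- if (ingestion_is_absolute) ingestion_multiple
          else ingestion_multiple * mu
  prey_per_day <- rate * (pred_ESD / prey_ESD)^3
  1440 / prey_per_day
}

#' Scenario preset catalogue
#'
#' The standard scenario sets: `"fig3"`, the five functional types at the
#' default conditions; `"fig4"`, constitutive mixoplankton and
#' phytoplankton at 20 and 250 um ESD with the proximal [H+] calculation
#' enabled; `"fig5"`, the five constitutive-mixoplankton variants
#' (phototrophy-priority, phagotrophy-priority, low light at PFD 50,
#' doubled prey, and doubled poor-quality prey).  Every preset carries both
#' the 300- and 600-uatm pCO2 variants.
#'
#' @param catalogue_id One of `"fig3"`, `"fig4"`, `"fig5"`.
#' @param ... Passed on to [make_scenario()] (e.g. `duration`, `dt_out`).
#' @return Named list of [make_scenario()] objects.
#' @export
scenario_presets <- function(catalogue_id, ...) {
  valid <- c("fig3", "fig4", "fig5")
  if (length(catalogue_id) != 1 || !catalogue_id %in% valid) {
    stop("unknown catalogue id '", catalogue_id, "'; available: ",
         paste(valid, collapse = ", "))
  }
  if (catalogue_id == "fig3") {
    out <- lapply(FUNCTIONAL_TYPES, function(nm) {
      make_scenario(config = make_config(nm), label = nm, ...)
    })
    names(out) <- FUNCTIONAL_TYPES
    return(out)
  }
  if (catalogue_id == "fig4") {
    combos <- expand.grid(type = c("CM", "phytoplankton"),
                          ESD = c(20, 250), stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(combos)), function(i) {
      make_scenario(
        config = make_config(combos$type[i],
                             overrides = list(ESD = combos$ESD[i])),
        proximal = TRUE,
        label = paste0(combos$type[i], "_ESD", combos$ESD[i]), ...)
    })
    names(out) <- paste0(combos$type, "_ESD", combos$ESD)
    return(out)
  }
  list(
    CM_photo_first = make_scenario(
      config = make_config("CM", variant = "photo_first"),
      label = "CM photo>phago", ...),
    CM_phago_first = make_scenario(
      config = make_config("CM", variant = "phago_first"),
      label = "CM phago>photo", ...),
    CM_low_PFD = make_scenario(
      config = make_config("CM"), PFD_light = 50, label = "CM low PFD", ...),
    CM_prey_quantity = make_scenario(
      config = make_config("CM"), prey = build_default_prey(40),
      label = "CM prey quantity", ...),
    CM_prey_quantity_quality = make_scenario(
      config = make_config("CM"),
      prey = build_default_prey(20, quality = 0.5),
      label = "CM prey quantity & quality", ...)
  )
}

#' End-of-run summary
#'
#' Deterministic aggregation of a simulation result: initial/final DIC, TA,
#' pH and [H+] per pCO2 variant, the DIC change, final biomass and
#' cumulative dissolved/voided organics.
#'
#' @param result A [run_scenario()] result.
#' @return A data.frame with one row per pCO2 variant.
#' @export
summarize_run <- function(result) {
  if (!inherits(result, "simulation_result") || is.null(result$chem) ||
      length(result$chem) == 0 || nrow(result$states) == 0) {
    stop("summarize_run needs a complete simulation result")
  }
  s <- result$states
  last <- nrow(s)
  rows <- lapply(names(result$chem), function(p) {
    df <- result$chem[[p]]
    data.frame(
      scenario = result$scenario$label, pCO2 = as.numeric(p),
      DIC_initial = df$DIC[1], DIC_final = df$DIC[nrow(df)],
      delta_DIC = df$DIC[nrow(df)] - df$DIC[1],
      TA_initial = df$TA[1], TA_final = df$TA[nrow(df)],
      H_initial = df$H[1], H_final = df$H[nrow(df)],
      pH_initial = df$pH[1], pH_final = df$pH[nrow(df)],
      pH_min = min(df$pH), pH_max = max(df$pH),
      biomass_C = s$C[last], biomass_N = s$N[last], biomass_P = s$P[last],
      DOC = s$DOC[last], VOC = s$VOC[last], VON = s$VON[last],
      VOP = s$VOP[last])
  })
  do.call(rbind, rows)
}
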