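# Closed-system batch-culture integration.  The physiology ODEs are
# integrated once; the carbonate chemistry is evaluated strictly
# downstream, per pCO2 variant, by adding the cumulative biological DIC and
# TA changes to the initial air-sea-equilibrated state and re-solving the
# speciation at every output step.  The square-wave light forcing is
# handled by stopping and restarting the integrator at every light/dark
# boundary so the discontinuity is never smeared across a step.

.state_names <- c("C", "N", "P", "Chl", "acquired_capacity",
                  "prey_C", "prey_N", "prey_P", "prey_Chl",
                  "NH4", "NO3", "PO4", "DOC", "DON", "DOP",
                  "VOC", "VON", "VOP",
                  "DIC_biological_delta", "TA_biological_delta")

.unpack <- function(y, config) {
  C <- max(y[["C"]], 0)
  # clamp quotas (and capacity) for rate evaluation: the balance terms keep
  # the true state inside the bounds, but the solver may probe beyond them
  N <- if (C > 0) min(max(y[["N"]], config$NC_min * C), config$NC_max * C)
       else y[["N"]]
  P <- if (C > 0) min(max(y[["P"]], config$PC_min * C), config$PC_max * C)
       else y[["P"]]
  A <- min(max(y[["acquired_capacity"]], 0), 1)
  state <- structure(list(C = C, N = N, P = P, Chl = max(y[["Chl"]], 0),
                          acquired_capacity = A), class = "protist_state")
  prey <- structure(list(prey_C = max(y[["prey_C"]], 0),
                         prey_N = max(y[["prey_N"]], 0),
                         prey_P = max(y[["prey_P"]], 0),
                         prey_Chl = max(y[["prey_Chl"]], 0),
                         prey_ESD = 5), class = "prey_field")
  pools <- structure(list(NH4 = max(y[["NH4"]], 0), NO3 = max(y[["NO3"]], 0),
                          PO4 = max(y[["PO4"]], 0), DOC = max(y[["DOC"]], 0),
                          DON = y[["DON"]], DOP = y[["DOP"]],
                          VOC = y[["VOC"]], VON = y[["VON"]],
                          VOP = y[["VOP"]],
                          DIC_biological_delta = y[["DIC_biological_delta"]]),
                     class = "dissolved_pools")
  list(state = state, prey = prey, pools = pools)
}

.derivs_at <- function(t, y, scenario) {
  s <- .unpack(y, scenario$config)
  protist_derivatives(s$state, s$pools, s$prey, scenario$config,
                      irradiance(t, scenario))
}

# parms = list(scenario, PFD): the light level is constant within an
# integration segment (segments never straddle a light/dark boundary)
.ode_fn <- function(t, y, parms) {
  s <- .unpack(y, parms$scenario$config)
  d <- protist_derivatives(s$state, s$pools, s$prey, parms$scenario$config,
                           parms$PFD)
  list(c(d$dstate, d$dprey, d$dpools))
}

.initial_y <- function(scenario) {
  cfg <- scenario$config
  C0 <- scenario$initial_biomass_C
  chl0 <- if (cfg$can_photosynthesize_constitutively) {
    0.5 * cfg$ChlC_max * C0
  } else 0
  y <- c(C = C0, N = C0 * 16 / 106, P = C0 / 106, Chl = chl0,
         acquired_capacity = if (cfg$can_photosynthesize_constitutively) 1
                             else 0,
         prey_C = scenario$prey$prey_C, prey_N = scenario$prey$prey_N,
         prey_P = scenario$prey$prey_P, prey_Chl = scenario$prey$prey_Chl,
         NH4 = scenario$NH4, NO3 = scenario$NO3, PO4 = scenario$PO4,
         DOC = 0, DON = 0, DOP = 0, VOC = 0, VON = 0, VOP = 0,
         DIC_biological_delta = 0, TA_biological_delta = 0)
  names(y) <- .state_names
  y
}

#' Run a closed batch-culture scenario
#'
#' Integrates the physiology once (the biology is independent of pCO2 by
#' construction: there is no feedback from carbonate chemistry to
#' physiology), then, for each requested pCO2 variant, initialises DIC by
#' atmospheric equilibration at the scenario alkalinity and applies the
#' cumulative biological DIC and TA changes, re-solving the speciation at
#' every output step.  Deterministic: identical scenarios give identical
#' results.
#'
#' @param scenario A [make_scenario()].
#' @return A `simulation_result`: list with `time`, `states` (data.frame of
#'   all biological pools over time), `fluxes` (data.frame of the full flux
#'   vector over time), `chem` (per-variant data.frames with `DIC`, `TA`,
#'   `H`, `pH`, plus `H_proximal`/`pH_proximal` when the scenario requests
#'   the near-cell calculation), `initial_chem` (per-variant equilibrium
#'   states) and the `scenario` echo.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  y <- .initial_y(scenario)
  out_times <- seq(0, scenario$duration, by = scenario$dt_out)

  # light/dark boundaries partition the run into smooth segments
  days <- seq(0, ceiling(scenario$duration))
  breaks <- sort(unique(pmin(c(days, days + scenario$light_fraction),
                             scenario$duration)))
  breaks <- breaks[breaks >= 0 & breaks <= scenario$duration]

  rows <- matrix(NA_real_, nrow = length(out_times),
                 ncol = length(.state_names),
                 dimnames = list(NULL, .state_names))
  rows[1, ] <- y
  filled <- 1
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]
    t1 <- breaks[i + 1]
    seg_out <- out_times[out_times > t0 + 1e-12 & out_times <= t1 + 1e-12]
    times <- sort(unique(c(t0, seg_out, t1)))
    # forcing evaluated mid-segment: constant within a light or dark phase
    parms <- list(scenario = scenario,
                  PFD = irradiance((t0 + t1) / 2, scenario))
    sol <- try(deSolve::lsoda(y, times, .ode_fn, parms = parms,
                              rtol = scenario$rtol, atol = scenario$atol,
                              maxsteps = 100000), silent = TRUE)
    if (inherits(sol, "try-error") ||
        abs(sol[nrow(sol), "time"] - t1) > 1e-8) {
      stop("integrator failure in segment [", t0, ", ", t1, "] of scenario '",
           scenario$label, "'; last valid state at t = ",
           if (inherits(sol, "try-error")) t0 else sol[nrow(sol), "time"])
    }
    keep <- match(round(seg_out, 9), round(sol[, "time"], 9))
    if (length(seg_out)) {
      rows[filled + seq_along(seg_out), ] <-
        as.matrix(sol[keep, .state_names, drop = FALSE])
      filled <- filled + length(seg_out)
    }
    y <- sol[nrow(sol), .state_names]
  }
  states <- as.data.frame(rows[seq_len(filled), , drop = FALSE])
  time <- out_times[seq_len(filled)]

  # negative-pool guard (beyond integrator tolerance)
  conserved <- c("C", "N", "P", "prey_C", "prey_N", "prey_P",
                 "NH4", "NO3", "PO4", "DOC", "DON", "DOP",
                 "VOC", "VON", "VOP")
  worst <- min(as.matrix(states[conserved]))
  if (worst < -1e-6 * max(abs(.initial_y(scenario)))) {
    stop("negative-pool excursion beyond tolerance (min = ", worst, ")")
  }

  # flux diagnostics at output resolution
  flux_list <- lapply(seq_along(time), function(i) {
    unlist(.derivs_at(time[i], unlist(states[i, ]), scenario)$fluxes)
  })
  fluxes <- as.data.frame(do.call(rbind, flux_list))

  # downstream carbonate chemistry, per pCO2 variant
  k <- equilibrium_constants(scenario$temperature, scenario$salinity)
  chem <- list()
  initial_chem <- list()
  for (p in scenario$pCO2_init) {
    eq <- equilibrate_with_atmosphere(p, scenario$TA_init, k)
    DIC <- eq$DIC + states$DIC_biological_delta
    TA <- scenario$TA_init + states$TA_biological_delta
    sp <- lapply(seq_along(time),
                 function(i) solve_speciation(DIC[i], TA[i], k))
    df <- data.frame(time = time, DIC = DIC, TA = TA,
                     H = vapply(sp, `[[`, numeric(1), "H"),
                     pH = vapply(sp, `[[`, numeric(1), "pH"))
    if (isTRUE(scenario$proximal)) {
      prox <- .proximal_series(states, fluxes, df, scenario, k)
      df$H_proximal <- prox$H
      df$pH_proximal <- prox$pH
    }
    chem[[as.character(p)]] <- df
    initial_chem[[as.character(p)]] <- eq
  }

  structure(list(time = time, states = states, fluxes = fluxes,
                 chem = chem, initial_chem = initial_chem,
                 scenario = scenario),
            class = "simulation_result")
}

.proximal_series <- function(states, fluxes, chem_df, scenario, k) {
  cfg <- scenario$config
  n <- nrow(states)
  H <- numeric(n)
  pH <- numeric(n)
  for (i in seq_len(n)) {
    vol <- list(
      DIC = fluxes$CO2_external_uptake[i] - fluxes$basal_respiration_C[i] -
        fluxes$SDA_net_external_C[i],
      NH4 = fluxes$NH4_uptake[i] - fluxes$regeneration_NH4[i] -
        fluxes$SDA_net_external_N[i],
      NO3 = fluxes$NO3_uptake[i],
      PO4 = fluxes$PO4_uptake[i] - fluxes$regeneration_PO4[i] -
        fluxes$SDA_net_external_P[i]
    )
    pp <- proximal_params(ESD = cfg$ESD,
                          fluxes_per_cell = per_cell_fluxes(
                            vol, states$C[i], cfg$ESD),
                          Sh = scenario$Sh)
    bulk <- structure(list(DIC = chem_df$DIC[i], TA = chem_df$TA[i]),
                      class = "carbonate_state")
    st <- proximal_H(bulk, pp, k)
    H[i] <- st$H
    pH[i] <- st$pH
  }
  list(H = H, pH = pH)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation result:", x$scenario$label, "-", length(x$time),
      "output steps over", max(x$time), "d;",
      "pCO2 variants:", paste(names(x$chem), collapse = ", "), "\n")
  for (p in names(x$chem)) {
    df <- x$chem[[p]]
    cat(sprintf("  %s uatm: pH %.3f -> %.3f, dDIC %+.1f umol/kg\n", p,
                df$pH[1], df$pH[nrow(df)],
                df$DIC[nrow(df)] - df$DIC[1]))
  }
  invisible(x)
}

#' Element mass balance of a run
#'
#' The batch system is closed: the sum of biomass, prey, dissolved organic,
#' voided and inorganic pools must be constant for each of C, N and P
#' (total C includes the biological DIC change).
#'
#' @param result A [run_scenario()] result (a truncated run is checked on
#'   its available prefix).
#' @return Named numeric: maximum over time of the relative deviation of
#'   each element total from its initial value.
#' @export
mass_balance <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  s <- result$states
  if (is.null(s) || nrow(s) == 0) stop("empty simulation result")
  totC <- s$C + s$prey_C + s$DOC + s$VOC + s$DIC_biological_delta
  totN <- s$N + s$prey_N + s$NH4 + s$NO3 + s$DON + s$VON
  totP <- s$P + s$prey_P + s$PO4 + s$DOP + s$VOP
  c(C = max(abs(totC - totC[1])) / totC[1],
    N = max(abs(totN - totN[1])) / totN[1],
    P = max(abs(totP - totP[1])) / totP[1])
}
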