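# Helper: a valid state at given normalized quota positions (sN, sP in [0,1])
state_at <- function(cfg, sN = 0.5, sP = 0.5, C = 10, chl_frac = 1,
                     A = NULL) {
  QN <- cfg$NC_min + sN * (cfg$NC_max - cfg$NC_min)
  QP <- cfg$PC_min + sP * (cfg$PC_max - cfg$PC_min)
  protist_state(C = C, N = QN * C, P = QP * C,
                Chl = chl_frac * cfg$ChlC_max * C,
                acquired_capacity = A, config = cfg)
}

test_that("acquisition controls are de-repressed by nutrient stress and obey priority", {
  cfg <- make_config("CM")
  # fully replete: phagotrophy and transporters repressed
  replete <- control_factors(state_at(cfg, 1, 1), cfg)
  expect_lte(replete$phago_control, 0.05)
  expect_true(all(replete$uptake_controls <= 0.05))
  # fully stressed: everything de-repressed
  starved <- control_factors(state_at(cfg, 0, 0), cfg)
  expect_equal(starved$photo_control, 1)
  expect_equal(starved$phago_control, 1)
  expect_equal(unname(starved$uptake_controls), c(1, 1, 1))
  # equal priority: identical controls at every quota
  for (s in seq(0.05, 0.95, by = 0.15)) {
    ctrl <- control_factors(state_at(cfg, s, s), cfg)
    expect_equal(ctrl$photo_control, ctrl$phago_control)
  }
  # monotone in stress
  photo <- vapply(seq(0, 1, by = 0.1), function(s)
    control_factors(state_at(cfg, s, s), cfg)$photo_control, numeric(1))
  expect_true(all(diff(photo) < 0))
  # priority shifts the de-repression threshold of the other mechanism
  pf <- make_config("CM", variant = "photo_first")
  gf <- make_config("CM", variant = "phago_first")
  mid_pf <- control_factors(state_at(pf, 0.5, 0.5), pf)
  mid_gf <- control_factors(state_at(gf, 0.5, 0.5), gf)
  expect_gt(mid_pf$photo_control, mid_pf$phago_control)
  expect_gt(mid_gf$phago_control, mid_gf$photo_control)
  # invalid quota is an invariant violation
  bad <- structure(list(C = 1, N = 2, P = 0.01, Chl = 0,
                        acquired_capacity = 1), class = "protist_state")
  expect_error(control_factors(bad, cfg), "quota")
})

test_that("photosynthesis saturates with light and needs photosystems", {
  cfg <- make_config("CM")
  st <- state_at(cfg, 0.5, 0.5)
  expect_identical(gross_photosynthesis(st, 0, cfg), 0)
  # PFD 500 saturates: >= 95% of the light-saturated maximum
  p500 <- gross_photosynthesis(st, 500, cfg)
  pmax <- gross_photosynthesis(st, 1e5, cfg)
  expect_gte(p500, 0.95 * pmax)
  expect_lt(gross_photosynthesis(st, 50, cfg), 0.5 * pmax)
  # no photosystems, no fixation
  no_chl <- state_at(cfg, 0.5, 0.5, chl_frac = 0)
  expect_identical(gross_photosynthesis(no_chl, 500, cfg), 0)
  gncm <- make_config("GNCM")
  dark_plastids <- state_at(gncm, 0.5, 0.5, A = 0)
  expect_identical(gross_photosynthesis(dark_plastids, 500, gncm), 0)
  zoo <- make_config("zooplankton")
  expect_identical(gross_photosynthesis(state_at(zoo, 0.5, 0.5), 500, zoo), 0)
})

test_that("inorganic uptake respects transporter capabilities and substrate", {
  pools <- dissolved_pools(NH4 = 0, NO3 = 10, PO4 = 1.25)
  gncm <- make_config("GNCM")
  up <- inorganic_uptake(state_at(gncm, 0.3, 0.3), pools, gncm)
  expect_identical(up$NO3, 0)        # GNCM cannot use nitrate
  expect_identical(up$NH4, 0)        # none present
  expect_gt(up$PO4, 0)
  zoo <- make_config("zooplankton")
  up_zoo <- inorganic_uptake(state_at(zoo, 0.3, 0.3),
                             dissolved_pools(10, 10, 1.25), zoo)
  expect_identical(unlist(up_zoo), c(NH4 = 0, NO3 = 0, PO4 = 0))
  cm <- make_config("CM")
  up0 <- inorganic_uptake(state_at(cm, 0.3, 0.3),
                          dissolved_pools(0, 0, 0), cm)
  expect_identical(unlist(up0), c(NH4 = 0, NO3 = 0, PO4 = 0))
  # ammonium represses nitrate uptake
  st <- state_at(cm, 0.3, 0.3)
  no3_without <- inorganic_uptake(st, dissolved_pools(0, 10, 1), cm)$NO3
  no3_with <- inorganic_uptake(st, dissolved_pools(5, 10, 1), cm)$NO3
  expect_lt(no3_with, 0.2 * no3_without)
})

test_that("ingestion follows a type II response scaled by encounter with size", {
  prey <- build_default_prey()
  cm <- make_config("CM")
  st <- state_at(cm, 0.4, 0.4)
  ing <- ingestion(st, prey, cm)
  expect_gt(ing$C, 0)
  # prey stoichiometric proportion
  expect_equal(ing$N / ing$C, prey$prey_N / prey$prey_C)
  expect_equal(ing$P / ing$C, prey$prey_P / prey$prey_C)
  expect_equal(ing$Chl / ing$C, prey$prey_Chl / prey$prey_C)
  # saturating in prey C
  rich <- prey_field(1e4, 1e4 * 16 / 106, 1e4 / 106)
  expect_lt(ingestion(st, rich, cm)$C / ingestion(st, prey, cm)$C,
            1e4 / prey$prey_C)
  # no prey / non-phagotroph
  expect_identical(ingestion(st, prey_field(0, 0, 0), cm)$C, 0)
  phyto <- make_config("phytoplankton")
  expect_identical(ingestion(state_at(phyto, 0.4, 0.4), prey, phyto)$C, 0)
  # larger predator, same biomass-specific parameters: more encounter
  big <- make_config("CM", overrides = list(ESD = 250))
  st_big <- state_at(big, 0.4, 0.4)
  expect_gt(ingestion(st_big, prey, big)$C, ingestion(st, prey, cm)$C)
})

test_that("digestion partitions ingestate exactly into voiding, SDA and anabolate", {
  cfg <- make_config("zooplankton")
  redfield <- list(C = 1, N = 16 / 106, P = 1 / 106)
  part <- digestion_partition(redfield, cfg)
  expect_equal(part$voided$C, 0.25)
  expect_equal(part$sda_gross$C, 0.225)
  expect_equal(part$anabolate$C, 0.525)
  lossless <- make_config("zooplankton",
                          overrides = list(AE = 1, SDA = 0))
  part1 <- digestion_partition(redfield, lossless)
  expect_equal(part1$anabolate$C, 1)
  expect_equal(part1$voided$C + part1$sda_gross$C, 0)
  # stoichiometric ecology: poor-quality (C-rich) food voids more carbon
  poor <- digestion_partition(list(C = 2, N = 16 / 106, P = 1 / 106), cfg)
  expect_gt(poor$voided$C / 2, part$voided$C)
  expect_equal(poor$voided$N, part$voided$N)
  # conservation property over random inputs and parameters
  set.seed(42)
  for (i in 1:25) {
    cfg_i <- make_config("CM", overrides = list(AE = runif(1, 0.2, 1),
                                                SDA = runif(1, 0, 0.9)))
    ing <- list(C = runif(1, 0, 10), N = runif(1, 0, 2), P = runif(1, 0, 0.2))
    p <- digestion_partition(ing, cfg_i)
    for (el in c("C", "N", "P")) {
      expect_equal(p$voided[[el]] + p$sda_gross[[el]] + p$anabolate[[el]],
                   ing[[el]], tolerance = 1e-12)
    }
  }
})

test_that("SDA releases are recycled up to concurrent demand, the rest leaves the cell", {
  rel <- list(C = 0.3, N = 0.05, P = 0.003)
  # zooplankton: no photosynthetic or inorganic demand, everything external
  zoo_out <- sda_recycle(rel, 0, 0, 0)
  expect_equal(zoo_out$net_external, rel)
  expect_equal(unlist(zoo_out$recycled), c(C = 0, N = 0, P = 0))
  # illuminated mixoplankton with demand >= release: nothing escapes
  mix_out <- sda_recycle(rel, 1, 0.2, 0.01)
  expect_equal(unlist(mix_out$net_external), c(C = 0, N = 0, P = 0))
  expect_equal(mix_out$recycled, rel)
  # no release, nothing anywhere
  none <- sda_recycle(list(C = 0, N = 0, P = 0), 1, 1, 1)
  expect_equal(unlist(none$recycled) + unlist(none$net_external),
               c(C = 0, N = 0, P = 0))
  # partial recycling is element-wise min
  part <- sda_recycle(rel, 0.1, 0.02, 1)
  expect_equal(part$recycled$C, 0.1)
  expect_equal(part$net_external$N, 0.03)
  expect_equal(part$net_external$P, 0)
})

test_that("acquired phototrophy is gained from ingested plastids and decays by type", {
  gncm <- make_config("GNCM")
  psncm <- make_config("pSNCM")
  cm <- make_config("CM")
  st <- state_at(gncm, 0.5, 0.5, chl_frac = 0.5, A = 0.8)
  # constitutive types bypass acquisition
  expect_identical(acquired_phototrophy_update(state_at(cm, 0.5, 0.5),
                                               1, cm),
                   list(dA = 0, dChl = 0))
  # no ingestion: generalist capacity decays fast, photosynthesis fades
  dec <- acquired_phototrophy_update(st, 0, gncm)
  expect_equal(dec$dA, -gncm$acquired_decay_rate * 0.8)
  expect_lt(dec$dChl, 0)
  # ingestion builds capacity, saturating towards 1
  grow <- acquired_phototrophy_update(st, 1, gncm)
  expect_gt(grow$dA, dec$dA)
  full <- state_at(gncm, 0.5, 0.5, chl_frac = 1, A = 1)
  expect_lte(acquired_phototrophy_update(full, 100, gncm)$dA, 0)
  # specialist with no ingestion still photoacclimates on retained plastids
  st_s <- state_at(psncm, 0.5, 0.5, chl_frac = 0.5, A = 0.8)
  spec <- acquired_phototrophy_update(st_s, 0, psncm)
  expect_gt(spec$dChl, 0)
})

test_that("maintenance losses scale with biomass and fixation", {
  cfg <- make_config("phytoplankton")
  empty <- structure(list(C = 0, N = 0, P = 0, Chl = 0,
                          acquired_capacity = 1), class = "protist_state")
  l0 <- maintenance_losses(empty, 0, cfg)
  expect_true(all(unlist(l0) == 0))
  st <- state_at(cfg, 0.5, 0.5)
  l <- maintenance_losses(st, 2, cfg)
  expect_equal(l$basal_respiration_C,
               cfg$basal_respiration * cfg$mu_max * st$C)
  expect_equal(l$DOC_leak, cfg$DOC_leak_fraction * 2)
  # respiration-allied regeneration at the current quota
  expect_equal(l$regeneration_NH4, (st$N / st$C) * l$basal_respiration_C)
  expect_equal(l$regeneration_PO4, (st$P / st$C) * l$basal_respiration_C)
})

test_that("dark metabolism releases CO2 and replete growth has no excess regeneration", {
  cfg <- make_config("phytoplankton")
  pools <- dissolved_pools()
  prey <- prey_field(0, 0, 0)
  st <- state_at(cfg, 0.5, 0.5)
  dark <- protist_derivatives(st, pools, prey, cfg, 0)
  expect_gt(dark$dpools[["DIC_biological_delta"]], 0)
  # replete, light-saturated growth: only the respiration-allied share is
  # regenerated (no quota-boundary excess)
  light <- protist_derivatives(st, pools, prey, cfg, 500)
  expect_equal(light$fluxes$regeneration_NH4,
               (st$N / st$C) * light$fluxes$basal_respiration_C)
  expect_gt(light$fluxes$net_growth_C, 0)
  # pure photosynthetic DIC removal with no nutrient fluxes leaves TA alone
  cfg0 <- make_config("phytoplankton",
                      overrides = list(basal_respiration = 0))
  d0 <- protist_derivatives(st, dissolved_pools(0, 0, 0), prey, cfg0, 500)
  expect_lt(d0$dpools[["DIC_biological_delta"]], 0)
  expect_identical(d0$dpools[["TA_biological_delta"]], 0)
})

test_that("every element budget closes for random valid states", {
  set.seed(7)
  for (i in 1:40) {
    nm <- sample(FUNCTIONAL_TYPES, 1)
    cfg <- make_config(nm)
    st <- state_at(cfg, runif(1), runif(1), C = runif(1, 0.01, 50),
                   chl_frac = runif(1),
                   A = if (cfg$acquired_phototrophy_mode != "none") runif(1)
                       else NULL)
    pools <- dissolved_pools(NH4 = runif(1, 0, 10), NO3 = runif(1, 0, 10),
                             PO4 = runif(1, 0, 2), DOC = runif(1, 0, 20))
    prey <- if (runif(1) < 0.8) build_default_prey(runif(1, 1, 40))
            else prey_field(0, 0, 0)
    d <- protist_derivatives(st, pools, prey, cfg, sample(c(0, 50, 500), 1))
    dC <- d$dstate[["C"]] + d$dprey[["prey_C"]] + d$dpools[["DOC"]] +
      d$dpools[["VOC"]] + d$dpools[["DIC_biological_delta"]]
    dN <- d$dstate[["N"]] + d$dprey[["prey_N"]] + d$dpools[["NH4"]] +
      d$dpools[["NO3"]] + d$dpools[["DON"]] + d$dpools[["VON"]]
    dP <- d$dstate[["P"]] + d$dprey[["prey_P"]] + d$dpools[["PO4"]] +
      d$dpools[["DOP"]] + d$dpools[["VOP"]]
    scale <- max(abs(unlist(d$fluxes)), 1e-12)
    expect_lt(abs(dC) / scale, 1e-10)
    expect_lt(abs(dN) / scale, 1e-10)
    expect_lt(abs(dP) / scale, 1e-10)
    # the flux-vector conservation identity (carbon arrows)
    f <- d$fluxes
    lhs <- f$ingestion_C + f$CO2_external_uptake - f$void_C -
      f$SDA_net_external_C - f$basal_respiration_C - f$DOC_leak +
      f$DOC_reabsorption
    expect_lt(abs(lhs - f$net_growth_C) / scale, 1e-10)
  }
})

test_that("derivatives never push quotas outside their bounds", {
  set.seed(11)
  for (i in 1:40) {
    nm <- sample(FUNCTIONAL_TYPES, 1)
    cfg <- make_config(nm)
    corner <- sample(list(c(0, runif(1)), c(1, runif(1)),
                          c(runif(1), 0), c(runif(1), 1)), 1)[[1]]
    st <- state_at(cfg, corner[1], corner[2], C = runif(1, 0.1, 30),
                   chl_frac = runif(1),
                   A = if (cfg$acquired_phototrophy_mode != "none") runif(1)
                       else NULL)
    pools <- dissolved_pools(NH4 = runif(1, 0, 10), NO3 = runif(1, 0, 10),
                             PO4 = runif(1, 0, 2))
    prey <- build_default_prey(runif(1, 1, 40))
    d <- protist_derivatives(st, pools, prey, cfg, sample(c(0, 500), 1))
    QN <- st$N / st$C
    QP <- st$P / st$C
    dQN <- (d$dstate[["N"]] - QN * d$dstate[["C"]]) / st$C
    dQP <- (d$dstate[["P"]] - QP * d$dstate[["C"]]) / st$C
    tol <- 1e-10
    if (corner[1] == 0) expect_gte(dQN, -tol)
    if (corner[1] == 1) expect_lte(dQN, tol)
    if (corner[2] == 0) expect_gte(dQP, -tol)
    if (corner[2] == 1) expect_lte(dQP, tol)
  }
})

test_that("non-phagotrophs are unaffected by prey and recycling caps external CO2 demand", {
  cfg <- make_config("phytoplankton")
  st <- state_at(cfg, 0.4, 0.4)
  pools <- dissolved_pools()
  with_prey <- protist_derivatives(st, pools, build_default_prey(), cfg, 500)
  without <- protist_derivatives(st, pools, prey_field(0, 0, 0), cfg, 500)
  expect_identical(with_prey$fluxes, without$fluxes)
  expect_identical(with_prey$dstate, without$dstate)
  # richer prey -> more ingestion -> never more external CO2 uptake
  cm <- make_config("CM")
  st_cm <- state_at(cm, 0.4, 0.4)
  ext <- vapply(c(0, 20, 132.5, 400), function(pc) {
    prey <- if (pc > 0) build_default_prey(pc * 16 / 106)
            else prey_field(0, 0, 0)
    d <- protist_derivatives(st_cm, pools, prey, cm, 500)
    expect_equal(d$fluxes$gross_photosynthesis_C,
                 gross_photosynthesis(st_cm, 500, cm))
    d$fluxes$CO2_external_uptake
  }, numeric(1))
  expect_true(all(diff(ext) <= 1e-12))
})
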