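# Frozen reference values for the seawater CO2 system, computed with an
# independent implementation of the same published constant formulations
# (Weiss 1974; Lueker et al. 2000; Dickson 1990; Millero 1995; Uppstrom
# 1974) solved with an unrelated root finder (see tools/carbonate_oracle.py).

ref_constants_15_35 <- list(K0 = 0.037459223, K1 = 1.148238198e-06, K2 = 7.430176513e-10,
  KB = 1.920801661e-09, KW = 2.380598455e-14, BT = 0.0004157)

ref_constants_25_35 <- list(K0 = 0.0283918818, K1 = 1.421828137e-06, K2 = 1.081554747e-09,
  KB = 2.52657299e-09, KW = 6.063863686e-14, BT = 0.0004157)

ref_pH_2100_2300_15_35 <- 8.00705685

ref_equil_300_2300_15_35 <- list(pH = 8.15043124, DIC = 2027.413768)
ref_equil_600_2300_15_35 <- list(pH = 7.89169914, DIC = 2150.060145)

# pH over the DIC x TA grid at 15 degC, S 35 (rows: DIC; cols: TA)
ref_grid_DIC <- c(1800, 1900, 2000, 2100, 2200, 2300, 2400)
ref_grid_TA <- c(2100, 2200, 2300, 2400, 2500)
ref_grid_pH <- matrix(c(
  8.231785, 8.376395, 8.497409, 8.603227, 8.698761,
  8.033426, 8.214952, 8.357684, 8.476996, 8.581115,
  7.774824, 8.019904, 8.198943, 8.339904, 8.457644,
  7.442662, 7.766942, 8.007057, 8.183689, 8.322973,
  7.132508, 7.446125, 7.759533, 7.994835, 8.169131,
  6.914793, 7.145960, 7.449333, 7.752558, 7.983194,
  6.761394, 6.932026, 7.158547, 7.452315, 7.745981
), nrow = 7, byrow = TRUE, dimnames = list(ref_grid_DIC, ref_grid_TA))
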