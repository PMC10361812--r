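#!/usr/bin/env python
"""Independent reference calculator for the seawater CO2 system.

Evaluates the published constant formulations (Weiss 1974 K0; Lueker et al.
2000 K1/K2 on the total pH scale; Dickson 1990 KB; Millero 1995 KW; Uppstrom
1974 total borate) and solves the alkalinity balance with scipy.brentq.
Used only to generate frozen expected values for the R test suite; the R
package never calls this.
"""
import math
import json
from scipy.optimize import brentq


def constants(T_c, S):
    T = T_c + 273.15
    lnK0 = (-60.2409 + 93.4517 * (100.0 / T) + 23.3585 * math.log(T / 100.0)
            + S * (0.023517 - 0.023656 * (T / 100.0)
                   + 0.0047036 * (T / 100.0) ** 2))
    K0 = math.exp(lnK0)
    pK1 = (3633.86 / T - 61.2172 + 9.6777 * math.log(T)
           - 0.011555 * S + 0.0001152 * S ** 2)
    pK2 = (471.78 / T + 25.929 - 3.16967 * math.log(T)
           - 0.01781 * S + 0.0001122 * S ** 2)
    K1, K2 = 10.0 ** -pK1, 10.0 ** -pK2
    sqS = math.sqrt(S)
    lnKB = ((-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S ** 1.5
             - 0.0996 * S ** 2) / T
            + 148.0248 + 137.1942 * sqS + 1.62142 * S
            + (-24.4344 - 25.085 * sqS - 0.2474 * S) * math.log(T)
            + 0.053105 * sqS * T)
    KB = math.exp(lnKB)
    lnKW = (148.9652 - 13847.26 / T - 23.6521 * math.log(T)
            + (118.67 / T - 5.977 + 1.0495 * math.log(T)) * sqS
            - 0.01615 * S)
    KW = math.exp(lnKW)
    BT = 0.0004157 * S / 35.0
    return dict(K0=K0, K1=K1, K2=K2, KB=KB, KW=KW, BT=BT)


def ta_of_h(h, dic, k):
    denom = h * h + k["K1"] * h + k["K1"] * k["K2"]
    hco3 = dic * k["K1"] * h / denom
    co3 = dic * k["K1"] * k["K2"] / denom
    return (hco3 + 2.0 * co3 + k["BT"] * k["KB"] / (k["KB"] + h)
            + k["KW"] / h - h)


def solve_ph(dic_umol, ta_umol, T_c, S):
    k = constants(T_c, S)
    dic, ta = dic_umol * 1e-6, ta_umol * 1e-6
    f = lambda ph: ta_of_h(10.0 ** -ph, dic, k) - ta
    return brentq(f, 2.0, 12.0, xtol=1e-12)


def equilibrate(pco2_uatm, ta_umol, T_c, S):
    k = constants(T_c, S)
    ta = ta_umol * 1e-6
    co2aq = k["K0"] * pco2_uatm * 1e-6

    def f(ph):
        h = 10.0 ** -ph
        hco3 = co2aq * k["K1"] / h
        co3 = co2aq * k["K1"] * k["K2"] / (h * h)
        return (hco3 + 2.0 * co3 + k["BT"] * k["KB"] / (k["KB"] + h)
                + k["KW"] / h - h) - ta
    ph = brentq(f, 2.0, 12.0, xtol=1e-12)
    h = 10.0 ** -ph
    dic = co2aq * (1.0 + k["K1"] / h + k["K1"] * k["K2"] / (h * h))
    return dict(pH=ph, DIC=dic * 1e6)


if __name__ == "__main__":
    out = {"constants_15_35": constants(15.0, 35.0),
           "constants_25_35": constants(25.0, 35.0),
           "pH_2100_2300_15_35": solve_ph(2100.0, 2300.0, 15.0, 35.0),
           "equil_300_2300_15_35": equilibrate(300.0, 2300.0, 15.0, 35.0),
           "equil_600_2300_15_35": equilibrate(600.0, 2300.0, 15.0, 35.0)}
    grid = {}
    for dic in [1800, 1900, 2000, 2100, 2200, 2300, 2400]:
        for ta in [2100, 2200, 2300, 2400, 2500]:
            grid["pH_%d_%d" % (dic, ta)] = solve_ph(dic, ta, 15.0, 35.0)
    out["grid_15_35"] = grid
    print(json.dumps(out, indent=1))
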