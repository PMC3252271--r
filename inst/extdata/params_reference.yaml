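# Reference kinetic parameters of the meiotic maturation network.
# Identifiers are systematic (ks_<target>_<driver>, ka_/ki_ for maximal
# activation/inactivation rates, km_* Michaelis constants, total_* class-II
# totals, lambda_class2 the arbitrary class-II rate scale). Values were
# calibrated module-wise: the MAPK cascade as a bistable switch, the MPF-APC
# core as a relaxation oscillator with excitable onset, and the remaining
# couplings against the wild-type MPF time course, the double-bistability
# diagram and the knockout phenotype classes. Units: concentrations in
# arbitrary units (class-II totals = 1), time in hours.
synthesis:
  ks_mpf_0: 0.08
  ks_apc_0: 0.3
  ks_mos_c1: 0.2
  ks_mpf_c1: 0.08
  ks_mpf_c4: 0.1
  ks_c1_0: 0.1
  ks_c4_c1: 0.3
  ks_emi_0: 0.0
  ks_emi_c4: 0.3
degradation:
  kd_mpf_0: 0.08
  kd_mpf_apc: 3.0
  kd_apc_0: 0.3
  kd_mos_0: 0.15
  kd_c1_0: 0.1
  kd_c1_mpfapc: 2.0
  kd_c4_0: 0.2
  kd_emi_0: 0.15
  kd_emi_x: 0.5
  kdp_emi: 0.5
activation:
  ka_mek_mos: 4.0
  ka_erk_mek: 4.0
  ka_rsk_erk: 4.0
  ka_mos_erk: 0.6
  ka_mpf_0: 0.02
  ka_mpf_c25: 3.0
  ka_c25_mpf: 3.0
  ka_myt_0: 1.0
  ka_apc_mpf: 2.0
  ka_mos_mpf: 1.5
  ka_c1_pg: 1.0
  ka_c1_mpf: 0.75
  ka_c4_mpf: 1.2
  ka_emi_rsk: 3.0
  ka_plx_0: 0.02
  ka_plx_pg: 0.35
  ka_plx_mpf: 2.0
  ka_c25_plx: 1.3
inactivation:
  ki_mek_0: 1.0
  ki_erk_0: 1.0
  ki_rsk_0: 1.0
  ki_mpf_0: 0.1
  ki_mpf_myt: 4.0
  ki_c25_0: 1.0
  ki_myt_mpf: 3.0
  ki_apc_0: 0.5
  ki_mos_0: 0.3
  ki_apc_e0: 4.5
  ki_apc_ea: 5.0
  ki_c1_0: 0.3
  ki_c4_0: 0.3
  ki_emi_mpf: 1.5
  ki_plx_0: 1.0
  ki_myt_plx: 1.0
  ki_myt_mos: 6.0
michaelis:
  km_act_mos: 0.1
  km_inact_mos: 0.1
  km_act_mpf: 0.1
  km_inact_mpf: 0.1
  km_act_apc: 0.1
  km_inact_apc: 0.1
  km_act_c1: 0.1
  km_inact_c1: 0.1
  km_act_c4: 0.1
  km_inact_c4: 0.1
  km_act_emi: 0.1
  km_inact_emi: 0.1
class2_totals:
  total_plx: 1.0
  total_c25: 1.0
  total_myt: 1.0
  total_mek: 1.0
  total_erk: 1.0
  total_rsk: 1.0
class2_scale:
  lambda_class2: 1.0
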