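heart:
  T: 0.40000000000000002
  t_peak: 0.14000000000000001
  t_sys: 0.22
  E_max: 14.0
  E_min: 0.22
  V0: 5.0
atrium:
  C: 2.0
  V0: 0.0
valves:
  R_av: 0.02
  R_ao: 0.10000000000000001
  eps: 0.0
lpm:
  h_max_us: 100.0
  hold: zero_order
  aortic_root:
    C: 0.25
    R_prox: 0.05
  beds:
    innominate:
      R_prox: 0.29999999999999999
      C: 0.05
      R_dist: 26.0
    l_carotid:
      R_prox: 0.29999999999999999
      C: 0.05
      R_dist: 26.0
    l_subclavian:
      R_prox: 0.29999999999999999
      C: 0.05
      R_dist: 26.0
    dao:
      R_prox: 0.14999999999999999
      C: 0.14999999999999999
      R_dist: 8.5
    lpa:
      R_prox: 0.05
      C: 0.12
      R_dist: 1.5
    rpa:
      R_prox: 0.05
      C: 0.12
      R_dist: 1.5
  venous:
    systemic:
      C: 15.0
      R_ret: 0.08
      L_ret: 0.0005
    pulmonary:
      C: 4.0
      R_ret: 0.06
      L_ret: 0.0005
  init:
    V_sv: 17.65780000000000172
    V_a: 6.41279000000000021
    P_ao: 48.70750000000000313
    P_inn: 47.40550000000000352
    P_car: 47.85289999999999822
    P_sub: 47.85289999999999822
    P_dao: 47.84629999999999939
    P_lpa: 11.40429999999999922
    P_rpa: 11.40429999999999922
    P_svn: 4.32951999999999959
    P_pvn: 3.93252999999999986
    Q_svr: 14.29470000000000063
    Q_pvr: 12.62989999999999924
leader:
  branches:
    inlet:
      R: 0.05
      L: 0.001
      k: 0.0
    arch_innominate:
      R: 0.05
      L: 0.001
      k: 0.0
    innominate_outlet:
      R: 0.05
      L: 0.0005
      k: 0.0
    l_carotid:
      R: 0.08
      L: 0.0015
      k: 0.0
    l_subclavian:
      R: 0.08
      L: 0.0015
      k: 0.0
    dao:
      R: 0.05
      L: 0.001
      k: 0.0
    shunt:
      R: 2.60000000000000009
      L: 0.002
      k: 0.14000000000000001
    lpa:
      R: 0.10000000000000001
      L: 0.0008
      k: 0.0
    rpa:
      R: 0.10000000000000001
      L: 0.0008
      k: 0.0
  tol_rel: 1.00000000000000008e-05
  max_iter: 50.0
  dt_min_us: 10.0
  dt_max_us: 2000.0
  dt_init_us: 200.0
  step_tol: 0.002
coupling:
  n_cycles: 8.0
  exchange_iterations: 0.0
seed: 1.0
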