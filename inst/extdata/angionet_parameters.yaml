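binding:
  v165_r2:
    kon: 1.0e+07
    koff: 0.0005
    Kd: 5.0e-11
  v121_r2:
    kon: 1.0e+07
    koff: 0.0005
    Kd: 5.0e-11
  v165_r1:
    kon: 3.0e+07
    koff: 0.0005
    Kd: 1.6666667e-11
  v121_r1:
    kon: 3.0e+07
    koff: 0.0005
    Kd: 1.6666667e-11
  v_n_hspg:
    kon: 3200000.0
    koff: 0.001
    Kd: 3.125e-10
  c_r2_vn:
    kon: 1.0e+07
    koff: 0.001
    Kd: 1.0e-10
  c_r2_vh:
    kon: 1.0e+07
    koff: 0.001
    Kd: 1.0e-10
  c_vr2_n_hspg:
    kon: 3200000.0
    koff: 0.001
    Kd: 3.125e-10
  c_n_h:
    kon: 1.0e+07
    koff: 0.001
    Kd: 1.0e-10
  v_ch:
    kon: 500000.0
    koff: 0.04
    Kd: 8.0e-08
  c_vr2_h:
    kon: 500000.0
    koff: 0.04
    Kd: 8.0e-08
  t_cd36:
    kon: 500000.0
    koff: 0.02
    Kd: 4.0e-08
  t_cd47:
    kon: 500000.0
    koff: 0.02
    Kd: 4.0e-08
  t_lrp1:
    kon: 500000.0
    koff: 0.0085
    Kd: 1.7e-08
  t_b1:
    kon: 500000.0
    koff: 0.04
    Kd: 8.0e-08
  t_ch:
    kon: 500000.0
    koff: 0.0205
    Kd: 4.1e-08
  c_tr_r2:
    kon: 1.0e+07
    koff: 0.001
    Kd: 1.0e-10
  f_ch:
    kon: 500000.0
    koff: 0.0195
    Kd: 3.9e-08
  fh_r:
    kon: 500000.0
    koff: 0.00015
    Kd: 3.0e-10
  f_r:
    kon: 500000.0
    koff: 0.02
    Kd: 4.0e-08
  c_dim:
    kon: 1.0e+07
    koff: 0.0001
    Kd: 1.0e-11
  p_cxcr3:
    kon: 500000.0
    koff: 0.000925
    Kd: 1.85e-09
  p_lrp1:
    kon: 500000.0
    koff: 0.119
    Kd: 2.38e-07
  p_ch:
    kon: 500000.0
    koff: 0.01
    Kd: 2.0e-08
  m9_lrp1:
    kon: 500000.0
    koff: 0.025
    Kd: 5.0e-08
  t_v:
    kon: 500000.0
    koff: 0.005
    Kd: 1.0e-08
  t_f:
    kon: 500000.0
    koff: 0.0054
    Kd: 1.08e-08
  p_v:
    kon: 500000.0
    koff: 0.0025
    Kd: 5.0e-09
  p_f:
    kon: 500000.0
    koff: 0.0185
    Kd: 3.7e-08
  v_ih:
    kon: 500000.0
    koff: 0.04
    Kd: 8.0e-08
  f_ih:
    kon: 500000.0
    koff: 0.0195
    Kd: 3.9e-08
  t_ih:
    kon: 500000.0
    koff: 0.0205
    Kd: 4.1e-08
  p_ih:
    kon: 500000.0
    koff: 0.01
    Kd: 2.0e-08
  v_n_alone:
    kon: 3200000.0
    koff: 0.02
    Kd: 6.25e-09
  c_vr2_n_alone:
    kon: 3200000.0
    koff: 0.02
    Kd: 6.25e-09
  c_vn_h:
    kon: 1.0e+07
    koff: 0.0001
    Kd: 1.0e-11
  c_r1_n:
    kon: 1.0e+07
    koff: 0.01
    Kd: 1.0e-09
  c_r1_h:
    kon: 1.0e+07
    koff: 0.0002
    Kd: 2.0e-11
unimolecular:
  koff_trimer_h: 0.001
  kint: 0.00028
catalytic:
  k_act_m9: 450.0
  k_cl_t: 1.2e+07
  k_cl_v: 70000.0
half_life_s:
  V165: 3600.0
  V121: 3600.0
  V114: 3600.0
  FGF2: 3600.0
  TSP1: 3600.0
  TSP1c: 3600.0
  PF4: 300.0
  MMP3: 3600.0
  proMMP9: 3600.0
  MMP9: 3600.0
production:
  q_v165_ec: 0.32154
  q_v165_tc: 0.32154
  q_v121_ec: 0.32154
  q_v121_tc: 0.32154
  q_fgf2_ec: 2.22574
  q_fgf2_tc: 2.22574
  q_tsp1_ec: 0.528693
  q_tsp1_tc: 0.528693
  q_mmp3_ec: 1.63385
  q_mmp3_tc: 1.63385
  q_prommp9_ec: 3.00638
  q_prommp9_tc: 3.00638
  q_pf4: 3.0656e+09
densities:
- species: VEGFR1
  side: ec
  value: 4500.0
  units: receptors/cell
  provenance: placeholder
- species: VEGFR2
  side: ec
  value: 3500.0
  units: receptors/cell
  provenance: placeholder
- species: NRP1
  side: ec
  value: 20000.0
  units: receptors/cell
  provenance: placeholder
- species: FGFR1
  side: ec
  value: 18000.0
  units: receptors/cell
  provenance: placeholder
- species: CD36
  side: ec
  value: 2000.0
  units: receptors/cell
  provenance: placeholder
- species: CD47
  side: ec
  value: 2000.0
  units: receptors/cell
  provenance: placeholder
- species: LRP1
  side: ec
  value: 1000.0
  units: receptors/cell
  provenance: placeholder
- species: B1
  side: ec
  value: 1000.0
  units: receptors/cell
  provenance: placeholder
- species: CXCR3
  side: ec
  value: 2500.0
  units: receptors/cell
  provenance: printed
- species: cHSPG
  side: ec
  value: 200000.0
  units: receptors/cell
  provenance: placeholder
- species: VEGFR1
  side: tc
  value: 500.0
  units: receptors/cell
  provenance: placeholder
- species: VEGFR2
  side: tc
  value: 300.0
  units: receptors/cell
  provenance: placeholder
- species: NRP1
  side: tc
  value: 15000.0
  units: receptors/cell
  provenance: placeholder
- species: FGFR1
  side: tc
  value: 18000.0
  units: receptors/cell
  provenance: placeholder
- species: CD36
  side: tc
  value: 2000.0
  units: receptors/cell
  provenance: placeholder
- species: CD47
  side: tc
  value: 2000.0
  units: receptors/cell
  provenance: placeholder
- species: LRP1
  side: tc
  value: 1000.0
  units: receptors/cell
  provenance: placeholder
- species: B1
  side: tc
  value: 1000.0
  units: receptors/cell
  provenance: placeholder
- species: CXCR3
  side: tc
  value: 2500.0
  units: receptors/cell
  provenance: printed
- species: cHSPG
  side: tc
  value: 200000.0
  units: receptors/cell
  provenance: placeholder
- species: iHSPG
  side: matrix
  value: 1.0e+14
  units: sites/cm3
  provenance: placeholder
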