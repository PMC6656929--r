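tumor_volume_cm3: 33.0
interstitial_fluid_fraction: 0.31
cells_ec_per_cm3: 1.0e+07
cells_tc_per_cm3: 1.0e+08
area_ec_cm2_per_cm3: 70.0
area_tc_cm2_per_cm3: 600.0
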