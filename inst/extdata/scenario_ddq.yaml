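# Simulation scenario: donor drug with 2,3-dichloro-5,6-dicyano-1,4-benzoquinone (DDQ).
name: ddq
lambda_max_nm: 470
K_L_mol: 137.0
epsilon_L_mol_cm: 2.07e+4
band_gap_eV: 2.1
acceptor_conc_M: 4.41e-3
donor_conc_range_M: [2.45e-5, 1.22e-4]
donor_uv_peaks_nm: [225, 253, 310]
calibration:
  slope_AU_per_ug_ml: 0.0117
  intercept_AU: 0.1361
  linear_range_ug_ml: [5, 300]
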