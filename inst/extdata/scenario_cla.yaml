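# Simulation scenario: donor drug with chloranilic acid (CLA) as pi-acceptor.
name: cla
lambda_max_nm: 530
K_L_mol: 147.0
epsilon_L_mol_cm: 1.29e+4
band_gap_eV: 1.9
acceptor_conc_M: 4.79e-3
donor_conc_range_M: [3.67e-5, 1.22e-4]
donor_uv_peaks_nm: [225, 253, 310]
calibration:
  slope_AU_per_ug_ml: 0.0289
  intercept_AU: 0.0887
  linear_range_ug_ml: [5, 120]
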