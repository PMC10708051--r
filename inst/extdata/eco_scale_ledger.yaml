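# Analytical Eco-Scale penalty ledger for the microwell charge-transfer assay.
method: microwell CT-complex spectrophotometric assay
items:
  - category: reagent_amount
    description: "solvent (methanol), <1 mL per sample"
    pp: 1
  - category: reagent_amount
    description: "reagent (pi-acceptor), <1 mL per sample"
    pp: 1
  - category: reagent_hazard
    description: "solvent: methanol"
    pp: 3
  - category: reagent_hazard
    description: "reagent: pi-acceptors"
    pp: 3
  - category: instrument_energy
    description: "microplate reader, <0.1 kWh per sample"
    pp: 0
  - category: occupational
    description: "hermetic process, no vapor emission"
    pp: 0
  - category: waste_production
    description: "<1 mL waste per sample"
    pp: 1
  - category: waste_treatment
    description: "no treatment"
    pp: 3
# Published pictogram-tool outputs, passed through into reports (not computed):
gapi:
  red_parameters: [1, 7, 15]
  yellow_parameters: [5, 6]
agree:
  score: 0.76
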