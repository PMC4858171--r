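design:
  strains:
  - '704'
  - cyg56
  - cdp1
  - '20.40'
  - '54.10'
  - '258.90'
  - '259.89'
  - N10
  - N24
  wild_type: '704'
  conditions:
  - NO3_4mM
  - NH4_8mM
  - NO3_4mM+NH4_8mM
  - NO3_4mM+NH4_1mM
  timepoints:
  - 0.5
  - 1.0
  - 3.0
  - 24.0
  gene_panel:
  - CYG56
  - CDP1
  - 20.40CG1
  - 258.90CG
  - CG-A
  - CG-B
  - 42.49CG1
  - 42.49CG2
  - 85.37CG
  - 106.20CG1
  - 106.20CG2
  - 209.82CG
  reference_gene: CYG56
  internal_standard: UBQ
  gene_to_mutant:
    CYG56: cyg56
    CDP1: cdp1
    20.40CG1: '20.40'
    258.90CG: '258.90'
    42.49CG1: '42.49'
    42.49CG2: '42.49'
    85.37CG: '85.37'
    106.20CG1: '106.20'
    106.20CG2: '106.20'
    209.82CG: '209.82'
baseline_log2: {}
condition_effects:
  CYG56:
    NH4_8mM: 2.0
    NO3_4mM+NH4_8mM: 2.0
    NO3_4mM+NH4_1mM: 1.0
  CDP1:
    NH4_8mM: 2.0
    NO3_4mM+NH4_8mM: 2.0
    NO3_4mM+NH4_1mM: 1.0
time_effects:
  CYG56:
    '24': -0.5
  CDP1:
    '24': -0.5
genotype_effects:
  CYG56:
    cyg56: 0.5
    cdp1: -2.0
    '20.40': 1.5
    '54.10': -3.0
    '258.90': -1.0
    '259.89': 2.0
    N10: -2.5
    N24: 1.0
  CDP1:
    cyg56: 0.05
    cdp1: -0.2
    '20.40': 0.15
    '54.10': -3.0
    '258.90': -0.1
    '259.89': 0.2
    N10: -0.25
    N24: 0.1
  42.49CG1:
    cyg56: 0.5
    cdp1: -2.0
    '20.40': 1.5
    '54.10': -3.0
    '258.90': -1.0
    '259.89': 2.0
    N10: -2.5
    N24: 1.0
  85.37CG:
    cyg56: 0.45
    cdp1: -1.8
    '20.40': 1.35
    '54.10': -1.0
    '258.90': -0.9
    '259.89': 1.8
    N10: -2.25
    N24: 0.9
  209.82CG:
    cyg56: 0.45
    cdp1: -1.8
    '20.40': 1.35
    '258.90': -0.9
    '259.89': 1.8
    N10: -2.25
    N24: 0.9
knockout_floor_log2: -10.0
noise_sd_log2: 0.5
detection_floor: 0.0009765625
seed: 1
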