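# Base-case model specification (2025 USD; survival time in months).
engine: both
cycle_days: 28
horizon_years: 10
discount_annual: 0.05
wtp: 41811
bg_annual_mortality: 0.00804
markov_grid: cycle
accrual: half_cycle
ae_disutility_once: true
vial_strategy: exact
patient:
  weight: 65.0
  bsa: 1.72
  crcl: 70.0
prices:
  sac_vial: 1315.85
  pem_vial: 65.52
  carb_vial: 11.06
  cis_vial: 1.71
  osi_tab: 23.18
  bsc_cycle: 436.19
  ae:
    anemia: 448.56
    leukopenia: 421.40
    neutropenia: 406.56
    thrombocytopenia: 2937.46
vial_strengths:
  sac: 200
  pem: 500
  carb: 150
  cis: 200
followup:
  cbc: 2.10
  biochem: 25.20
  urinalysis: 2.52
  ct: 11.20
  mri: 70.00
  nursing: 3.64
  bed: 2.80
  consult: 3.08
  injection: 0.81
  prep: 4.76
  ct_every: 2
  mri_every: 3
utilities:
  pfs: 0.804
  pd: 0.321
ae:
  name: [anemia, leukopenia, neutropenia, thrombocytopenia]
  disutility: [0.073, 0.200, 0.200, 0.190]
  inc_sac_tmt: [0.110, 0.280, 0.400, 0.020]
  inc_chemo: [0.140, 0.220, 0.330, 0.160]
strategies:
  sac_tmt:
    label: sac-TMT
    regimen: sac
    pfs: {family: lognormal, meanlog: 2.20, sdlog: 0.999}
    os: {family: loglogistic, shape: 1.538, scale: 27.354}
    pd_mix: {bsc: 1.0, pem: 0.0, osi: 0.0}
  chemo:
    label: Chemotherapy
    regimen: chemo
    pfs: {family: loglogistic, shape: 2.420, scale: 4.590}
    os: {family: weibull_ph, shape: 1.599, rate: 0.007}
    pd_mix: {bsc: 1.0, pem: 0.0, osi: 0.180}
comparator: chemo
psa:
  "n": 1000   # quoted: bare n is YAML-1.1 boolean
  seed: 2026
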