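name: >-
  First-line pembrolizumab + chemotherapy vs placebo + chemotherapy,
  advanced TNBC, PD-L1 CPS >= 10, Chinese healthcare system, 2024 US$
settings:
  cycle_days: 21
  horizon_cycles: 174            # 10 years of 3-week cycles
  discount_rate: 0.05
  wtp: 38224                     # 3x China per-capita GDP (2023)
  background_mortality_annual: 0.002
  half_cycle_correction: false
  ae_disutility_scope: intervention
patient:
  bsa_m2: 1.72
  weight_kg: 65.0
strategies:
  pembro_chemo:
    role: intervention
    n_trial: 220
    curves:
      pfs: {family: lognormal, meanlog: 2.3487, sdlog: 1.2258}
      os:  {family: lognormal, meanlog: 3.1454, sdlog: 1.1058}
    regimen:
      - {drug: pembrolizumab,  dose_mg: 200.0, rule: flat,   admin_per_cycle: 1, max_cycles: 35, weight: 1.00}
      - {drug: gemcitabine,    dose_mg: 1000.0, rule: per_m2, admin_per_cycle: 2, max_cycles: 6, weight: 0.55}
      - {drug: carboplatin,    dose_mg: 260.0, rule: flat,   admin_per_cycle: 2, max_cycles: 6, weight: 0.55}
      - {drug: nab_paclitaxel, dose_mg: 100.0, rule: per_m2, admin_per_cycle: 3, max_cycles: 6, weight: 0.32}
      - {drug: paclitaxel,     dose_mg: 90.0,  rule: per_m2, admin_per_cycle: 3, max_cycles: 6, weight: 0.13}
    ae:
      anemia: 0.165
      neutropenia: 0.297
      neutrophil_count_decreased: 0.174
  placebo_chemo:
    role: comparator
    n_trial: 103
    curves:
      pfs: {family: loglogistic, shape: 1.763, scale: 6.618}
      os:  {family: loglogistic, shape: 1.702, scale: 16.631}
    regimen:
      - {drug: gemcitabine,    dose_mg: 1000.0, rule: per_m2, admin_per_cycle: 2, max_cycles: 6, weight: 0.55}
      - {drug: carboplatin,    dose_mg: 260.0, rule: flat,   admin_per_cycle: 2, max_cycles: 6, weight: 0.55}
      - {drug: nab_paclitaxel, dose_mg: 100.0, rule: per_m2, admin_per_cycle: 3, max_cycles: 6, weight: 0.32}
      - {drug: paclitaxel,     dose_mg: 90.0,  rule: per_m2, admin_per_cycle: 3, max_cycles: 6, weight: 0.13}
    ae:
      anemia: 0.146
      neutropenia: 0.299
      neutrophil_count_decreased: 0.203
costs:
  drug_price_per_100mg:
    pembrolizumab: 2451.60
    gemcitabine: 18.64
    carboplatin: 7.06
    nab_paclitaxel: 20.25
    paclitaxel: 24.75
  supportive_per_cycle: 359.0
  follow_up_per_cycle: 170.0
  terminal_care: 2325.75
  ae_per_event:
    anemia: 607.06
    neutropenia: 547.50
    neutrophil_count_decreased: 104.95
  supportive_gate: on_treatment   # supportive care accompanies active chemotherapy
  follow_up_gate: pd              # routine follow-up accrues in progressed disease
utilities:
  pfs: 0.76
  pd: 0.55
  death: 0.0
disutilities:                     # absolute one-off QALY decrements
  anemia: 0.029
  neutropenia: 0.012
  neutrophil_count_decreased: 0.2
psa:
  n_iterations: 1000
  seed: 20250101
  include_survival_uncertainty: true
  trial_cutoff_months: 44
  censor_rate_per_month: 0.006
parameters:
  - {id: cost_pembrolizumab, path: costs.drug_price_per_100mg.pembrolizumab, base: 2451.60, lower: 1838.70, upper: 3064.50, dist: gamma}
  - {id: cost_gemcitabine, path: costs.drug_price_per_100mg.gemcitabine, base: 18.64, lower: 13.98, upper: 23.30, dist: gamma}
  - {id: cost_carboplatin, path: costs.drug_price_per_100mg.carboplatin, base: 7.06, lower: 5.29, upper: 8.82, dist: gamma}
  - {id: cost_nab_paclitaxel, path: costs.drug_price_per_100mg.nab_paclitaxel, base: 20.25, lower: 15.19, upper: 25.31, dist: gamma}
  - {id: cost_paclitaxel, path: costs.drug_price_per_100mg.paclitaxel, base: 24.75, lower: 18.56, upper: 30.94, dist: gamma}
  - {id: cost_anemia, path: costs.ae_per_event.anemia, base: 607.06, lower: 455.30, upper: 758.83, dist: gamma}
  - {id: cost_neutropenia, path: costs.ae_per_event.neutropenia, base: 547.50, lower: 410.63, upper: 684.38, dist: gamma}
  - {id: cost_neutrophil_count_decreased, path: costs.ae_per_event.neutrophil_count_decreased, base: 104.95, lower: 78.71, upper: 131.19, dist: gamma}
  - {id: cost_supportive, path: costs.supportive_per_cycle, base: 359.0, lower: 269.25, upper: 448.75, dist: gamma}
  - {id: cost_follow_up, path: costs.follow_up_per_cycle, base: 170.0, lower: 127.50, upper: 212.50, dist: gamma}
  - {id: cost_terminal, path: costs.terminal_care, base: 2325.75, lower: 1744.34, upper: 2907.24, dist: gamma}
  - {id: utility_pfs, path: utilities.pfs, base: 0.76, lower: 0.57, upper: 0.95, dist: beta}
  - {id: utility_pd, path: utilities.pd, base: 0.55, lower: 0.41, upper: 0.69, dist: beta}
  - {id: disutility_anemia, path: disutilities.anemia, base: 0.029, lower: 0.022, upper: 0.036, dist: beta}
  - {id: disutility_neutropenia, path: disutilities.neutropenia, base: 0.012, lower: 0.009, upper: 0.015, dist: beta}
  - {id: disutility_neutrophil_count_decreased, path: disutilities.neutrophil_count_decreased, base: 0.2, lower: 0.149, upper: 0.498, dist: beta}
  - {id: risk_anemia_pembro, path: strategies.pembro_chemo.ae.anemia, base: 0.165, lower: 0.134, upper: 0.196, dist: beta}
  - {id: risk_neutropenia_pembro, path: strategies.pembro_chemo.ae.neutropenia, base: 0.297, lower: 0.259, upper: 0.335, dist: beta}
  - {id: risk_neutrophil_pembro, path: strategies.pembro_chemo.ae.neutrophil_count_decreased, base: 0.174, lower: 0.142, upper: 0.206, dist: beta}
  - {id: risk_anemia_placebo, path: strategies.placebo_chemo.ae.anemia, base: 0.146, lower: 0.104, upper: 0.188, dist: beta}
  - {id: risk_neutropenia_placebo, path: strategies.placebo_chemo.ae.neutropenia, base: 0.299, lower: 0.245, upper: 0.353, dist: beta}
  - {id: risk_neutrophil_placebo, path: strategies.placebo_chemo.ae.neutrophil_count_decreased, base: 0.203, lower: 0.156, upper: 0.251, dist: beta}
  - {id: discount_rate, path: settings.discount_rate, base: 0.05, lower: 0.0, upper: 0.08, dist: beta}
  - {id: bsa, path: patient.bsa_m2, base: 1.72, lower: 1.29, upper: 2.15, dist: beta}
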