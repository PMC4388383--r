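label: duration6
horizon_months: 6
wtp_grid: [0, 100, 200, 300, 400, 500, 600, 700, 800, 900, 1000, 1100, 1200, 1300, 1400, 1500, 1600, 1700, 1800, 1900, 2000, 2100, 2200, 2300, 2400, 2500, 2600, 2700, 2800, 2900, 3000, 3100, 3200, 3300, 3400, 3500, 3600, 3700, 3800, 3900, 4000, 4100, 4200, 4300, 4400, 4500, 4600, 4700, 4800, 4900, 5000]
intervention.name: liraglutide
intervention.hba1c_reduction: [1.48, 1.38, 1.58, beta]
intervention.p_disc_early: [0.0333, 0.0266, 0.04, beta]
intervention.p_disc_late: [0.0978, 0.0782, 0.1174, beta]
intervention.monthly_drug_cost: [536, 482, 589, normal]
intervention.monthly_supply_cost: [9, 8, 10, normal]
intervention.p_any_teae: [0.6489, 0.5191, 0.7787, beta]
intervention.p_gi_given_teae: [0.547, 0.4378, 0.6566, beta]
comparator.name: exenatide
comparator.hba1c_reduction: [1.28, 1.18, 1.38, beta]
comparator.p_disc_early: [0, 0, 0.01, beta]
comparator.p_disc_late: [0.1323, 0.1059, 0.1588, beta]
comparator.monthly_drug_cost: [407, 367, 448, normal]
comparator.monthly_supply_cost: [0, 0, 0, fixed]
comparator.p_any_teae: [0.6139, 0.4911, 0.7367, beta]
comparator.p_gi_given_teae: [0.3993, 0.3194, 0.4792, beta]
shared.gi_event_cost: [1113, 890, 1335, normal]
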