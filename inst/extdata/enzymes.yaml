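# Default enzyme and nanoparticle definitions for the glycolysis /
# saccharification cascade presets.
#
# Units: kcat in 1/s per monomer active site, km in micromolar,
# monomer_kda in kDa, delta_g in kJ/mol (standard transformed reaction
# energy), capacities as integer copies-per-particle ranges estimated
# from enzyme size and binding orientation, nanoparticle dims in nm.
#
# "free" blocks hold apparent Michaelis-Menten constants measured for the
# enzyme free in solution; "bound" blocks hold the constants measured
# with the enzyme displayed on quantum dots (the ratio showing maximal
# enhancement; see direction_note where an assay ran the reverse
# reaction for technical reasons).

cascade:
  default_preset: 7E
  k_cof_uM: 10        # half-saturation of the smooth cofactor-availability factor

conditions:
  upstream:           # glucose -> 3-PG family (7E/8E/9E/10E), NADH formation
    glucose_uM: 10000
    atp_uM: 7500
    adp_uM: 7500
    nad_uM: 1130
    pi_uM: 4000
    sucrose_uM: 120000        # 8E / 10E substrate
    maltoheptaose_uM: 4000    # 9E / 10E substrate
    t_end_s: 64800            # 18 h monitoring
    sample_dt_s: 60
  downstream:         # 3-PG -> lactate (4E), NADH consumption
    pg3_uM: 7500
    nadh_uM: 1500
    adp_uM: 10000
    pi_uM: 4000
    t_end_s: 324000           # > 90 h monitoring
    sample_dt_s: 300
  epsilon_nadh: 6220          # 1/(M cm) at 340 nm
  path_length_cm: 0.36        # 50 uL in a 384-well plate; plate-geometry specific

assay:
  # Printed free-enzyme working concentrations (nM) for cascade assays.
  enzyme_concs_nM:
    7E: {Glk: 5.5, PGI: 1, PFK: 9, FBA: 12, TPI: 1, GPD: 27, PGK: 7.5}
    9E: {Amy: 6.4, Mlt: 8.5, Glk: 7.5, PGI: 2, PFK: 10, FBA: 12, TPI: 1,
         GPD: 27, PGK: 9.5}
    4E: {PGM: 89.5, Eno: 38.5, PykA: 93.5, LDH: 94}

noise:
  sigma_abs: 0.002
  sample_dt_s: 60

optimize:
  t_obs_s: 30000
  round1_factors: [0.5, 1, 2, 4]
  round2_factors: [0.75, 1, 1.25, 1.5]

np:
  QD520: {shape: sphere, dims: [4.0]}
  QD600: {shape: sphere, dims: [9.7]}
  QD660: {shape: sphere, dims: [13.4]}
  NPL:   {shape: platelet, dims: [19.2, 17.3, 2.6]}

enzymes:
  Amy:
    name: Amylase
    subunits: 1
    monomer_kda: 59.6
    free:  {kcat: 25.0, km: 213, kcat_se: 0.4, km_se: 15}
    bound: {kcat: 24.9, km: 212, kcat_se: 1.9, km_se: 28}
    capacity: {QD520: [4, 10], QD600: [18, 25], QD660: [32, 39], NPL: [24, 36]}
  Mlt:
    name: Maltase
    subunits: 1
    monomer_kda: 74.5
    free:  {kcat: 0.40, km: 335, kcat_se: 0.03, km_se: 80}
    bound: {kcat: 15.3, km: 347, kcat_se: 5.8, km_se: 90}
    capacity: {QD520: [4, 8], QD600: [16, 21], QD660: [26, 34], NPL: [21, 31]}
  Inv:
    name: Invertase
    subunits: 4
    monomer_kda: 47.2
    free:  {kcat: 0.07, km: 191, kcat_se: 0.01, km_se: 100}
    bound: {kcat: 0.26, km: 2504, kcat_se: 0.03, km_se: 954}
    capacity: {QD520: [4, 6], QD600: [11, 17], QD660: [18, 29], NPL: [14, 24]}
  Glk:
    name: Glucokinase
    subunits: 2
    monomer_kda: 36.9
    free:  {kcat: 2.6, km: 36, kcat_se: 0.1, km_se: 10}
    bound: {kcat: 30.7, km: 109, kcat_se: 6.3, km_se: 14}
    capacity: {QD520: [6, 7], QD600: [19, 29], QD660: [34, 43], NPL: [25, 33]}
  PGI:
    name: Phosphoglucose isomerase
    subunits: 2
    monomer_kda: 63.7
    direction_note: assayed in the reverse direction (F6P -> G6P)
    free:  {kcat: 2481, km: 393, kcat_se: 53, km_se: 31}
    bound: {kcat: 2033, km: 398, kcat_se: 89, km_se: 46}
    capacity: {QD520: [4, 7], QD600: [14, 20], QD660: [22, 34], NPL: [17, 23]}
  PFK:
    name: Phosphofructokinase I
    subunits: 4
    monomer_kda: 34.6
    free:  {kcat: 10.1, km: 202, kcat_se: 0.2, km_se: 21}
    bound: {kcat: 9.8, km: 203, kcat_se: 0.7, km_se: 25}
    capacity: {QD520: [5, 9], QD600: [13, 21], QD660: [22, 36], NPL: [17, 24]}
  FBA:
    name: Fructose-bisphosphate aldolase
    subunits: 2
    monomer_kda: 41.3
    free:  {kcat: 6.8, km: 216, kcat_se: 0.2, km_se: 23}
    bound: {kcat: 5.7, km: 160, kcat_se: 2.8, km_se: 20}
    capacity: {QD520: [5, 9], QD600: [18, 27], QD660: [29, 45], NPL: [23, 30]}
  TPI:
    name: Triose phosphate isomerase
    subunits: 2
    monomer_kda: 29.1
    free:  {kcat: 194, km: 1717, kcat_se: 12, km_se: 236}
    bound: {kcat: 225.8, km: 2628, kcat_se: 38.3, km_se: 693}
    capacity: {QD520: [7, 12], QD600: [23, 32], QD660: [37, 43], NPL: [29, 38]}
  GPD:
    name: Glyceraldehyde-3-phosphate dehydrogenase
    subunits: 4
    monomer_kda: 37.7
    delta_g: 15.9
    free:  {kcat: 3.2, km: 3494, kcat_se: 0.04, km_se: 1039}
    bound: {kcat: 9.6, km: 1790, kcat_se: 4.8, km_se: 844}
    capacity: {QD520: [4, 6], QD600: [13, 20], QD660: [20, 34], NPL: [16, 28]}
  PGK:
    name: Phosphoglycerate kinase
    subunits: 1
    monomer_kda: 43.3
    delta_g: -20.2
    direction_note: assayed in the reverse direction (3-PG -> 1,3-BPG)
    free:  {kcat: 18.1, km: 1048, kcat_se: 0.9, km_se: 171}
    bound: {kcat: 53.1, km: 933, kcat_se: 4.6, km_se: 72}
    capacity: {QD520: [5, 12], QD600: [19, 28], QD660: [31, 43], NPL: [29, 36]}
  PGM:
    name: Phosphoglycerate mutase
    subunits: 1
    monomer_kda: 58.3
    free:  {kcat: 1.0, km: 3584, kcat_se: 0.1, km_se: 1138}
    bound: {kcat: 5.3, km: 3344, kcat_se: 0.5, km_se: 514}
    capacity: {QD520: [4, 10], QD600: [15, 23], QD660: [25, 36], NPL: [24, 37]}
  Eno:
    name: Enolase
    subunits: 2
    monomer_kda: 47.8
    free:  {kcat: 22.9, km: 2040, kcat_se: 3.0, km_se: 72}
    bound: {kcat: 31.1, km: 2361, kcat_se: 5.6, km_se: 249}
    capacity: {QD520: [5, 11], QD600: [16, 25], QD660: [26, 41], NPL: [21, 33]}
  PykA:
    name: Pyruvate kinase II
    subunits: 4
    monomer_kda: 53.5
    free:  {kcat: 277, km: 690, kcat_se: 9, km_se: 70}
    bound: {kcat: 214, km: 920, kcat_se: 6, km_se: 80}
    capacity: {QD520: [3, 9], QD600: [10, 19], QD660: [16, 27], NPL: [13, 26]}
  LDH:
    name: Lactate dehydrogenase
    subunits: 4
    monomer_kda: 38.7
    free:  {kcat: 195.5, km: 1470, kcat_se: 10.4, km_se: 690}
    bound: {kcat: 202, km: 1732, kcat_se: 7.6, km_se: 3578}
    capacity: {QD520: [4, 10], QD600: [12, 27], QD660: [20, 33], NPL: [16, 32]}
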