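# Measured acoustical and mechanical properties of grafts and biomaterials
# for temporal-bone reconstruction. average_tl_db is the 13-band average
# transmission loss at the listed specimen thickness; for the gelatin
# sponge the absorption average (0.171) is listed instead.
- name: gelatin_sponge
  thickness_mm: 6.6
  diameter_mm: 20
  density_kg_m3: 34.2
  average_absorption: 0.171
  youngs_modulus_mpa: 0.170
  poisson_ratio: 0.3
- name: solidified_gelatin_sponge
  thickness_mm: 6.4
  diameter_mm: 20
  density_kg_m3: 368.9
  average_tl_db: 10.9
  youngs_modulus_mpa: 0.0599
  poisson_ratio: 0.3
- name: bone_wax
  thickness_mm: 3.3
  diameter_mm: 20
  density_kg_m3: 945.3
  average_tl_db: 45.3
  youngs_modulus_mpa: 0.146
  poisson_ratio: 0.37
- name: bone_pate_1
  thickness_mm: 1.5
  diameter_mm: 20
  density_kg_m3: 420
  average_tl_db: 7.0
  youngs_modulus_mpa: 12000
  poisson_ratio: 0.3
- name: bone_pate_2
  thickness_mm: 1.5
  diameter_mm: 30
  density_kg_m3: 465
  average_tl_db: 3.6
  youngs_modulus_mpa: 12000
  poisson_ratio: 0.3
- name: temporalis_fascia_1
  thickness_mm: 1.5
  diameter_mm: 20
  density_kg_m3: 703
  average_tl_db: 9.7
  youngs_modulus_mpa: 36
  poisson_ratio: 0.3
- name: temporalis_fascia_2
  thickness_mm: 2.0
  diameter_mm: 30
  density_kg_m3: 536
  average_tl_db: 18.5
  youngs_modulus_mpa: 36
  poisson_ratio: 0.3
- name: auricular_cartilage
  thickness_mm: 1.0
  diameter_mm: 20
  density_kg_m3: 1130
  average_tl_db: 15.2
  youngs_modulus_mpa: 1.66
  poisson_ratio: 0.47
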