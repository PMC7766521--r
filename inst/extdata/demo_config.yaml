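# Demonstration pipeline configuration (desk-scale problem sizes).
seed: 1
ligand:
  tautomer: Ntau
  protonated: true
  side_torsion: 158.8
solvation:
  n_water: 40
  radius: 8.0
  contact_distance: 2.8
aqueous:
  n_frames: 300
  populations:
    trans: 0.73
    gauche: 0.27
  jitter_sigma: 0.01
  # marginal occupancies of the three N2...water contacts (mean 2.2 bonds)
  n2_contact_occupancies: [1.0, 1.0, 0.2]
conformer:
  gauche_max: 90.0
  trans_min: 120.0
hbond:
  distance: 3.5
  angle: 135.0
rdf:
  r_max: 7.0
  dr: 0.1
deuteration:
  fraction: 0.023
shell:
  n_waters: 12
  cutoff: 4.0
cluster_ranges:
  - [98, 103]
  - [186, 190]
  - [250, 254]
energies: cycle_components.tsv
decomposition:
  table: mmgbsa_per_residue.tsv
  favorable_threshold: -0.06
  unfavorable_threshold: 0.02
affinity:
  temperature: 298.15
  pki: 4.3
  pic50_control: 7.25
  pic50_d2o: 7.80
  pH: 7.4
  pKa_ring: 6.0
  pKa_amine: 9.7
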