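simulate:
  n_genomes: 24
  n_estus: 6
  core_size: 60
  flex_size: 240
  n_ecags: 6
  ecag_size_min: 3
  ecag_size_max: 7
  max_gap: 1
  n_neutral: 120
  neutral_carriage: 0.5
  n_stations: 40
  depth: 5.0
  read_length: 100
  gene_length_min: 800
  gene_length_max: 2500
  overdispersion: 0.0
  marker_length: 645
normalize:
  min_families: ~
  min_cov: 1.0
  min_samples: 2
  marker: petB
  min_marker_cov: 0.1
cluster:
  linkage: ward.D2
  n_perm: 10000
  k: ~
modules:
  powers:
  - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  - 7
  - 8
  - 9
  - 10
  - 11
  - 12
  - 13
  - 14
  - 15
  - 16
  - 17
  - 18
  - 19
  - 20
  target_fit: 0.8
  n_bins: 10
  min_module_size: 10
  cut_height: 0.995
  merge_height: 0.25
  min_gene_kme: 0.5
  min_kme: 0.7
  alpha: 0.01
  transform: none
  marker_control: yes
synteny:
  mode: support
  D_support: 5
  D_any: 4
  min_support: 0.8
ecags:
  min_size: 2
  genus_prefix: Pro
  enrichment_alpha: 0.05
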