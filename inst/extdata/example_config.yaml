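# Example run configuration: the general-purpose 20:80 mix for the packaged
# UK lowland candidate lists. Point `input` at a species trait table CSV.
input: species.csv
out_dir: seedmix_out
name: general_20_80
filter:
  life_history: perennial
  native_status: native
  require_distribution: true
  require_pollinator_support_forbs: true
rubric:
  profile: uk_lowland_2019
  soil_profile: most_soils
  soil_weight: 5
selection:
  forbs:
    min_total: 6            # reproduces the case-study forb cut
    include:
      - Primula vulgaris    # early flowerer, included despite its score
  grasses: {}               # no threshold: all gated grasses are considered
mix:
  forb_fraction: 0.2
  season: [3, 10]           # March-October activity season
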