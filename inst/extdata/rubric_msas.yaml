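name: MSAS
ebl_bins:
- min: 0.0
  max: 50.0
  min_incl: yes
  max_incl: yes
  points: 3
- min: 50.0
  max: 150.0
  min_incl: no
  max_incl: yes
  points: 2
- min: 150.0
  max: 300.0
  min_incl: no
  max_incl: yes
  points: 1
- min: 300.0
  max: .inf
  min_incl: no
  max_incl: no
  points: 0
map_bins:
- min: 0.0
  max: 40.0
  min_incl: no
  max_incl: no
  points: 0
- min: 40.0
  max: 55.0
  min_incl: yes
  max_incl: no
  points: 1
- min: 55.0
  max: 70.0
  min_incl: yes
  max_incl: no
  points: 2
- min: 70.0
  max: .inf
  min_incl: yes
  max_incl: no
  points: 3
hr_bins:
- min: 0.0
  max: 55.0
  min_incl: no
  max_incl: yes
  points: 4
- min: 55.0
  max: 65.0
  min_incl: no
  max_incl: yes
  points: 3
- min: 65.0
  max: 75.0
  min_incl: no
  max_incl: yes
  points: 2
- min: 75.0
  max: 85.0
  min_incl: no
  max_incl: yes
  points: 1
- min: 85.0
  max: .inf
  min_incl: no
  max_incl: no
  points: 0
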