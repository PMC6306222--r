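# Demonstration configuration: 40x40 climate cells, fine vegetation at 5x
# resolution, the default five-variable climate, ten-class niche layout and
# six-output scenario set at three time steps.
grid:
  rows: 40
  cols: 40
  fine_factor: 5
  cell_area_ha: 100
seed: 20260926
label_noise: 0.1
variables: default
rules: default
classes: default
scenarios: default
timesteps: [2020s, 2050s, 2080s]
model:
  n_trees: 200
  holdout: 0.2
  replace: false
  threshold: ~   # null means 1/K
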