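# Desk-scale demo pipeline: 2 archetype species, 3 grid steps per trait,
# one N level, 2 scored years per run.
seed: 42
out_dir: grasscape_demo
n_levels: [360]
fraction: 0.3
steps: 3
years: 2
spin_cycles: 3
species:
  n: 2
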