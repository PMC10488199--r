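# Demo pipeline configuration: everything generated, small sizes.
seed: 7
output_dir: pumplipid_demo_out
stages:
  kinetics: yes
  membrane: yes
  conservation: no
alpha: 0.05
kinetics:
  reference: PC
  window_s: 30
  base_rate: 0.001          # 1/s, reference initial quench rate
  quench_k: 0.006           # shared quench time constant (1/s)
  n_traces: 6
  noise_sd: 0.005
  conditions:
    PC: 1.0
    PS: 5.3
    PG: 2.4
membrane:
  n_frames: 60
  n_lipids_total: 524
  composition: {PS: 0.1, PC: 0.9}
  cutoff: 0.55
  site_spacing: 0.05
  spacing_3d: 0.1
  min_enrichment: 2.0
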