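# Coarse end-to-end smoke configuration: one fixed-grid solve, a small-voxel
# synthetic series, morphometry and ROC. Runs in well under a minute.

[solver]
flow_rate = "12 ml/min"
spacing = 150e-6
refine = false
include_inertia = true

[uct]
voxel_size = 130e-6

[synthetic]
weeks = [2, 3, 4]
rate = 0.3
bonus = 0.25
noise_sd = 25

[run]
seed = 7
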