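# Phantom-style ES-mGRE protocol: TR 1200 ms, flip 75 deg, one third of the
# 64 echoes shifted, K = 10, desk-scale 64 x 64 matrix; slice count is
# maximized for the readout block.
config_version: 1
TR: 1200
n_slices: auto
n_echoes: 64
n_shifted: 21
TE1: 3.0
dTE: 1.47
dPE: 0.8
K: 10
flip_angle: 75
slice_thickness: 2
readout_bandwidth: 800
matrix: [64, 64]
fov: [240.0, 216.0]
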