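# In vivo ES-mGRE protocol: 64 echoes (43 prompt + 21 shifted), navigators
# at train slots 16 and 49, K = 10 on the slice axis, 1 x 1 mm in-plane.
config_version: 1
TR: 3000
n_slices: 23
n_echoes: 64
n_shifted: 21
TE1: 3.0
dTE: 1.47
dPE: 0.8
K: 10
flip_angle: 60
slice_thickness: 2
readout_bandwidth: 800
matrix: [240, 216]
fov: [240.0, 216.0]
navigator_slots: [16, 49]
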