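# Packaged default synthetic sapling grammar (see ?sapling_grammar).
# Rotation symbols may be written with ASCII aliases: < > yaw, ^ & pitch.
axiom: FA
rules:
  A: "[^FA]+++[>FA]"
iterations: 7
angle_mean: 30
angle_sd: 5
initial_length: 1
length_scaling_mean: 0.75
length_scaling_sd: 0.1
initial_radius: 0.1
radius_scaling_mean: 0.75
radius_scaling_sd: 0.1
seed: 42
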