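# Synthetic demo study at the reference scale:
# 3 diet groups (C, Exp1, Exp2) x 15 birds x 4 scanning planes (L, T, O1, O2),
# 480 x 640 speckle ultrasonograms calibrated to the reference MPI targets.
out_dir = demo_out
seed = 1
n_per_group = 15
image_rows = 480
image_cols = 640
spot_diameter = 33
spot_spacing = 40
alpha = 0.05
n_traits_nominal = 26
pooled = true
mph_mode = per-spot
bh_annotation = false
screen_source = images
anisotropy_L = 3
anisotropy_T = 1
anisotropy_O1 = 1.5
anisotropy_O2 = 2.5
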