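# Example postop3d pipeline configuration (desk-scale phantom).
seed: 7
out: postop3d-run
simulate: true
phantom:
  shape: [64, 64, 64]
  spacing: 2
  n_screws: 4
  noise_sd: 20
backends:
  cuts: oracle
  pelvis: oracle
coarse_registration:
  sampling: 0.25
fine_registration:
  sampling: 0.25
hough:
  minvotes: 20   # point clouds at 2 mm voxels carry ~90 points per screw
head_axis: [0, 0, 1]
hu_threshold: 2500
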