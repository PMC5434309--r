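# Demonstration pipeline configuration: virtual grinding of the bundled
# two-sphere phantom (bone sphere r = 500 um with an axial vessel channel),
# 35 um nominal abrasion, then registration, segmentation, reconstruction
# and morphometry.
seed: 7
pixel_size_um: 5
simulate:
  preset: two_sphere_test
  n_runs: 33
  nominal_abrasion: 35
out_dir: microgrindr_out
# reconstruction voxel: the 35 um inter-plane gap dominates the volume
# error, so voxels finer than ~gap/3 only add runtime
voxel_size_um: 10
smoothing_iters: 10
min_area_um2: 200
diffusion_limit_um: 150
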