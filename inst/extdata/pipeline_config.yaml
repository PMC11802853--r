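# Bundled end-to-end fixture: 4 patients x (blood + tumour) x 250 cells
# = 2,000 cells, with the default subsampling depths and 1000 replicates.
seed: 7
simulate:
  n_patients: 4
  cells_per_sample: 250
  shared_clone_prob: 0.2
  cross_subset_prob: 0.2
  shm_rate: 2
  depth_mean: 2000
  clone_size_law:
    law: power_law
    alpha: 2.5
clonality:
  intra_depth: 5
  inter_depth: 50
  reps: 1000
interactions:
  min_cells: 3
  include_self: true
scoring:
  positive_subset: DC
  negative_subset: CD8_effector
  n_bins: 24
  n_ctrl: 100
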