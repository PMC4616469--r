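# Shared fixtures, built in code.

# canonical measurement set: tumor/in/out counts 800/150/50, tumor 500 mL,
# in-target 1000 mL, out-target 300 mL, LSF 0.05
fix_measurements <- function(lsf = 0.05) {
  partition_measurements(
    tumor = voi_measurement(500, total_counts = 800),
    in_target = voi_measurement(1000, total_counts = 150),
    out_target = voi_measurement(300, total_counts = 50),
    lung_total_counts = 0, lsf = lsf)
}

# random measurement sets for property tests
random_measurements <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    partition_measurements(
      tumor = voi_measurement(runif(1, 20, 2000), total_counts = runif(1, 1, 5000)),
      in_target = voi_measurement(runif(1, 20, 2000), total_counts = runif(1, 1, 5000)),
      out_target = voi_measurement(runif(1, 20, 2000), total_counts = runif(1, 1, 5000)),
      lung_total_counts = runif(1, 0, 500),
      lsf = runif(1, 0, 0.19))
  })
}

# small fast phantom: same 384 mm anatomy at 8 mm voxels
small_spec <- function(...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L), voxel_size = 8, ...)
}
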