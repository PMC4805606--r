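# Small in-code fixtures shared across test files.

unit_grid <- function(n = c(16L, 16L, 16L), dims = c(1, 1, 1)) {
  voxel_grid(n, diag(c(dims, 1)))
}

# mask with the given linear voxel indices set
mask_from_idx <- function(grid, idx, label = "WMH") {
  v <- array(0, grid$shape)
  v[idx] <- 1
  label_mask(grid, v, label = label)
}

random_mask <- function(grid, p = 0.1, label = "WMH") {
  label_mask(grid, array(as.numeric(runif(prod(grid$shape)) < p),
                         grid$shape), label = label)
}

# axis-aligned solid cube mask of side `side` voxels starting at `at` (1-based)
cube_mask <- function(grid, at = c(3L, 3L, 3L), side = 10L, label = "WMH") {
  v <- array(0, grid$shape)
  v[at[1]:(at[1] + side - 1), at[2]:(at[2] + side - 1),
    at[3]:(at[3] + side - 1)] <- 1
  label_mask(grid, v, label = label)
}

# compact phantom for registration tests: same scene, smaller lattice
small_phantom_spec <- function(rotations_deg = c(0, 0, 0),
                               translations_mm = c(0, 0, 0), seed = 7L,
                               noise_sd = 1.4, ...) {
  phantom_spec(
    shape = c(64L, 64L, 48L), brain_semiaxes_mm = c(26, 28, 20),
    ventricle_centers_mm = rbind(c(-7, 5, 1), c(7, 5, 1)),
    ventricle_semiaxes_mm = c(5, 11, 7),
    lesions = list(
      list(center = c(10, 17, 1), baseline_cc = 1.5, followup_cc = 1.5,
           class = "stable"),
      list(center = c(-15, -4, 5), baseline_cc = 1.0, followup_cc = 0.4,
           class = "shrinking"),
      list(center = c(13, -10, -4), baseline_cc = 0.4, followup_cc = 1.1,
           class = "growing")),
    rotations_deg = rotations_deg, translations_mm = translations_mm,
    noise_sd = noise_sd, seed = seed, ...)
}

run_phantom_subject <- function(ph, inject = TRUE, id = "s1", ...) {
  run_subject(ph$baseline_t1, ph$followup_t1, ph$baseline_wmh,
              ph$followup_wmh, ph$baseline_vcsf, ph$followup_vcsf,
              subject_id = id,
              inject_transform = if (inject) ph$true_transform else NULL,
              ...)
}

rotation_error_deg <- function(a, b) {
  d <- rigid_compose(rigid_invert(a), b)$matrix[1:3, 1:3]
  acos(max(-1, min(1, (sum(diag(d)) - 1) / 2))) * 180 / pi
}

translation_error_mm <- function(a, b) {
  d <- rigid_compose(rigid_invert(a), b)$matrix[1:3, 4]
  sqrt(sum(d^2))
}
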