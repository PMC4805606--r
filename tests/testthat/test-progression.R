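test_that("overlap decomposition follows the set definitions", {
  g <- unit_grid(c(8L, 8L, 8L))
  b <- mask_from_idx(g, c(1, 2, 3))
  f <- mask_from_idx(g, c(2, 3, 4))
  ov <- compute_overlap(b, f)
  expect_equal(which(ov$shrink$values == 1), 1)
  expect_equal(which(ov$grow$values == 1), 4)
  expect_equal(which(ov$stable$values == 1), c(2, 3))

  # empty baseline: everything present at follow-up is growth
  ov0 <- compute_overlap(mask_from_idx(g, integer(0)), f)
  expect_equal(sum(ov0$shrink$values), 0)
  expect_equal(sum(ov0$stable$values), 0)
  expect_identical(ov0$grow$values, f$values)
})

test_that("overlap conservation is exact on random mask pairs", {
  set.seed(77)
  g <- unit_grid(c(48L, 48L, 48L))
  for (i in 1:20) {
    b <- random_mask(g, runif(1, 0.05, 0.3))
    f <- random_mask(g, runif(1, 0.05, 0.3))
    ov <- compute_overlap(b, f)
    expect_identical(sum(ov$stable$values) + sum(ov$shrink$values),
                     sum(b$values))
    expect_identical(sum(ov$stable$values) + sum(ov$grow$values),
                     sum(f$values))
    # disjointness
    expect_equal(sum(ov$shrink$values * ov$grow$values), 0)
    expect_equal(sum(ov$shrink$values * ov$stable$values), 0)
    expect_equal(sum(ov$grow$values * ov$stable$values), 0)
    # grow - shrink equals the intermediate-space net change, exactly
    expect_equal(volume_cc(ov$grow) - volume_cc(ov$shrink),
                 volume_cc(f) - volume_cc(b), tolerance = 1e-12)
  }
})

test_that("ventricular correction removes exactly the engulfed voxels", {
  g <- unit_grid(c(16L, 16L, 16L))
  # no ventricular change: nothing removed
  b <- mask_from_idx(g, 1:100)
  f <- mask_from_idx(g, 51:150)
  vcsf <- mask_from_idx(g, 2001:2100, label = "vCSF")
  ov <- compute_overlap(b, f)
  vc <- ventricular_correction(ov, vcsf, vcsf)
  expect_equal(sum(vc$removed$values), 0)
  expect_identical(vc$masks$shrink$values, ov$shrink$values)

  # one baseline-WMH voxel inside the growth region leaves shrink
  vcsf_f <- mask_from_idx(g, c(2001:2100, 1), label = "vCSF")
  vc1 <- ventricular_correction(ov, vcsf, vcsf_f)
  expect_equal(which(vc1$removed$values == 1), 1)
  expect_equal(sum(vc1$masks$shrink$values), sum(ov$shrink$values) - 1)

  # 50 engulfed baseline voxels lower shrink volume by exactly 50 voxels
  vcsf_f50 <- mask_from_idx(g, c(2001:2100, 1:50), label = "vCSF")
  vc50 <- ventricular_correction(ov, vcsf, vcsf_f50)
  expect_equal(volume_cc(ov$shrink) - volume_cc(vc50$masks$shrink),
               50 * voxel_volume_mm3(g) / 1000)
  # conservation still holds after correction
  expect_identical(sum(vc50$masks$stable$values) +
                     sum(vc50$masks$shrink$values),
                   sum(vc50$masks$baseline_int$values))
})

test_that("net change matches published serial-volume differences", {
  expect_equal(net_change(14.0, 15.7), 1.7, tolerance = 1e-12)
  expect_equal(net_change(9.2, 4.5), -4.7, tolerance = 1e-12)
  expect_equal(net_change(5.0, 5.0), 0)
  expect_error(net_change(-1, 2))
})

test_that("the per-subject pipeline recovers phantom dynamics (oracle)", {
  ph <- generate_phantom(default_phantom_suite()$mixed)
  res <- run_phantom_subject(ph, inject = TRUE)
  expect_equal(res$shrink_cc, ph$truth$shrink_cc, tolerance = 1e-12)
  expect_equal(res$grow_cc, ph$truth$grow_cc, tolerance = 1e-12)
  expect_equal(res$stable_cc, ph$truth$stable_cc, tolerance = 1e-12)
  expect_equal(res$vcsf_removed_cc, ph$truth$engulfed_cc, tolerance = 1e-12)
  # engulfed voxels sit in pre-correction shrink, so after correction the
  # spatial net exceeds the native net by exactly the removed volume
  expect_equal(res$net_change_intermediate_cc,
               res$net_change_cc + res$vcsf_removed_cc, tolerance = 1e-12)
})

test_that("rotational oracle runs recover volumes within resampling noise", {
  ph <- generate_phantom(small_phantom_spec(
    rotations_deg = c(2, -1.5, 3), translations_mm = c(2, -1, 1.5),
    seed = 61L))
  res <- run_phantom_subject(ph, inject = TRUE)
  for (k in c("shrink", "grow", "stable")) {
    tru <- ph$truth[[paste0(k, "_cc")]]
    expect_lt(abs(res[[paste0(k, "_cc")]] - tru), max(0.05, 0.05 * tru))
  }
})

test_that("swapping scan order swaps shrink and grow (injected)", {
  ph <- generate_phantom(default_phantom_suite()$high_burden)
  fwd <- run_phantom_subject(ph, inject = TRUE)
  rev <- run_subject(ph$followup_t1, ph$baseline_t1, ph$followup_wmh,
                     ph$baseline_wmh, ph$followup_vcsf, ph$baseline_vcsf,
                     subject_id = "rev",
                     inject_transform = rigid_invert(ph$true_transform))
  expect_equal(rev$shrink_cc, fwd$grow_cc, tolerance = 0.01)
  expect_equal(rev$grow_cc, fwd$shrink_cc, tolerance = 0.01)
  expect_lt(abs(rev$stable_cc - fwd$stable_cc) / fwd$stable_cc, 0.01)
})

test_that("enlarging the follow-up mask never shrinks grow or stable", {
  set.seed(91)
  g <- unit_grid(c(24L, 24L, 24L))
  b <- random_mask(g, 0.15)
  f <- random_mask(g, 0.15)
  extra <- mask_union(f, random_mask(g, 0.05))
  ov1 <- compute_overlap(b, f)
  ov2 <- compute_overlap(b, extra)
  expect_gte(volume_cc(ov2$grow), volume_cc(ov1$grow))
  expect_gte(volume_cc(ov2$stable), volume_cc(ov1$stable))
})

test_that("stage failures carry subject and stage context", {
  ph <- generate_phantom(small_phantom_spec())
  bad_wmh <- mask_from_idx(unit_grid(c(8L, 8L, 8L)), 1)
  expect_error(
    run_subject(ph$baseline_t1, ph$followup_t1, bad_wmh, ph$followup_wmh,
                ph$baseline_vcsf, ph$followup_vcsf, subject_id = "s9"),
    "\\[s9\\] stage 'validate inputs'")
})
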