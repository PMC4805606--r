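test_that("zero motion, zero noise, static lesions give identical scans", {
  static <- lapply(default_lesions(), function(L) {
    L$followup_cc <- L$baseline_cc; L
  })
  ph <- generate_phantom(phantom_spec(
    lesions = static, expansion_factor = 1.0, noise_sd = 0,
    rotations_deg = c(0, 0, 0), translations_mm = c(0, 0, 0)))
  expect_identical(ph$baseline_t1$values, ph$followup_t1$values)
  expect_identical(ph$baseline_wmh$values, ph$followup_wmh$values)
  expect_equal(ph$truth$shrink_cc, 0)
  expect_equal(ph$truth$grow_cc, 0)
  expect_equal(ph$truth$engulfed_cc, 0)
})

test_that("lesion realisation hits target volumes within one voxel", {
  ph <- generate_phantom(phantom_spec(
    lesions = list(list(center = c(-20, -8, 6), baseline_cc = 10,
                        followup_cc = 10, class = "stable")),
    expansion_factor = 1.0, rotations_deg = c(0, 0, 0),
    translations_mm = c(0, 0, 0)))
  vx_cc <- voxel_volume_mm3(ph$baseline_wmh$grid) / 1000
  expect_lte(abs(volume_cc(ph$baseline_wmh) - 10), vx_cc)
})

test_that("generation is deterministic by seed", {
  a <- generate_phantom(phantom_spec(seed = 9L))
  b <- generate_phantom(phantom_spec(seed = 9L))
  expect_identical(a$baseline_t1$values, b$baseline_t1$values)
  expect_identical(a$followup_t1$values, b$followup_t1$values)
  c <- generate_phantom(phantom_spec(seed = 10L))
  expect_false(identical(a$baseline_t1$values, c$baseline_t1$values))
  # masks are noise-free, hence seed independent
  expect_identical(a$baseline_wmh$values, c$baseline_wmh$values)
})

test_that("truth volumes are self-consistent for every suite phantom", {
  for (spec in default_phantom_suite()) {
    tr <- generate_phantom(spec)$truth
    expect_equal(tr$baseline_wmh_cc,
                 tr$stable_cc + tr$shrink_cc + tr$engulfed_cc,
                 tolerance = 1e-12)
    expect_equal(tr$followup_wmh_cc, tr$stable_cc + tr$grow_cc,
                 tolerance = 1e-12)
  }
})

test_that("ventricular expansion engulfs periventricular lesion voxels", {
  ph <- generate_phantom(phantom_spec(expansion_factor = 1.15,
                                      rotations_deg = c(0, 0, 0),
                                      translations_mm = c(0, 0, 0)))
  expect_gt(ph$truth$engulfed_cc, 0.1)
  expect_gt(ph$truth$followup_vcsf_cc, ph$truth$baseline_vcsf_cc)
  # engulfed voxels left the follow-up WMH mask
  expect_lt(ph$truth$followup_wmh_cc,
            ph$truth$baseline_wmh_cc + ph$truth$grow_cc)
})

test_that("infeasible lesions are rejected by name", {
  expect_error(phantom_spec(lesions = list(
    list(center = c(60, 0, 0), baseline_cc = 1, followup_cc = 1,
         class = "stable"))), "lesion 1 centre lies outside")
  expect_error(phantom_spec(lesions = list(
    list(center = c(11, 8, 2), baseline_cc = 1, followup_cc = 1,
         class = "stable"))), "inside a baseline ventricle")
  expect_error(generate_phantom(phantom_spec(lesions = list(
    list(center = c(-20, -8, 6), baseline_cc = 400, followup_cc = 400,
         class = "stable")))), "lesion 1 .* overflows")
  expect_error(phantom_spec(rotations_deg = c(30, 0, 0)), "sanity bound")
})

test_that("truth_table scores oracle runs and flags id mismatches", {
  suite <- default_phantom_suite()[c("mixed", "incident")]
  truths <- lapply(suite, generate_phantom)
  results <- lapply(names(truths), function(id)
    run_phantom_subject(truths[[id]], inject = TRUE, id = id))
  tt <- truth_table(truths, results)
  expect_equal(max(tt$aggregate$max_abs_err_cc), 0)
  expect_equal(tt$frac_rot_within_half_deg, 1)
  expect_identical(dim(tt$per_subject)[1], 2L)

  results[[1]]$subject_id <- "wrong"
  expect_error(truth_table(truths, results), "mismatch")
})

test_that("identity-motion phantoms give exactly zero dynamic error", {
  static <- lapply(default_lesions(), function(L) {
    L$followup_cc <- L$baseline_cc; L
  })
  ph <- generate_phantom(phantom_spec(
    lesions = static, expansion_factor = 1.0, rotations_deg = c(0, 0, 0),
    translations_mm = c(0, 0, 0)))
  res <- run_phantom_subject(ph, inject = TRUE, id = "id0")
  tt <- truth_table(list(id0 = ph), list(res))
  expect_equal(max(tt$per_subject$shrink_abs_err_cc,
                   tt$per_subject$grow_abs_err_cc,
                   tt$per_subject$stable_abs_err_cc,
                   tt$per_subject$engulfed_abs_err_cc), 0)
})

test_that("phantom output files round trip through disk", {
  ph <- generate_phantom(small_phantom_spec(translations_mm = c(1.2, 0, 0)))
  d <- file.path(tempdir(), "ph_out")
  paths <- write_phantom(ph, d)
  expect_true(all(file.exists(paths)))
  m <- read_volume(paths["baseline_wmh"], as = "mask")
  expect_identical(m$values, ph$baseline_wmh$values)
  t2 <- read_transform(paths["true_transform"])
  expect_lt(max(abs(t2$matrix - ph$true_transform$matrix)), 1e-10)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$shrink_cc, ph$truth$shrink_cc)
})
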