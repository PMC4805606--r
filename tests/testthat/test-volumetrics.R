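test_that("TIC is the union volume of the supplied compartments", {
  # 10 mm voxels: one voxel = 1 cc, so counts read directly as cc
  g <- unit_grid(c(20L, 20L, 20L), dims = c(10, 10, 10))
  gm <- mask_from_idx(g, 1:600, label = "GM")
  wm <- mask_from_idx(g, 601:1100, label = "WM")
  csf <- mask_from_idx(g, 1101:1200, label = "sCSF")
  expect_equal(compute_tic(list(gm, wm, csf)), 1200)
  # overlapping voxels are counted once
  wm_overlap <- mask_from_idx(g, 301:1100, label = "WM")
  expect_equal(compute_tic(list(gm, wm_overlap, csf)), 1200)
  expect_equal(compute_tic(list(gm)), volume_cc(gm))
})

test_that("BPF follows (GM + WM + WMH) / TIC", {
  expect_equal(compute_bpf(500, 400, 5, 1216.6), 905 / 1216.6)
  expect_equal(compute_bpf(500, 400, 5, 1216.6), 0.7439, tolerance = 1e-4)
  expect_equal(compute_bpf(600, 590, 10, 1200), 1.0)
  expect_equal(compute_bpf(0, 0, 0, 1200), 0.0)
  expect_error(compute_bpf(500, 400, 5, 0), "positive")
  expect_error(compute_bpf(900, 900, 100, 1000), "exceeds")
})

test_that("BPF is invariant under uniform voxel rescaling", {
  build <- function(scale) {
    g <- unit_grid(c(12L, 12L, 12L), dims = rep(scale, 3))
    list(gm = mask_from_idx(g, 1:400, "GM"),
         wm = mask_from_idx(g, 401:700, "WM"),
         wmh = mask_from_idx(g, 701:720, "WMH"),
         scsf = mask_from_idx(g, 721:800, "sCSF"),
         vcsf = mask_from_idx(g, 801:850, "vCSF"))
  }
  bpf <- vapply(c(0.5, 1, 2.7), function(s) {
    m <- build(s)
    do.call(tissue_volumes, m)$bpf
  }, 0)
  expect_lt(max(abs(bpf - bpf[1])), 1e-12)
})

test_that("SVD classification splits at the threshold with strict low", {
  expect_identical(classify_svd(1.3), "low")
  expect_identical(classify_svd(14.0), "high")
  expect_identical(classify_svd(3.5), "high")   # boundary goes high
  expect_identical(classify_svd(3.5 - 1e-9), "low")
  expect_error(classify_svd(-0.1), "non-negative")
  # monotone in volume
  v <- sort(runif(50, 0, 10))
  cls <- classify_svd(v)
  expect_true(all(diff(cls == "high") >= 0))
  # configurable threshold
  expect_identical(classify_svd(5, threshold_cc = 6), "low")
})

test_that("cohort summaries report group mean with population SD", {
  rows <- data.frame(group = c("NC", "AD"), shrink_cc = c(1.3, 3.8),
                     grow_cc = c(2.1, 6.3), stable_cc = c(4.4, 9.3),
                     net_change_cc = c(0.8, 1.7))
  s <- summarize_cohort(rows)
  tab <- s$table
  nc_grow <- tab[tab$group == "NC" & tab$variable == "grow_cc", ]
  expect_equal(nc_grow$mean, 2.1)
  expect_equal(nc_grow$sd, 0)
  expect_equal(nc_grow$n, 1)

  # duplicating the cohort changes neither means nor SDs
  s2 <- summarize_cohort(rbind(rows, rows))
  expect_equal(s2$table$mean, tab$mean)
  expect_equal(s2$table$sd, tab$sd)
  expect_identical(s$sd_convention, "population")
})

test_that("log transforms admit zero change volumes", {
  rows <- data.frame(group = "NC", shrink_cc = 0, grow_cc = 0.5,
                     stable_cc = 2, net_change_cc = 0)
  s <- summarize_cohort(rows, log_offset_cc = 0.01)
  tab <- s$table
  expect_equal(tab[tab$variable == "log_shrink_cc", "mean"], log(0.01))
  expect_true(is.finite(tab[tab$variable == "log_shrink_cc", "mean"]))
  # log-modulus of the signed net change is 0 at 0 and odd
  expect_equal(tab[tab$variable == "log_net_change_cc", "mean"], 0)
  r2 <- data.frame(group = c("a", "a"), net_change_cc = c(-2, 2))
  t2 <- summarize_cohort(r2)$table
  expect_equal(t2[t2$variable == "log_net_change_cc", "mean"], 0)
})

test_that("group means are recovered from sampled cohorts", {
  set.seed(314)
  n <- 200
  # right-skewed growth volumes with mean 6.3 cc, SD 4.3 cc
  shape <- (6.3 / 4.3)^2
  rows <- data.frame(group = "AD_high",
                     grow_cc = rgamma(n, shape = shape,
                                      scale = 4.3^2 / 6.3))
  s <- summarize_cohort(rows)
  est <- s$table[s$table$variable == "grow_cc", ]
  expect_lt(abs(est$mean - 6.3), 2 * 4.3 / sqrt(n))
})

test_that("degenerate cohorts are rejected", {
  expect_error(summarize_cohort(data.frame()), "empty")
  expect_error(summarize_cohort(data.frame(x = 1)), "group")
})
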