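# The activation chain: window percent change, voxelwise Welch t, the
# rank-based false-positive filter (against a brute-force oracle), the
# signed significance mask, composites, VOA and time courses.

test_that("percent change is the window-mean contrast in percent", {
  nt <- 60
  series <- c(rep(1000, 30), rep(1020, 30))
  sc <- constant_scan(series)
  pc <- percent_change(sc, c(1, 30), c(31, 60))
  expect_equal(unique(pc[sc$mask]), 2)

  const <- constant_scan(rep(500, nt))
  expect_equal(unique(percent_change(const, c(1, 30), c(31, 60))[const$mask]), 0)

  # invariant under global rescaling of the scan
  sc2 <- sc
  sc2$data <- sc2$data * 7.3
  expect_equal(
    percent_change(sc2, c(1, 30), c(31, 60)),
    percent_change(sc, c(1, 30), c(31, 60))
  )

  # flagged acquisitions are excluded from the means
  flagged <- sc
  flagged$data[, , , 31] <- 1e6
  flagged$outlier_flags[31] <- TRUE
  expect_equal(
    unique(percent_change(flagged, c(1, 30), c(31, 60))[sc$mask]), 2
  )

  expect_error(percent_change(sc, c(1, 30), c(25, 60)), "disjoint")
})

test_that("voxelwise Welch t matches stats::t.test and calibrates under the null", {
  set.seed(7)
  # dual route: the vectorised Welch path against t.test voxel by voxel
  Y <- matrix(rnorm(20 * 30, mean = 100), 20, 30)
  sc <- matrix_scan(Y, c(5, 4, 1))
  p <- voxel_ttest(sc, c(1, 14), c(15, 30))
  p_ref <- apply(Y, 1, function(y) t.test(y[15:30], y[1:14])$p.value)
  expect_equal(p[sc$mask], p_ref, tolerance = 1e-10)

  # null calibration: p uniform across 10,000 voxels
  Yn <- matrix(rnorm(10000 * 40, mean = 50), 10000, 40)
  scn <- matrix_scan(Yn, c(100, 100, 1))
  pn <- voxel_ttest(scn, c(1, 20), c(21, 40))[scn$mask]
  expect_gt(stats::ks.test(pn, "punif")$p.value, 0.01)

  # a +10 SD shift is detected overwhelmingly
  Ys <- cbind(
    matrix(rnorm(50 * 20), 50, 20), matrix(rnorm(50 * 20, mean = 10), 50, 20)
  )
  scs <- matrix_scan(Ys, c(50, 1, 1))
  ps <- voxel_ttest(scs, c(1, 20), c(21, 40))[scs$mask]
  expect_lt(max(ps), 1e-6)

  # zero variance in both windows: p = 1 by convention
  scz <- constant_scan(rep(5, 40))
  expect_equal(unique(voxel_ttest(scz, c(1, 20), c(21, 40))[scz$mask]), 1)
})

# independent brute-force reading of the step-up rule: try every rank i
# from largest to smallest; the first i with P_(i) <= i*q/(V*c_V) wins
fdr_oracle <- function(p, q, c_V = 1) {
  V <- length(p)
  o <- order(p)
  keep <- rep(FALSE, V)
  for (i in rev(seq_len(V))) {
    if (p[o[i]] <= i * q / (V * c_V)) {
      keep[o[seq_len(i)]] <- TRUE
      break
    }
  }
  keep
}

test_that("the rank-based filter matches its brute-force oracle", {
  # worked example: thresholds (0.0667, 0.1333, 0.2) keep only 0.001
  expect_identical(
    fdr_filter(c(0.001, 0.25, 0.9), q = 0.2), c(TRUE, FALSE, FALSE)
  )
  expect_identical(fdr_filter(rep(1, 5), q = 0.2), rep(FALSE, 5))
  expect_identical(fdr_filter(rep(0, 5), q = 0.2), rep(TRUE, 5))

  set.seed(42)
  for (rep_i in seq_len(1000)) {
    V <- sample(1:50, 1)
    p <- round(runif(V), sample(c(1, 2, 3, 6), 1)) # ties included
    q <- sample(c(0.05, 0.2, 0.5, 1), 1)
    expect_identical(fdr_filter(p, q = q), fdr_oracle(p, q))
  }
})

test_that("the filter keep-set is monotone nondecreasing in q", {
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(5:40, 1))
    qs <- sort(runif(4))
    keeps <- lapply(qs, function(q) fdr_filter(p, q = q))
    for (j in seq_len(3)) {
      expect_true(all(keeps[[j]] <= keeps[[j + 1]]))
    }
  }
})

test_that("significance requires both the filter and the magnitude gate", {
  pc <- array(c(0.5, 2.5, -2.5, 0.2), dim = c(4, 1, 1))
  p <- array(c(1e-8, 1e-8, 1e-8, 0.9), dim = c(4, 1, 1))
  sig <- significance_mask(pc, p, q = 0.2, magnitude_threshold_pct = 1)
  expect_identical(as.vector(sig), c(0L, 1L, -1L, 0L)) # tiny p but |0.5%| < 1% gate fails

  # alpha reading: p <= 0.01 instead of the magnitude gate
  sig_a <- significance_mask(pc, p, q = 0.2, gate = "alpha")
  expect_identical(as.vector(sig_a), c(1L, 1L, -1L, 0L))

  # noise-free 2% voxel comes out significant positive
  atl <- small_atlas()
  cfg <- quick_sim_config(
    active_regions = 3L, noise_sd = 0.25, motion_spike_prob = 0
  )
  sim <- simulate_phmri_subject(atl, cfg, "3mg", seed = 13)
  m <- map_activation(sim$scan,
    baseline_window = cfg$baseline_window,
    response_window = cfg$response_window
  )
  expect_gt(
    mean(m$significance[atl$labels == 3] == 1L), 0.95
  )
  expect_lt(mean(m$significance[atl$labels != 3 & atl$labels > 0] != 0L), 0.05)
})

test_that("composite maps average zeroed subject contributions", {
  atl <- small_atlas(R = 3, shape = c(8, 8, 4))
  dims <- dim(atl$labels)
  m1 <- array(2, dims)
  m2 <- array(4, dims)
  comp <- composite_map(list(m1, m2), atlas = atl)
  expect_equal(unique(as.vector(comp)), 3)

  # one subject, identity transform: composite equals its zeroed map
  cfg <- quick_sim_config(active_regions = 2L, noise_sd = 0.5, motion_spike_prob = 0)
  sim <- simulate_phmri_subject(atl, cfg, "3mg", seed = 3)
  am <- map_activation(sim$scan,
    baseline_window = cfg$baseline_window, response_window = cfg$response_window
  )
  comp1 <- composite_map(list(am), atlas = atl)
  z <- ifelse(is.na(am$zeroed), 0, am$zeroed)
  expect_equal(comp1, array(z, dims), tolerance = 1e-10)

  # known shift: the composite peak lands at the atlas-true location
  peak <- array(0, dims)
  peak[3, 4, 2] <- 10
  shift <- affine_transform(translation = c(2, 1, 0))
  shifted_subject <- resample_trilinear(peak, affine_invert(shift))
  shifted_subject[is.na(shifted_subject)] <- 0
  comp_s <- composite_map(list(shifted_subject), list(shift), atlas = atl)
  expect_identical(
    unname(which(comp_s == max(comp_s, na.rm = TRUE), arr.ind = TRUE)[1, ]),
    c(3L, 4L, 2L)
  )

  expect_error(composite_map(list(), atlas = atl), "no subjects")
})

test_that("region VOA counts partition the significant voxels", {
  atl <- small_atlas()
  dims <- dim(atl$labels)
  empty <- array(0L, dims)
  voa0 <- region_voa(empty, atl, "positive")
  expect_true(all(voa0$n_voxels == 0))

  set.seed(5)
  sig <- array(sample(c(-1L, 0L, 1L), prod(dims), replace = TRUE), dims)
  for (sgn in c("positive", "negative")) {
    want <- if (sgn == "positive") 1L else -1L
    voa <- region_voa(sig, atl, sgn)
    expect_identical(
      sum(voa$n_voxels), sum(sig == want & atl$labels > 0)
    )
  }

  # only the simulated active region carries counts in a clean subject
  cfg <- quick_sim_config(active_regions = 4L, noise_sd = 0.25, motion_spike_prob = 0)
  sim <- simulate_phmri_subject(atl, cfg, "3mg", seed = 8)
  m <- map_activation(sim$scan,
    baseline_window = cfg$baseline_window, response_window = cfg$response_window
  )
  voa <- region_voa(m, atl, "positive")
  expect_gt(voa$n_voxels[voa$region_id == 4], 0)
  expect_lt(sum(voa$n_voxels[voa$region_id != 4]), sum(atl$labels > 0) * 0.02)

  expect_error(region_voa(array(0L, dims + 1L), atl), "dimensions differ")
})

test_that("region time courses track the simulated ramp exactly when noise-free", {
  atl <- small_atlas()
  const <- constant_scan(rep(800, 120), shape = dim(atl$labels))
  tc0 <- time_course(const, atl, region_ids = 1:2, baseline_window = c(2, 30))
  expect_true(all(tc0$percent_change == 0))

  cfg <- quick_sim_config(
    active_regions = 3L, noise_sd = 0, motion_spike_prob = 0, drift_slope = 0
  )
  sim <- simulate_phmri_subject(atl, cfg, "3mg", seed = 2)
  tc <- time_course(sim$scan, atl,
    region_ids = 3, baseline_window = cfg$baseline_window
  )
  plateau <- tc$percent_change[tc$acquisition >= cfg$onset_acquisition +
    cfg$ramp_length]
  expect_equal(unique(round(plateau, 10)), 2)
  expect_error(time_course(sim$scan, atl, integer(0)), "empty region set")
})

test_that("epoch contrasts recover a simulated hypercapnic response", {
  # 50-baseline / 50-challenge / 50-post design
  series <- c(rep(1000, 50), rep(1025, 50), rep(1005, 50))
  sc <- constant_scan(series)
  ec <- epoch_contrast(sc, list(
    baseline = c(1, 50), co2 = c(51, 100), post = c(101, 150)
  ))
  expect_equal(ec$mean_percent_change[ec$epoch == "baseline"], 0)
  expect_equal(ec$mean_percent_change[ec$epoch == "co2"], 2.5)
  expect_equal(ec$mean_percent_change[ec$epoch == "post"], 0.5)

  sc2 <- constant_scan(rep(100, 60))
  ec2 <- epoch_contrast(sc2, list(a = c(1, 30), b = c(31, 60)))
  expect_equal(ec2$mean_percent_change, c(0, 0))
  expect_error(
    epoch_contrast(sc2, list(a = c(1, 30), b = c(30, 60))), "overlap"
  )
})

test_that("activation tidiers summarise maps consistently", {
  atl <- small_atlas()
  cfg <- quick_sim_config(active_regions = 2L, noise_sd = 0.5, motion_spike_prob = 0)
  sim <- simulate_phmri_subject(atl, cfg, "3mg", seed = 17)
  m <- map_activation(sim$scan,
    baseline_window = cfg$baseline_window, response_window = cfg$response_window
  )
  td <- tidy(m, atlas = atl)
  gl <- glance(m)
  expect_identical(sum(td$n_positive), gl$n_positive)
  expect_identical(nrow(td), nrow(atl$region_names))
  expect_equal(gl$n_tested, sum(atl$labels > 0))
})
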