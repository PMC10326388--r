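# The generator must deliver what its ground truth claims: known partitions,
# known amplitudes, known noise autocorrelation, and bit-identical reruns.

test_that("atlas generation partitions the brain mask as claimed", {
  # single region: everything in-brain gets label 1
  a1 <- generate_atlas(1, c(8, 8, 8), seed = 1)
  expect_true(all(a1$labels[a1$labels > 0] == 1L))
  expect_gt(sum(a1$labels == 1L), 0)

  # R = 4: exactly 4 nonempty labels; per-region counts partition the mask
  a4 <- generate_atlas(4, c(16, 16, 16), seed = 1)
  counts <- table(a4$labels[a4$labels > 0])
  expect_length(counts, 4L)
  expect_true(all(counts > 0))
  expect_identical(sum(counts), sum(a4$labels > 0))

  # full-scale parcellation count
  a173 <- generate_atlas(173, c(96, 96, 20), seed = 1)
  expect_identical(length(unique(a173$labels[a173$labels > 0])), 173L)
  expect_identical(
    sum(region_sizes(a173)$n_voxels), sum(a173$labels > 0)
  )

  # more regions than voxels is impossible
  expect_error(generate_atlas(10000, c(5, 5, 5)), "exceeds")
})

test_that("atlas generation is deterministic and seed-sensitive", {
  a <- generate_atlas(7, c(12, 12, 8), seed = 5)
  b <- generate_atlas(7, c(12, 12, 8), seed = 5)
  c <- generate_atlas(7, c(12, 12, 8), seed = 6)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c$labels))
})

test_that("noise-free simulation reproduces the configured amplitude exactly", {
  atl <- small_atlas()
  cfg <- quick_sim_config(
    active_regions = 3L, noise_sd = 0, motion_spike_prob = 0, drift_slope = 0
  )
  sim <- simulate_phmri_subject(atl, cfg, dose = "3mg", seed = 1)
  pc <- percent_change(sim$scan, cfg$baseline_window, cfg$response_window)
  expect_equal(unique(pc[atl$labels == 3]), 2, tolerance = 1e-10)
  expect_equal(max(abs(pc[atl$labels > 0 & atl$labels != 3])), 0,
    tolerance = 1e-10
  )
  # ground truth marks exactly the active region
  expect_identical(sim$truth$active_voxel_mask, atl$labels == 3)
  expect_equal(unique(sim$truth$amplitude_map[atl$labels == 3]), 2)
})

test_that("null simulation has near-zero percent change in every region", {
  atl <- small_atlas()
  cfg <- quick_sim_config(motion_spike_prob = 0) # amplitude irrelevant: no active regions
  sim <- simulate_phmri_subject(atl, cfg, dose = "vehicle", seed = 2)
  pc <- percent_change(sim$scan, cfg$baseline_window, cfg$response_window)
  per_region <- tapply(pc[atl$labels > 0], atl$labels[atl$labels > 0], mean)
  # sd of a region-mean percent change is well under 0.2% at these sizes
  expect_lt(max(abs(per_region)), 0.75)
})

test_that("the inverted-U amplitude design and dose errors behave", {
  cfg <- quick_sim_config()
  amps <- cfg$amplitude_by_dose
  expect_true(amps[["3mg"]] > amps[["1mg"]] && amps[["3mg"]] > amps[["10mg"]])
  expect_true(amps[["vehicle"]] == 0)
  atl <- small_atlas()
  expect_error(
    simulate_phmri_subject(atl, cfg, dose = "30mg", seed = 1), "absent"
  )
  expect_error(
    simulate_phmri_subject(
      atl, quick_sim_config(active_regions = 99L), "3mg", 1
    ),
    "not in atlas"
  )
})

test_that("generated null noise has the configured lag-1 autocorrelation", {
  atl <- small_atlas(R = 2, shape = c(8, 8, 6))
  cfg <- phmri_sim_config(
    n_acquisitions = 350L, motion_spike_prob = 0, drift_slope = 0,
    ar1_coefficient = 0.3
  )
  sim <- simulate_phmri_subject(atl, cfg, dose = "vehicle", seed = 9)
  Y <- matrix(sim$scan$data, ncol = 350)[as.vector(sim$scan$mask), ]
  ac1 <- apply(Y[1:50, ], 1, function(x) cor(x[-1], x[-length(x)]))
  expect_lt(abs(mean(ac1) - 0.3), 0.1)
  expect_gt(mean(abs(ac1 - 0.3) < 0.15), 0.9)
})

test_that("simulation is bit-identical under a fixed seed", {
  atl <- small_atlas()
  cfg <- quick_sim_config(active_regions = 2L)
  s1 <- simulate_phmri_subject(atl, cfg, "1mg", seed = 11)
  s2 <- simulate_phmri_subject(atl, cfg, "1mg", seed = 11)
  expect_identical(s1$scan$data, s2$scan$data)
  expect_identical(s1$scan$outlier_flags, s2$scan$outlier_flags)
  st1 <- simulate_phmri_study(atl, quick_sim_config(
    n_per_group = c(vehicle = 2L, `3mg` = 2L)
  ), seed = 3)
  st2 <- simulate_phmri_study(atl, quick_sim_config(
    n_per_group = c(vehicle = 2L, `3mg` = 2L)
  ), seed = 3)
  expect_identical(
    st1$subjects[[1]]$scan$data, st2$subjects[[1]]$scan$data
  )
  expect_identical(st1$manifest, st2$manifest)
})

test_that("resting simulator reproduces its generating covariance", {
  atl <- small_atlas(R = 2, shape = c(10, 10, 6))
  # two nodes correlated at 0.8: recovered r within the Fisher-Z sampling band
  sig <- matrix(c(1, 0.8, 0.8, 1), 2)
  cfg <- resting_sim_config(n_timepoints = 150, node_covariance = sig)
  sim <- simulate_resting_subject(atl, cfg, seed = 4)
  r <- cor(sim$node_series)[1, 2]
  expect_lt(abs(r - 0.8), 0.15)
  # recovered region series track the generating courses
  ts <- region_timeseries(sim$scan, atl)
  expect_gt(cor(ts[, 1], sim$node_series[, 1]), 0.9)
  expect_gt(cor(ts[, 2], sim$node_series[, 2]), 0.9)

  # identity covariance: independent nodes
  atl8 <- small_atlas(R = 8, shape = c(12, 12, 8))
  cfg8 <- resting_sim_config(n_timepoints = 150, node_covariance = diag(8))
  sim8 <- simulate_resting_subject(atl8, cfg8, seed = 5)
  rr <- cor(sim8$node_series)
  expect_lt(mean(abs(rr[upper.tri(rr)])), 0.2)
})

test_that("resting config rejects invalid covariances", {
  bad <- matrix(c(1, 2, 2, 1), 2) # not PSD
  expect_error(resting_sim_config(node_covariance = bad), "semidefinite")
  asym <- matrix(c(1, 0.2, 0.5, 1), 2)
  expect_error(resting_sim_config(node_covariance = asym), "symmetric")
  off_diag <- diag(2) * 2
  expect_error(resting_sim_config(node_covariance = off_diag), "unit diagonal")
  atl <- small_atlas(R = 3, shape = c(10, 10, 6))
  cfg <- resting_sim_config(node_covariance = diag(2))
  expect_error(simulate_resting_subject(atl, cfg, 1), "dimension")
})
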