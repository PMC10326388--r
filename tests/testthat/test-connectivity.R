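# Connectivity: node extraction, Pearson/Fisher-Z edges, group Z scores,
# thresholded graphs with degree identities, k-NN clustering and subregion
# degree comparisons.

test_that("region time series average exactly over region voxels", {
  atl <- small_atlas(R = 4, shape = c(8, 8, 4))
  nt <- 20
  dims <- dim(atl$labels)
  data <- array(rnorm(prod(dims) * nt), dim = c(dims, nt))
  sc <- bold_scan(data, tr_seconds = 1, mask = atl$labels > 0)
  ts <- region_timeseries(sc, atl)
  # brute force for region 2
  sel <- which(atl$labels == 2)
  manual <- vapply(seq_len(nt), function(t) {
    mean(matrix(data[, , , t], ncol = 1)[sel, ])
  }, 0)
  expect_equal(ts[, "2"], manual, tolerance = 1e-12)

  # single-voxel region passes through exactly
  lab1 <- array(0L, c(4, 4, 2))
  lab1[2, 2, 1] <- 1L
  lab1[3, 3, 2] <- 2L
  atl1 <- atlas_volume(lab1)
  d1 <- array(rnorm(32 * nt), dim = c(4, 4, 2, nt))
  sc1 <- bold_scan(d1, tr_seconds = 1, mask = lab1 > 0)
  ts1 <- region_timeseries(sc1, atl1)
  expect_equal(ts1[, "1"], d1[2, 2, 1, ], tolerance = 1e-12)

  # empty region is dropped with a warning
  lab1[3, 3, 2] <- 1L
  atl_gap <- atlas_volume(lab1, region_names = tibble::tibble(
    region_id = 1:2, region_name = c("a", "b")
  ))
  scg <- bold_scan(d1, tr_seconds = 1, mask = lab1 > 0)
  expect_warning(tsg <- region_timeseries(scg, atl_gap), "no voxel support")
  expect_identical(attr(tsg, "dropped_regions"), 2L)
})

test_that("pairwise correlations cover all unordered pairs", {
  set.seed(2)
  x <- rnorm(100)
  series <- cbind(x, -x, rnorm(100))
  colnames(series) <- 1:3
  es <- pairwise_correlation(series)
  expect_equal(es$r[1, 2], -1)
  expect_true(all(is.na(diag(es$r))))
  expect_equal(es$r, t(es$r))

  # node count of the published parcellation: 171 nodes -> 14,535 pairs
  big <- matrix(rnorm(150 * 171), 150, 171)
  esb <- pairwise_correlation(big)
  expect_identical(sum(upper.tri(esb$r)), 14535L)

  # zero-variance node: NA edges
  series2 <- cbind(x, rep(1, 100))
  colnames(series2) <- 1:2
  es2 <- pairwise_correlation(series2)
  expect_true(all(is.na(es2$r[2, ])))
})

test_that("Fisher Z is the closed-form atanh with its exact inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_lt(max(abs(fisher_z_inverse(fisher_z(r)) - r)), 1e-12)
  expect_warning(z1 <- fisher_z(1), "infinite")
  expect_identical(z1, Inf)
  expect_error(fisher_z(1.5), "\\[-1, 1\\]")
})

test_that("group edge test is standard normal under the null and detects constants", {
  zeros <- replicate(5, matrix(0, 4, 4), simplify = FALSE)
  Z0 <- group_edge_test(zeros)
  expect_equal(unique(Z0[upper.tri(Z0)]), 0)

  consts <- replicate(5, matrix(0.5, 4, 4), simplify = FALSE)
  Zc <- group_edge_test(consts)
  expect_true(all(Zc[upper.tri(Zc)] > 2.3)) # epsilon-guarded constant edges

  expect_error(group_edge_test(zeros[1:2]), "at least 3")
})

test_that("thresholded degrees satisfy the handshake identity (oracle check)", {
  # K4: every |Z| above cutoff -> complete graph, all degrees 3
  k4 <- matrix(3, 4, 4)
  diag(k4) <- NA
  net4 <- threshold_network(k4, cutoff = 2.3)
  expect_identical(unname(net4$degrees), rep(3L, 4))

  sub <- matrix(0.5, 4, 4)
  diag(sub) <- NA
  expect_identical(unname(threshold_network(sub)$degrees), rep(0L, 4))

  set.seed(6)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    m <- matrix(rnorm(n * n, sd = 2), n)
    m <- (m + t(m)) / 2
    diag(m) <- NA
    net <- threshold_network(m, cutoff = 2.3)
    # brute-force row sums of the adjacency
    A <- matrix(0L, n, n)
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a != b && !is.na(m[a, b]) && abs(m[a, b]) >= 2.3) A[a, b] <- 1L
      }
    }
    expect_identical(unname(net$degrees), as.integer(rowSums(A)))
    expect_identical(sum(net$degrees), 2L * as.integer(sum(A) / 2))
  }
})

test_that("k-NN clustering separates planted modules", {
  # two perfectly separated blocks
  blockZ <- matrix(-1, 8, 8)
  blockZ[1:4, 1:4] <- 5
  blockZ[5:8, 5:8] <- 5
  diag(blockZ) <- NA
  lab <- knn_cluster(blockZ, k = 2)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(length(unique(lab[1:4])), 1L)
  expect_identical(length(unique(lab[5:8])), 1L)

  # identical rows: one cluster
  same <- matrix(1, 6, 6)
  diag(same) <- NA
  expect_identical(unique(knn_cluster(same, k = 2)), 1L)
  expect_error(knn_cluster(same, k = 6), "smaller")

  # planted 3-module covariance recovered through the full edge pipeline
  modules <- list(1:8, 9:16, 17:24)
  sig <- block_covariance(24, modules, within_r = 0.6, between_r = 0)
  cfg <- resting_sim_config(n_timepoints = 150, node_covariance = sig)
  subjects <- lapply(1:6, function(s) {
    zz <- with(list(), {
      set.seed(300 + s)
      ed <- eigen(sig, symmetric = TRUE)
      L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)))
      series <- matrix(rnorm(150 * 24), 150) %*% t(L)
      colnames(series) <- 1:24
      pairwise_correlation(series)
    })
    zz
  })
  Z <- group_edge_test(subjects)
  lab3 <- knn_cluster(Z, k = 4)
  truth <- rep(1:3, each = 8)
  expect_gt(adjusted_rand(lab3, truth), 0.8)
})

test_that("subregion degree comparison gates on normality and finds planted loss", {
  set.seed(8)
  n <- 24
  m <- matrix(rnorm(n * n, sd = 2), n)
  m <- (m + t(m)) / 2
  diag(m) <- NA
  net_a <- threshold_network(m, cutoff = 1.5)
  submap <- tibble::tibble(
    region_id = 1:24,
    subregion = rep(c("sensorimotor", "thalamus", "prefrontal", "basal_ganglia"),
      each = 6
    )
  )

  # identical networks: all differences zero, p = 1
  same <- compare_degrees(net_a, net_a, submap)
  expect_true(all(same$p_value == 1))
  expect_true(all(same$direction == "="))
  expect_identical(nrow(same), 4L)

  # remove every suprathreshold edge inside one subregion in condition B
  m_b <- m
  m_b[1:6, 1:6] <- 0
  net_b <- threshold_network(m_b, cutoff = 1.5)
  res <- compare_degrees(net_a, net_b, submap)
  row <- res[res$subregion == "sensorimotor", ]
  expect_identical(row$direction, ">")
  expect_lt(row$p_value, 0.05)

  # undersized subregions are skipped with a warning
  tiny <- tibble::tibble(region_id = 1:2, subregion = "tiny")
  expect_warning(out <- compare_degrees(net_a, net_a, tiny), "fewer than 3")
  expect_identical(nrow(out), 0L)
})

test_that("network tidiers and degree table agree with the adjacency", {
  set.seed(4)
  m <- matrix(rnorm(36, sd = 2), 6)
  m <- (m + t(m)) / 2
  diag(m) <- NA
  net <- threshold_network(m, cutoff = 2)
  td <- tidy(net)
  expect_identical(nrow(td), 15L)
  expect_identical(sum(td$suprathreshold), as.integer(sum(net$adjacency) / 2))
  gl <- glance(net)
  expect_equal(gl$n_edges, sum(net$adjacency) / 2)
  expect_identical(degree_table(net)$degree, unname(net$degrees))
})
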