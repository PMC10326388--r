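# Resting-state functional connectivity: region time series, pairwise
# Pearson correlations with Fisher-Z transform, group edge statistics,
# thresholded undirected graphs with degree centrality, k-NN clustering of
# connectivity profiles, and subregion degree comparisons.

#' Region-averaged time series
#'
#' Averages the scan over each atlas region's voxels at every timepoint.
#' Regions with no voxel support are dropped with a warning and recorded in
#' the `dropped_regions` attribute.
#'
#' @param scan A [bold_scan()] registered to atlas space.
#' @param atlas An [atlas_volume()].
#' @return t x n matrix of node time courses, columns named by region id;
#'   attribute `region_ids` holds the retained node set.
#' @export
region_timeseries <- function(scan, atlas) {
  if (!identical(dim(scan$data)[1:3], dim(atlas$labels))) {
    abort("scan and atlas dimensions differ; register the scan first.")
  }
  nt <- n_acquisitions(scan)
  lab <- as.vector(atlas$labels)
  inb <- lab > 0
  m <- matrix(scan$data, ncol = nt)[inb, , drop = FALSE]
  sums <- rowsum(m, lab[inb]) # region x t
  counts <- tabulate(lab[inb], nbins = max(atlas$region_names$region_id))
  ids <- as.integer(rownames(sums))
  series <- t(sums / counts[ids])
  colnames(series) <- ids
  missing <- setdiff(atlas$region_names$region_id, ids)
  if (length(missing) == length(atlas$region_names$region_id)) {
    abort("all regions are empty.")
  }
  if (length(missing)) {
    warn(paste0(
      "dropping ", length(missing), " region(s) with no voxel support: ",
      paste(head(missing, 10), collapse = ", ")
    ))
  }
  attr(series, "region_ids") <- ids
  attr(series, "dropped_regions") <- missing
  series
}

#' Fisher Z transform and its inverse
#'
#' `fisher_z(r) = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the
#' variance-stabilising transform of Pearson correlations. `|r| = 1` maps to
#' `+/-Inf` with a warning so such edges can be excluded downstream.
#'
#' @param r Correlations in `[-1, 1]`.
#' @param z Fisher-Z values.
#' @return Transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("correlations must lie in [-1, 1].")
  if (any(abs(r) == 1, na.rm = TRUE)) {
    warn("|r| = 1 maps to infinite Z; such edges should be excluded.")
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Pairwise Pearson correlations between node series
#'
#' Computes all `n (n - 1) / 2` unordered node pairs and the Fisher-Z
#' transform of each. Zero-variance nodes yield `NA` edges, which are
#' excluded downstream.
#'
#' @param node_series t x n matrix ([region_timeseries()]).
#' @return Object of class `edge_stats`: `r` and `z` (n x n symmetric
#'   matrices, `NA` diagonal), `nodes` (region ids), `n_timepoints`.
#' @export
pairwise_correlation <- function(node_series) {
  if (nrow(node_series) < 4) abort("need at least 4 timepoints.")
  if (ncol(node_series) < 2) abort("need at least 2 nodes.")
  zero_var <- apply(node_series, 2, sd) == 0
  r <- suppressWarnings(cor(node_series))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r) <- NA_real_
  z <- suppressWarnings(atanh(r))
  nodes <- colnames(node_series) %||% as.character(seq_len(ncol(node_series)))
  structure(
    list(
      r = r, z = z, nodes = as.integer(nodes),
      n_timepoints = nrow(node_series)
    ),
    class = "edge_stats"
  )
}

#' Group-level edge statistics
#'
#' One-sample t-test of the subjects' Fisher-Z values against zero at every
#' edge, converted to a signed standard-normal-scale Z through the t
#' cumulative distribution (`Z = qnorm(pt(t, df))`, so under the null Z is
#' standard normal regardless of the group size).
#'
#' @param z_matrices List of per-subject n x n Fisher-Z matrices (or
#'   `edge_stats` objects), at least 3 subjects.
#' @param z_max Clamp for infinite Z (default `qnorm(1 - 1e-15)`).
#' @return n x n symmetric group Z-score matrix, `NA` diagonal.
#' @export
group_edge_test <- function(z_matrices, z_max = qnorm(1 - 1e-15)) {
  z_matrices <- lapply(z_matrices, function(m) {
    if (inherits(m, "edge_stats")) m$z else m
  })
  s <- length(z_matrices)
  if (s < 3) abort("need at least 3 subjects for the one-group t-test.")
  dims <- unique(lapply(z_matrices, dim))
  if (length(dims) != 1) abort("all subjects must share the node set.")
  sum1 <- Reduce(`+`, z_matrices)
  sum2 <- Reduce(`+`, lapply(z_matrices, function(m) m^2))
  mu <- sum1 / s
  sdv <- sqrt(pmax(sum2 - s * mu^2, 0) / (s - 1))
  sdv <- pmax(sdv, 1e-12) # epsilon guard: constant edges get a huge, finite t
  tstat <- mu / (sdv / sqrt(s))
  Z <- qnorm(pt(tstat, df = s - 1))
  Z <- pmin(pmax(Z, -z_max), z_max)
  Z[is.na(mu)] <- NA_real_
  diag(Z) <- NA_real_
  Z
}

#' Threshold a Z matrix into an undirected network
#'
#' Builds the binary adjacency `A[i, j] = 1` iff `|Z[i, j]| >= cutoff`
#' (`i != j`; `NA` edges never connect) and the per-node degree centrality
#' `C_D(j) = sum_i A[i, j]`, so the degree total equals twice the edge
#' count.
#'
#' @param z_score_matrix Symmetric n x n matrix (group Z or per-subject z).
#' @param cutoff |Z| threshold (default 2.3).
#' @param nodes Optional node ids (default from dimnames or 1..n).
#' @return Object of class `connectivity_network`: `nodes`, `weights`,
#'   `threshold`, `adjacency`, `degrees`.
#' @export
threshold_network <- function(z_score_matrix, cutoff = 2.3, nodes = NULL) {
  m <- as.matrix(z_score_matrix)
  if (nrow(m) != ncol(m)) abort("matrix must be square.")
  if (!isSymmetric(unname(ifelse(is.na(m), 0, m)), tol = 1e-8)) {
    abort("matrix must be symmetric.")
  }
  A <- (abs(m) >= cutoff) * 1L
  A[is.na(m)] <- 0L
  diag(A) <- 0L
  nodes <- nodes %||% as.integer(rownames(m) %||% seq_len(nrow(m)))
  deg <- as.integer(rowSums(A))
  structure(
    list(
      nodes = nodes, weights = m, threshold = cutoff, adjacency = A,
      degrees = setNames(deg, nodes)
    ),
    class = "connectivity_network"
  )
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat(
    "<connectivity_network> ", length(x$nodes), " nodes, ",
    sum(x$adjacency) / 2, " edges at |Z| >= ", x$threshold,
    ", mean degree ", round(mean(x$degrees), 2), "\n",
    sep = ""
  )
  invisible(x)
}

#' Cluster nodes by their connectivity profiles (k-NN graph)
#'
#' Treats each row of the Z matrix as the node's connectivity profile,
#' measures correlation distance `1 - cor(profile_i, profile_j)`, connects
#' every node to its `k` nearest neighbours, and returns the connected
#' components of the resulting undirected graph as cluster labels —
#' an unsupervised reading of "k-nearest-neighbours clustering" that is
#' deterministic given its input. A spectral alternative on the same k-NN
#' graph is available via `method = "spectral"` (requires `n_clusters`).
#'
#' @param z_score_matrix Symmetric n x n matrix; diagonal ignored.
#' @param k Neighbours per node, `1 <= k < n` (default 5).
#' @param method `"components"` (default) or `"spectral"`.
#' @param n_clusters Number of clusters for the spectral method.
#' @return Integer cluster labels (length n), numbered by decreasing
#'   cluster size.
#' @export
knn_cluster <- function(z_score_matrix, k = 5, method = c("components", "spectral"),
                        n_clusters = NULL) {
  method <- match.arg(method)
  m <- as.matrix(z_score_matrix)
  n <- nrow(m)
  if (k >= n) abort("`k` must be smaller than the number of nodes.")
  if (k < 1) abort("`k` must be >= 1.")
  prof <- m
  diag(prof) <- 0
  prof[is.na(prof)] <- 0
  cc <- suppressWarnings(cor(t(prof)))
  cc[is.na(cc)] <- -1 # zero-variance profiles: maximally distant
  d <- 1 - cc
  diag(d) <- Inf
  nb <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (method == "components") {
    lab <- igraph::components(g)$membership
  } else {
    if (is.null(n_clusters)) abort("spectral method needs `n_clusters`.")
    L <- igraph::laplacian_matrix(g, normalization = "symmetric")
    ev <- eigen(as.matrix(L), symmetric = TRUE)
    U <- ev$vectors[, n - seq_len(n_clusters) + 1, drop = FALSE]
    U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
    lab <- with_preserved_seed(1L, stats::kmeans(U, n_clusters, nstart = 10)$cluster)
  }
  # renumber by decreasing size for stable output
  sizes <- sort(table(lab), decreasing = TRUE)
  as.integer(setNames(seq_along(sizes), names(sizes))[as.character(lab)])
}

#' Compare degree centrality between two conditions by subregion
#'
#' For every named subregion, pairs the two networks' node degrees region by
#' region, tests the paired differences for normality (Shapiro-Wilk at
#' alpha 0.05), and applies a paired t-test when normality is tenable or a
#' Wilcoxon signed-rank test otherwise. Subregions with fewer than 3 member
#' regions are skipped with a warning. Identical conditions (all differences
#' zero) report `p = 1`.
#'
#' Note the pairing unit: the two conditions come from different animal
#' groups, so the paired design pairs by region (each region's degree under
#' condition A vs condition B), not by subject.
#'
#' @param network_a,network_b `connectivity_network`s sharing a node set.
#' @param subregion_map Tibble/data frame with columns `region_id`,
#'   `subregion`.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return Tibble: `subregion`, `n_regions`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `shapiro_p`, `method`, `statistic`, `p_value`, `direction`.
#' @export
compare_degrees <- function(network_a, network_b, subregion_map,
                            alpha_normality = 0.05) {
  if (!identical(network_a$nodes, network_b$nodes)) {
    abort("networks must share the same node set.")
  }
  subregion_map <- as_tibble(subregion_map)
  stopifnot(all(c("region_id", "subregion") %in% names(subregion_map)))
  da <- network_a$degrees
  db <- network_b$degrees
  purrr::map_dfr(split(subregion_map, subregion_map$subregion), function(sm) {
    ids <- as.character(intersect(sm$region_id, network_a$nodes))
    if (length(ids) < 3) {
      warn(paste0(
        "subregion '", sm$subregion[1], "' has fewer than 3 regions; skipped."
      ))
      return(tibble())
    }
    x <- as.numeric(da[ids])
    y <- as.numeric(db[ids])
    diffs <- x - y
    if (all(diffs == 0)) {
      sw_p <- NA_real_
      method <- "degenerate"
      stat <- 0
      p <- 1
    } else {
      sw_p <- if (length(unique(diffs)) > 1) shapiro.test(diffs)$p.value else 0
      if (!is.na(sw_p) && sw_p > alpha_normality) {
        ht <- t.test(x, y, paired = TRUE)
        method <- "paired t"
      } else {
        ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
        method <- "wilcoxon signed-rank"
      }
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
    tibble(
      subregion = sm$subregion[1], n_regions = length(ids),
      mean_a = mean(x), sd_a = sd(x), mean_b = mean(y), sd_b = sd(y),
      shapiro_p = sw_p, method = method, statistic = stat, p_value = p,
      direction = if (mean(x) > mean(y)) ">" else if (mean(x) < mean(y)) "<" else "="
    )
  })
}
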