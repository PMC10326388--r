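# broom-style tidiers for the result objects.

#' Tidy an activation map into per-region summaries
#'
#' @param x An `activation_map`.
#' @param atlas The [atlas_volume()] the map lives in.
#' @param ... Unused.
#' @return Tibble: `region_id`, `region_name`, `n_voxels`,
#'   `n_positive`, `n_negative`, `median_percent_change`.
#' @method tidy activation_map
#' @export
tidy.activation_map <- function(x, atlas, ...) {
  lab <- atlas$labels
  purrr::map_dfr(seq_len(nrow(atlas$region_names)), function(i) {
    id <- atlas$region_names$region_id[i]
    sel <- lab == id
    sig <- x$significance[sel]
    tibble(
      region_id = id,
      region_name = atlas$region_names$region_name[i],
      n_voxels = sum(sel),
      n_positive = sum(sig == 1L, na.rm = TRUE),
      n_negative = sum(sig == -1L, na.rm = TRUE),
      median_percent_change = median(x$percent[sel], na.rm = TRUE)
    )
  })
}

#' One-row summary of an activation map
#' @param x An `activation_map`.
#' @param ... Unused.
#' @return Tibble: `subject_id`, `n_tested`, `n_positive`, `n_negative`,
#'   `significant_fraction`.
#' @method glance activation_map
#' @export
glance.activation_map <- function(x, ...) {
  n_tested <- sum(!is.na(x$significance))
  np <- sum(x$significance == 1L, na.rm = TRUE)
  nn <- sum(x$significance == -1L, na.rm = TRUE)
  tibble(
    subject_id = x$subject_id, n_tested = n_tested,
    n_positive = np, n_negative = nn,
    significant_fraction = (np + nn) / n_tested
  )
}

#' Tidy a connectivity network into an edge list
#'
#' @param x A `connectivity_network`.
#' @param ... Unused.
#' @return Tibble of unordered node pairs: `node_a`, `node_b`, `weight`
#'   (Z), `suprathreshold`.
#' @method tidy connectivity_network
#' @export
tidy.connectivity_network <- function(x, ...) {
  n <- length(x$nodes)
  ij <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble(
    node_a = x$nodes[ij[, 1]],
    node_b = x$nodes[ij[, 2]],
    weight = x$weights[ij],
    suprathreshold = x$adjacency[ij] == 1L
  )
}

#' One-row summary of a connectivity network
#' @param x A `connectivity_network`.
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `n_edges`, `threshold`, `mean_degree`,
#'   `max_degree`.
#' @method glance connectivity_network
#' @export
glance.connectivity_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    n_edges = sum(x$adjacency) / 2,
    threshold = x$threshold,
    mean_degree = mean(x$degrees),
    max_degree = max(x$degrees)
  )
}

#' Degree-centrality table of a network
#' @param network A `connectivity_network`.
#' @return Tibble: `region_id`, `degree`.
#' @export
degree_table <- function(network) {
  tibble(region_id = network$nodes, degree = as.integer(network$degrees))
}
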