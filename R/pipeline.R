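# The two studies end to end: drug-challenge activation (per-subject maps ->
# composites -> region VOA -> dose-response tables) and resting-state
# connectivity (preprocess -> node series -> edges -> group networks ->
# degree comparison). Each has an in-memory analysis function and a
# disk-based runner that reads/writes the standard formats.

log_stage <- function(stage, subject, t0, quiet = FALSE) {
  if (!quiet) {
    message(sprintf(
      "[%s] %s subject=%s elapsed=%.2fs",
      format(Sys.time(), "%H:%M:%S"), stage, subject,
      as.numeric(Sys.time()) - t0
    ))
  }
}

#' Run the activation analysis on an in-memory study
#'
#' Per subject: percent change, voxelwise Welch t, significance mask; then
#' the per-dose composite maps, the per-region positive/negative volume of
#' activation, the Kruskal-Wallis dose-response table and the
#' vehicle-vs-dose rank-sum post-hoc table.
#'
#' @param study Result of [simulate_phmri_study()] (or a list with
#'   `subjects`, each `list(scan = ...)`, and a `manifest` tibble with
#'   `subject_id`, `dose`).
#' @param atlas The [atlas_volume()] the scans live in.
#' @param config An [analysis_config()].
#' @param transforms Optional named list of subject->atlas
#'   `affine_transform`s (default identity: simulated data are already in
#'   atlas space).
#' @param posthoc_pair Character vector of two dose labels for the post-hoc
#'   contrast; default the first and the dose with the largest median VOA.
#' @param quiet Suppress per-stage log lines.
#' @return List: `maps` (per-subject `activation_map`s), `composites`
#'   (per-dose 3D arrays), `voa` (tibble region x subject counts),
#'   `kruskal` (dose-response table), `posthoc` (rank-sum table),
#'   `config_hash`.
#' @export
analyze_activation <- function(study, atlas, config = analysis_config(),
                               transforms = NULL, posthoc_pair = NULL,
                               quiet = TRUE) {
  t0 <- as.numeric(Sys.time())
  man <- study$manifest
  bw <- c(config$baseline_start, config$baseline_end)
  rw <- c(config$response_start, config$response_end)
  maps <- purrr::imap(study$subjects, function(sub, id) {
    m <- map_activation(sub$scan,
      baseline_window = bw, response_window = rw,
      q = config$fdr_q, c_V = config$c_V,
      magnitude_threshold_pct = config$magnitude_threshold_pct,
      gate = config$gate, atlas = atlas, per_region = config$per_region_fdr
    )
    log_stage("activation", id, t0, quiet)
    m
  })
  doses <- man$dose
  composites <- purrr::map(split(seq_along(maps), doses), function(ix) {
    composite_map(maps[ix],
      transforms = if (is.null(transforms)) NULL else transforms[ix],
      atlas = atlas
    )
  })
  voa <- purrr::imap_dfr(maps, function(m, id) {
    dplyr::bind_rows(
      dplyr::mutate(region_voa(m, atlas, "positive"),
        sign = "positive", subject_id = id
      ),
      dplyr::mutate(region_voa(m, atlas, "negative"),
        sign = "negative", subject_id = id
      )
    )
  })
  voa <- dplyr::left_join(voa, man[, c("subject_id", "dose")], by = "subject_id")
  pos <- dplyr::filter(voa, .data$sign == "positive")
  kw <- kruskal_wallis_by_region(pos, value = "n_voxels", group = "dose")
  if (is.null(posthoc_pair)) {
    lvls <- unique(doses)
    meds <- vapply(
      lvls,
      function(g) median(pos$n_voxels[pos$dose == g]), 0
    )
    posthoc_pair <- c(lvls[1], lvls[which.max(meds + seq_along(lvls) * 1e-9)])
  }
  ph <- wilcoxon_posthoc(pos,
    group_a = posthoc_pair[1], group_b = posthoc_pair[2],
    value = "n_voxels", group = "dose"
  )
  list(
    maps = maps, composites = composites, voa = voa, kruskal = kw,
    posthoc = ph, posthoc_pair = posthoc_pair,
    config_hash = config_hash(config)
  )
}

#' Preprocess one resting-state scan for connectivity
#'
#' The resting chain in order: motion-outlier detection, band-pass filtering
#' (0.01--0.1 Hz), detrending, spatial smoothing (FWHM 0.8 mm), nuisance
#' regression (motion outliers, six motion parameters, mean white matter and
#' CSF).
#'
#' @param scan A [bold_scan()].
#' @param config An [analysis_config()].
#' @param voxel_size mm per axis for smoothing.
#' @return The preprocessed [bold_scan()].
#' @export
preprocess_resting <- function(scan, config = analysis_config(),
                               voxel_size = c(1, 1, 1)) {
  scan <- detect_motion_outliers(scan, threshold = config$motion_z_threshold)
  if (config$slice_timing) scan <- slice_timing_correct(scan)
  Y <- flatten_scan(scan) # voxel x t
  Yf <- t(bandpass_filter(t(Y), scan$tr_seconds,
    low_hz = config$bandpass_low_hz, high_hz = config$bandpass_high_hz
  ))
  Yf <- t(detrend(t(Yf)))
  scan$data <- unflatten_scan(Yf, scan)
  if (config$smooth_fwhm_mm > 0) {
    scan$data <- gaussian_smooth(scan$data, config$smooth_fwhm_mm, voxel_size)
  }
  nuisance_regress(scan)
}

#' Run the resting-state connectivity analysis on in-memory groups
#'
#' Per subject: [preprocess_resting()], [region_timeseries()],
#' [pairwise_correlation()]. Per group: [group_edge_test()] and
#' [threshold_network()] at the configured |Z| cutoff. If a subregion map is
#' given the two groups' degree centralities are compared per subregion.
#'
#' @param groups Named list (one element per group) of lists of
#'   [bold_scan()]s.
#' @param atlas The [atlas_volume()].
#' @param config An [analysis_config()].
#' @param subregion_map Optional tibble `region_id`, `subregion` for
#'   [compare_degrees()] between the first two groups.
#' @param preprocess Apply [preprocess_resting()] (default `TRUE`; set
#'   `FALSE` when the scans are already residual images).
#' @param quiet Suppress log lines.
#' @return List: `edges` (per group, per subject `edge_stats`),
#'   `group_z` (per group n x n Z matrix), `networks` (per group
#'   `connectivity_network`), `clusters` (per group k-NN cluster labels),
#'   `degree_comparison` (tibble or `NULL`), `config_hash`.
#' @export
analyze_connectivity <- function(groups, atlas, config = analysis_config(),
                                 subregion_map = NULL, preprocess = TRUE,
                                 quiet = TRUE) {
  t0 <- as.numeric(Sys.time())
  if (any(lengths(groups) < 3)) {
    abort("every group needs at least 3 subjects for the one-group t-test.")
  }
  per_group <- purrr::imap(groups, function(scans, gname) {
    edges <- purrr::map(scans, function(scan) {
      if (preprocess) {
        scan <- preprocess_resting(scan, config, voxel_size = atlas$voxel_size)
      }
      ts <- region_timeseries(scan, atlas)
      log_stage("connectivity", scan$subject_id, t0, quiet)
      pairwise_correlation(ts)
    })
    Z <- group_edge_test(edges)
    nodes <- edges[[1]]$nodes
    net <- threshold_network(Z, cutoff = config$z_cutoff, nodes = nodes)
    clusters <- knn_cluster(Z, k = config$knn_k)
    list(edges = edges, group_z = Z, network = net, clusters = clusters)
  })
  comp <- NULL
  if (!is.null(subregion_map) && length(per_group) >= 2) {
    comp <- compare_degrees(
      per_group[[1]]$network, per_group[[2]]$network, subregion_map
    )
  }
  list(
    edges = purrr::map(per_group, "edges"),
    group_z = purrr::map(per_group, "group_z"),
    networks = purrr::map(per_group, "network"),
    clusters = purrr::map(per_group, "clusters"),
    degree_comparison = comp,
    config_hash = config_hash(config)
  )
}

# ---- disk-based runners ----------------------------------------------------

#' Simulate a study to disk
#'
#' Writes the atlas, every subject's scan (NIfTI + nuisance TSV), the
#' ground-truth amplitude maps (NIfTI mask + CSV), the config, and a
#' manifest CSV (`subject_id`, `dose`, `seed`, paths).
#'
#' @param out_dir Writable output directory (created if needed).
#' @param atlas An [atlas_volume()] (e.g. from [generate_atlas()]).
#' @param cfg A [phmri_sim_config()].
#' @param seed Master seed.
#' @param config An [analysis_config()] stored alongside the data.
#' @return The manifest tibble (invisibly also written to
#'   `<out_dir>/manifest.csv`).
#' @export
simulate_study_files <- function(out_dir, atlas, cfg, seed = 1L,
                                 config = analysis_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(
    atlas, file.path(out_dir, "atlas.nii.gz"),
    file.path(out_dir, "atlas_regions.csv")
  )
  write_analysis_config(config, file.path(out_dir, "analysis_config.txt"))
  study <- simulate_phmri_study(atlas, cfg, seed = seed)
  man <- study$manifest
  man$scan_prefix <- file.path(out_dir, man$subject_id)
  purrr::pwalk(
    list(study$subjects, man$scan_prefix, man$subject_id),
    function(sub, prefix, id) {
      write_bold_scan(sub$scan, prefix)
      RNifti::writeNifti(
        RNifti::asNifti(sub$truth$amplitude_map),
        paste0(prefix, "_truth.nii.gz")
      )
    }
  )
  truth_csv <- tibble(
    region_id = cfg$active_regions,
    amplitude = purrr::map_dbl(
      cfg$active_regions,
      function(r) max(cfg$amplitude_by_dose)
    )
  )
  readr::write_csv(truth_csv, file.path(out_dir, "ground_truth_regions.csv"))
  readr::write_csv(man, file.path(out_dir, "manifest.csv"))
  man
}

#' Run the activation study from a simulated-study directory
#'
#' Reads the manifest, atlas and config written by [simulate_study_files()],
#' runs [analyze_activation()], and writes the dose-response and post-hoc
#' tables as CSV, the per-dose composite maps as NIfTI, and a provenance
#' file carrying the config hash.
#'
#' @param study_dir Directory produced by [simulate_study_files()].
#' @param out_dir Output directory.
#' @param quiet Suppress log lines.
#' @return The [analyze_activation()] result, invisibly.
#' @export
run_activation_study <- function(study_dir, out_dir = study_dir, quiet = FALSE) {
  man <- readr::read_csv(file.path(study_dir, "manifest.csv"),
    show_col_types = FALSE
  )
  missing <- man$scan_prefix[!file.exists(paste0(man$scan_prefix, ".nii.gz"))]
  if (length(missing)) {
    abort(paste0("missing scan files for: ", paste(basename(missing), collapse = ", ")))
  }
  atlas <- read_atlas(
    file.path(study_dir, "atlas.nii.gz"),
    file.path(study_dir, "atlas_regions.csv")
  )
  config <- read_analysis_config(file.path(study_dir, "analysis_config.txt"))
  subjects <- purrr::map(seq_len(nrow(man)), function(i) {
    list(scan = read_bold_scan(man$scan_prefix[i], subject_id = man$subject_id[i]))
  })
  names(subjects) <- man$subject_id
  res <- analyze_activation(
    list(subjects = subjects, manifest = man), atlas, config,
    quiet = quiet
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$kruskal, file.path(out_dir, "dose_response.csv"))
  readr::write_csv(res$posthoc, file.path(out_dir, "posthoc.csv"))
  readr::write_csv(res$voa, file.path(out_dir, "region_voa.csv"))
  purrr::iwalk(res$composites, function(cm, dose) {
    cm[is.na(cm)] <- 0
    RNifti::writeNifti(
      RNifti::asNifti(cm),
      file.path(out_dir, paste0("composite_", dose, ".nii.gz"))
    )
  })
  writeLines(
    c(
      paste0("config_hash = ", res$config_hash),
      paste0("package_version = ", as.character(utils::packageVersion("phmri")))
    ),
    file.path(out_dir, "provenance.txt")
  )
  invisible(res)
}

#' Simulate a resting-state study to disk
#'
#' Writes the atlas and one resting scan per subject for each group, plus a
#' manifest CSV (`subject_id`, `group`, `seed`, scan prefix).
#'
#' @param out_dir Output directory.
#' @param atlas An [atlas_volume()].
#' @param cfg_by_group Named list of [resting_sim_config()]s, one per group
#'   (e.g. vehicle vs drug with a scaled covariance).
#' @param n_per_group Subjects per group (single number or named vector).
#' @param seed Master seed.
#' @return The manifest tibble.
#' @export
simulate_resting_study_files <- function(out_dir, atlas, cfg_by_group,
                                         n_per_group = 7L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(
    atlas, file.path(out_dir, "atlas.nii.gz"),
    file.path(out_dir, "atlas_regions.csv")
  )
  gnames <- names(cfg_by_group)
  if (length(n_per_group) == 1L) {
    n_per_group <- setNames(rep(n_per_group, length(gnames)), gnames)
  }
  design <- rep(gnames, times = n_per_group[gnames])
  sub_seeds <- with_preserved_seed(seed, sample.int(2^31 - 2, length(design)))
  ids <- paste0("rs", formatC(seq_along(design), width = 2, flag = "0"))
  man <- tibble(
    subject_id = ids, group = design, seed = sub_seeds,
    scan_prefix = file.path(out_dir, ids)
  )
  purrr::pwalk(man, function(subject_id, group, seed, scan_prefix) {
    sim <- simulate_resting_subject(atlas, cfg_by_group[[group]], seed,
      subject_id = subject_id
    )
    write_bold_scan(sim$scan, scan_prefix)
  })
  readr::write_csv(man, file.path(out_dir, "rs_manifest.csv"))
  man
}

#' Run the resting-state connectivity study from disk
#'
#' Reads the resting manifest and atlas written by
#' [simulate_resting_study_files()], runs [analyze_connectivity()], and
#' writes per-group Z matrices (CSV, header = region names), edge lists
#' (TSV), thresholded graphs (GraphML), degree tables (CSV), and the
#' subregion degree comparison.
#'
#' @param study_dir Directory with `rs_manifest.csv` and the atlas files.
#' @param out_dir Output directory.
#' @param config An [analysis_config()].
#' @param subregion_map Optional tibble `region_id`, `subregion`.
#' @param quiet Suppress log lines.
#' @return The [analyze_connectivity()] result, invisibly.
#' @export
run_connectivity_study <- function(study_dir, out_dir = study_dir,
                                   config = analysis_config(),
                                   subregion_map = NULL, quiet = FALSE) {
  man <- readr::read_csv(file.path(study_dir, "rs_manifest.csv"),
    show_col_types = FALSE
  )
  atlas <- read_atlas(
    file.path(study_dir, "atlas.nii.gz"),
    file.path(study_dir, "atlas_regions.csv")
  )
  groups <- lapply(split(man, man$group), function(g) {
    purrr::map2(
      g$scan_prefix, g$subject_id,
      function(p, id) read_bold_scan(p, subject_id = id)
    )
  })
  if (any(lengths(groups) < 3)) {
    abort("every group needs at least 3 subjects for the one-group t-test.")
  }
  res <- analyze_connectivity(groups, atlas,
    config = config,
    subregion_map = subregion_map, quiet = quiet
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  name_of <- setNames(atlas$region_names$region_name, atlas$region_names$region_id)
  purrr::iwalk(res$networks, function(net, gname) {
    Z <- net$weights
    colnames(Z) <- rownames(Z) <- unname(name_of[as.character(net$nodes)])
    utils::write.csv(Z, file.path(out_dir, paste0("zmatrix_", gname, ".csv")))
    readr::write_tsv(
      tidy(net), file.path(out_dir, paste0("edges_", gname, ".tsv"))
    )
    readr::write_csv(
      degree_table(net), file.path(out_dir, paste0("degrees_", gname, ".csv"))
    )
    g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
    igraph::write_graph(
      g, file.path(out_dir, paste0("network_", gname, ".graphml")),
      format = "graphml"
    )
  })
  if (!is.null(res$degree_comparison)) {
    readr::write_csv(
      res$degree_comparison, file.path(out_dir, "degree_comparison.csv")
    )
  }
  writeLines(
    c(
      paste0("config_hash = ", res$config_hash),
      paste0("z_cutoff = ", config$z_cutoff)
    ),
    file.path(out_dir, "connectivity_provenance.txt")
  )
  invisible(res)
}
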