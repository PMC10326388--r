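# File formats: NIfTI-1 volumes, TSV side-cars, plain-text transforms,
# the flat typed analysis config, and the study manifest.

#' Write / read an atlas (NIfTI labels + region-name CSV)
#'
#' @param atlas An [atlas_volume()].
#' @param nifti_path Label image path (`.nii` / `.nii.gz`).
#' @param csv_path Region lookup table path.
#' @return `write_atlas` returns the paths invisibly; `read_atlas` an
#'   `atlas_volume`.
#' @export
write_atlas <- function(atlas, nifti_path, csv_path) {
  img <- RNifti::asNifti(atlas$labels * 1.0, pixdim = atlas$voxel_size)
  RNifti::writeNifti(img, nifti_path)
  readr::write_csv(
    atlas$region_names[, c("region_id", "region_name")], csv_path
  )
  invisible(c(nifti_path, csv_path))
}

#' @rdname write_atlas
#' @export
read_atlas <- function(nifti_path, csv_path) {
  img <- RNifti::readNifti(nifti_path)
  vs <- RNifti::pixdim(img)[1:3]
  labels <- array(as.integer(round(img)), dim = dim(img))
  names <- readr::read_csv(csv_path, show_col_types = FALSE)
  atlas_volume(labels, voxel_size = vs, region_names = names)
}

#' Write / read a BOLD scan with its side-cars
#'
#' The 4D data and the mask go to NIfTI; motion parameters, outlier flags
#' and tissue means go to a TSV with one row per acquisition.
#'
#' @param scan A [bold_scan()].
#' @param prefix Path prefix; files `<prefix>.nii.gz`,
#'   `<prefix>_mask.nii.gz`, `<prefix>_nuisance.tsv` are written.
#' @return `write_bold_scan` the prefix invisibly; `read_bold_scan` the
#'   scan.
#' @export
write_bold_scan <- function(scan, prefix) {
  vs <- rep(1, 3)
  RNifti::writeNifti(
    RNifti::asNifti(scan$data, pixdim = c(vs, scan$tr_seconds)),
    paste0(prefix, ".nii.gz")
  )
  RNifti::writeNifti(
    RNifti::asNifti(scan$mask * 1.0), paste0(prefix, "_mask.nii.gz")
  )
  nt <- n_acquisitions(scan)
  nuis <- tibble(
    acquisition = seq_len(nt),
    outlier = as.integer(scan$outlier_flags)
  )
  mp <- scan$motion_params %||% matrix(0, nt, 6)
  colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  nuis <- dplyr::bind_cols(nuis, as_tibble(mp))
  nuis$white_matter <- scan$tissue_means$white_matter %||% rep(NA_real_, nt)
  nuis$csf <- scan$tissue_means$csf %||% rep(NA_real_, nt)
  readr::write_tsv(nuis, paste0(prefix, "_nuisance.tsv"))
  invisible(prefix)
}

#' @rdname write_bold_scan
#' @param tr_seconds Repetition time; if `NULL`, taken from the NIfTI
#'   header.
#' @param subject_id Identifier for the scan record.
#' @export
read_bold_scan <- function(prefix, tr_seconds = NULL, subject_id = basename(prefix)) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  tr <- tr_seconds %||% RNifti::pixdim(img)[4]
  mask <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz")) > 0.5
  nuis <- readr::read_tsv(paste0(prefix, "_nuisance.tsv"), show_col_types = FALSE)
  tissue <- NULL
  if (!all(is.na(nuis$white_matter))) {
    tissue <- list(white_matter = nuis$white_matter, csf = nuis$csf)
  }
  bold_scan(
    array(as.numeric(img), dim = dim(img)),
    tr_seconds = tr, mask = array(mask, dim = dim(img)[1:3]),
    motion_params = as.matrix(nuis[, c("tx", "ty", "tz", "rx", "ry", "rz")]),
    outlier_flags = nuis$outlier > 0, tissue_means = tissue,
    subject_id = subject_id
  )
}

# ---- flat typed analysis config -------------------------------------------

config_schema <- function() {
  list(
    schema_version = "integer",
    baseline_start = "integer", baseline_end = "integer",
    response_start = "integer", response_end = "integer",
    fdr_q = "numeric", c_V = "numeric",
    magnitude_threshold_pct = "numeric", gate = "character",
    per_region_fdr = "logical",
    z_cutoff = "numeric", knn_k = "integer",
    slice_timing = "logical", threshold_before_degree = "logical",
    smooth_fwhm_mm = "numeric",
    bandpass_low_hz = "numeric", bandpass_high_hz = "numeric",
    motion_z_threshold = "numeric",
    seed = "integer"
  )
}

#' Analysis configuration
#'
#' Every tunable of the two pipelines in one flat, typed record. Defaults
#' are the published analysis settings: windows 5--45 / 300--345, filter
#' `q = 0.2` with `c_V = 1`, 1% magnitude gate, |Z| cutoff 2.3, smoothing
#' FWHM 0.8 mm, band-pass 0.01--0.1 Hz.
#'
#' @param ... Named overrides of the defaults; unknown names are an error.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    schema_version = 1L,
    baseline_start = 5L, baseline_end = 45L,
    response_start = 300L, response_end = 345L,
    fdr_q = 0.2, c_V = 1,
    magnitude_threshold_pct = 1, gate = "magnitude",
    per_region_fdr = FALSE,
    z_cutoff = 2.3, knn_k = 5L,
    slice_timing = FALSE, threshold_before_degree = TRUE,
    smooth_fwhm_mm = 0.8,
    bandpass_low_hz = 0.01, bandpass_high_hz = 0.1,
    motion_z_threshold = 5,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "analysis_config")
}

#' Write / read the analysis config as flat `key = value` text
#'
#' Unknown keys in a file are an error (typos in thresholds are the main
#' operational risk); values are parsed against the typed schema.
#'
#' @param cfg An [analysis_config()].
#' @param path File path.
#' @return `write_analysis_config` the path invisibly;
#'   `read_analysis_config` the config.
#' @export
write_analysis_config <- function(cfg, path) {
  lines <- vapply(
    names(cfg),
    function(k) paste0(k, " = ", as.character(cfg[[k]])), ""
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  schema <- config_schema()
  unknown <- setdiff(keys, names(schema))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  over <- purrr::map2(keys, vals, function(k, v) {
    switch(schema[[k]],
      integer = as.integer(v),
      numeric = as.numeric(v),
      logical = as.logical(v),
      character = v
    )
  })
  names(over) <- keys
  do.call(analysis_config, over)
}

#' Stable hash of a config (provenance stamp for outputs)
#' @param cfg An [analysis_config()].
#' @return Character hash.
#' @export
config_hash <- function(cfg) rlang::hash(unclass(cfg))
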