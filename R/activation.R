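# Voxelwise percent-change activation mapping with the rank-based
# false-positive filter, composite maps, volume of activation and region
# time courses.

window_indices <- function(window, flags) {
  idx <- seq.int(window[1], window[2])
  idx[!flags[idx]]
}

#' Percent BOLD change between two acquisition windows
#'
#' Per voxel: `100 * (mean(response) - mean(baseline)) / mean(baseline)`,
#' with motion-flagged acquisitions excluded from both window means. The
#' default windows compare the late drug plateau (acquisitions 300--345) to
#' the pre-injection baseline (5--45). Voxels whose baseline mean is not
#' positive are returned as `NA` (percent change undefined).
#'
#' @param scan A [bold_scan()].
#' @param baseline_window,response_window Inclusive 1-based acquisition
#'   ranges; must be disjoint and leave at least 3 unflagged acquisitions
#'   each.
#' @return 3D array of percent change (`NA` outside the mask).
#' @export
percent_change <- function(scan, baseline_window = c(5, 45),
                           response_window = c(300, 345)) {
  nt <- n_acquisitions(scan)
  if (max(baseline_window, response_window) > nt) {
    abort("analysis windows exceed the scan length.")
  }
  if (length(intersect(
    seq.int(baseline_window[1], baseline_window[2]),
    seq.int(response_window[1], response_window[2])
  ))) {
    abort("baseline and response windows must be disjoint.")
  }
  ib <- window_indices(baseline_window, scan$outlier_flags)
  ir <- window_indices(response_window, scan$outlier_flags)
  if (length(ib) < 3 || length(ir) < 3) {
    abort("each window needs at least 3 unflagged acquisitions.")
  }
  Y <- flatten_scan(scan)
  mb <- rowMeans(Y[, ib, drop = FALSE])
  mr <- rowMeans(Y[, ir, drop = FALSE])
  pc <- ifelse(mb > 0, 100 * (mr - mb) / mb, NA_real_)
  out <- array(NA_real_, dim = dim(scan$data)[1:3])
  out[scan$mask] <- pc
  out
}

# vectorised Welch t: rows are voxels, a/b are column index sets
.welch_rows <- function(Y, ia, ib) {
  na <- length(ia); nb <- length(ib)
  A <- Y[, ia, drop = FALSE]; B <- Y[, ib, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- (rowSums(A^2) - na * ma^2) / (na - 1)
  vb <- (rowSums(B^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate voxels: no variance anywhere
  zero <- se2 == 0
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  list(t = tstat, df = df, p = p)
}

#' Voxelwise Welch t-test between two windows
#'
#' Independent two-sample t-test with unequal (heteroscedastic) variances,
#' two-tailed, comparing the response-window acquisitions to the
#' baseline-window acquisitions voxel by voxel. Flagged acquisitions are
#' excluded. Voxels with zero variance in both windows get `p = 1` when the
#' means agree (nothing to detect) by convention.
#'
#' @inheritParams percent_change
#' @return 3D array of two-tailed p-values (`NA` outside the mask).
#' @export
voxel_ttest <- function(scan, baseline_window = c(5, 45),
                        response_window = c(300, 345)) {
  ib <- window_indices(baseline_window, scan$outlier_flags)
  ir <- window_indices(response_window, scan$outlier_flags)
  if (length(ib) < 3 || length(ir) < 3) {
    abort("each window needs at least 3 unflagged acquisitions.")
  }
  Y <- flatten_scan(scan)
  w <- .welch_rows(Y, ib, ir)
  out <- array(NA_real_, dim = dim(scan$data)[1:3])
  out[scan$mask] <- w$p
  out
}

#' Rank-based false-positive filter
#'
#' Step-up rule over the `V` tested p-values: sort ascending, find the
#' largest rank `i` with `P_(i) <= (i * q) / (V * c_V)`, and keep every
#' p-value of rank `<= i`. With `q = 0.2` and `c_V = 1` this is the filter
#' used to hold the average voxelwise false-positive detection rate below
#' 0.05 in window-contrast phMRI maps.
#'
#' @param p_values Numeric vector of probabilities in `[0, 1]` (`NA` allowed;
#'   `NA` entries are never kept and do not count toward `V`).
#' @param q False-positive filter value (default 0.2).
#' @param c_V Predetermined constant (default 1).
#' @return Logical keep-mask, same length as `p_values`.
#' @export
fdr_filter <- function(p_values, q = 0.2, c_V = 1) {
  if (q <= 0 || q > 1) abort("`q` must be in (0, 1].")
  if (c_V < 1) abort("`c_V` must be >= 1.")
  keep <- rep(FALSE, length(p_values))
  ok <- which(!is.na(p_values))
  V <- length(ok)
  if (V == 0) return(keep)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  o <- order(p)
  thr <- seq_len(V) * q / (V * c_V)
  hits <- which(p[o] <= thr)
  if (length(hits)) keep[ok[o[seq_len(max(hits))]]] <- TRUE
  keep
}

#' Signed significance mask
#'
#' A voxel is significant iff it survives the rank-based filter over the
#' tested voxel population AND passes the magnitude gate
#' `|percent change| >= magnitude_threshold_pct` (default 1%, guarding
#' against normal fluctuations of the awake-animal BOLD signal). The
#' alternative reading of the 1% figure — an additional `p <= 0.01` alpha
#' gate on the t-test, with no magnitude requirement — is available via
#' `gate = "alpha"`.
#'
#' @param percent_map 3D percent-change array ([percent_change()]).
#' @param p_map 3D p-value array ([voxel_ttest()]).
#' @param q,c_V Filter parameters, see [fdr_filter()].
#' @param magnitude_threshold_pct Minimum |percent change| (percent).
#' @param gate `"magnitude"` (default) or `"alpha"`.
#' @param atlas Optional [atlas_volume()]; when given with
#'   `per_region = TRUE` the rank filter runs within each region's voxel
#'   population (`V` = region size) instead of the whole brain.
#' @param per_region Apply the filter per region (default `FALSE`).
#' @return 3D integer array: `+1` significant positive, `-1` significant
#'   negative, `0` not significant, `NA` untested.
#' @export
significance_mask <- function(percent_map, p_map, q = 0.2, c_V = 1,
                              magnitude_threshold_pct = 1,
                              gate = c("magnitude", "alpha"),
                              atlas = NULL, per_region = FALSE) {
  gate <- match.arg(gate)
  if (!identical(dim(percent_map), dim(p_map))) {
    abort("`percent_map` and `p_map` must share dimensions.")
  }
  tested <- !is.na(p_map) & !is.na(percent_map)
  keep <- array(FALSE, dim = dim(p_map))
  if (per_region) {
    if (is.null(atlas)) abort("`per_region = TRUE` needs an atlas.")
    for (r in atlas$region_names$region_id) {
      sel <- tested & (atlas$labels == r)
      if (any(sel)) keep[sel] <- fdr_filter(p_map[sel], q, c_V)
    }
  } else {
    keep[tested] <- fdr_filter(p_map[tested], q, c_V)
  }
  if (gate == "magnitude") {
    keep <- keep & abs(percent_map) >= magnitude_threshold_pct
  } else {
    keep <- keep & p_map <= 0.01
  }
  out <- array(NA_integer_, dim = dim(p_map))
  out[tested] <- 0L
  out[which(keep & percent_map > 0)] <- 1L
  out[which(keep & percent_map < 0)] <- -1L
  out
}

#' Full per-subject activation map
#'
#' Runs [percent_change()], [voxel_ttest()] and [significance_mask()] on one
#' scan and bundles the results. In the zeroed map (used for composites),
#' significant voxels retain their percent-change values and all other
#' voxels are set to zero.
#'
#' @inheritParams percent_change
#' @inheritParams significance_mask
#' @return Object of class `activation_map`: `percent`, `p`, `significance`,
#'   `zeroed` (3D arrays), `subject_id`, and the parameters used.
#' @export
map_activation <- function(scan, baseline_window = c(5, 45),
                           response_window = c(300, 345), q = 0.2, c_V = 1,
                           magnitude_threshold_pct = 1,
                           gate = "magnitude",
                           atlas = NULL, per_region = FALSE) {
  pc <- percent_change(scan, baseline_window, response_window)
  p <- voxel_ttest(scan, baseline_window, response_window)
  sig <- significance_mask(pc, p,
    q = q, c_V = c_V,
    magnitude_threshold_pct = magnitude_threshold_pct, gate = gate,
    atlas = atlas, per_region = per_region
  )
  zeroed <- ifelse(!is.na(sig) & sig != 0L, pc, 0)
  zeroed[is.na(sig)] <- NA_real_
  structure(
    list(
      percent = pc, p = p, significance = sig, zeroed = zeroed,
      subject_id = scan$subject_id,
      params = list(
        baseline_window = baseline_window, response_window = response_window,
        q = q, c_V = c_V, magnitude_threshold_pct = magnitude_threshold_pct,
        gate = gate, per_region = per_region
      )
    ),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  n <- sum(!is.na(x$significance))
  cat(
    "<activation_map> ", x$subject_id, ": ", n, " tested voxels, ",
    sum(x$significance == 1L, na.rm = TRUE), " positive / ",
    sum(x$significance == -1L, na.rm = TRUE), " negative significant\n",
    sep = ""
  )
  invisible(x)
}

#' Composite (group-average) percent-change map in atlas space
#'
#' Each atlas voxel is inverse-mapped through every subject's transform and
#' takes the trilinear interpolation of that subject's zeroed map
#' (significant voxels keep their percent change, all others contribute 0).
#' The composite value is the mean over subjects; out-of-field (missing)
#' contributions are excluded from the mean rather than counted as zero.
#'
#' @param subject_maps List of `activation_map`s (or 3D arrays already
#'   zeroed).
#' @param transforms List of `affine_transform`s, one per subject, mapping
#'   subject world coordinates to atlas world coordinates. Defaults to
#'   identity for data simulated directly in atlas space.
#' @param atlas An [atlas_volume()] defining the target grid.
#' @param subject_voxel_size mm per axis of the subject grids.
#' @return 3D array (atlas grid) of mean percent change; `NA` where no
#'   subject contributed.
#' @export
composite_map <- function(subject_maps, transforms = NULL, atlas,
                          subject_voxel_size = atlas$voxel_size) {
  if (!length(subject_maps)) abort("no subjects.")
  if (is.null(transforms)) {
    transforms <- replicate(length(subject_maps), affine_transform(),
      simplify = FALSE
    )
  }
  if (length(transforms) != length(subject_maps)) {
    abort("need one transform per subject.")
  }
  tdim <- dim(atlas$labels)
  acc <- array(0, tdim)
  nuse <- array(0L, tdim)
  for (s in seq_along(subject_maps)) {
    m <- subject_maps[[s]]
    vol <- if (inherits(m, "activation_map")) m$zeroed else m
    vol0 <- ifelse(is.na(vol), 0, vol) # untested in-subject voxels contribute 0
    res <- resample_trilinear(vol0, transforms[[s]],
      target_dim = tdim,
      source_voxel_size = subject_voxel_size,
      target_voxel_size = atlas$voxel_size
    )
    ok <- !is.na(res)
    acc[ok] <- acc[ok] + res[ok]
    nuse[ok] <- nuse[ok] + 1L
  }
  out <- ifelse(nuse > 0, acc / pmax(nuse, 1L), NA_real_)
  array(out, tdim)
}

#' Volume of activation per region
#'
#' Counts, for every atlas region, the voxels carrying the requested sign in
#' a signed significance mask. The sum over regions equals the total
#' in-brain significant voxel count of that sign.
#'
#' @param mask 3D signed mask ([significance_mask()]) in atlas space, or an
#'   `activation_map`.
#' @param atlas An [atlas_volume()] with matching dimensions.
#' @param sign `"positive"` or `"negative"`.
#' @return Tibble `region_id`, `region_name`, `n_voxels`.
#' @export
region_voa <- function(mask, atlas, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (inherits(mask, "activation_map")) mask <- mask$significance
  if (!identical(dim(mask), dim(atlas$labels))) {
    abort("mask and atlas dimensions differ; is the mask in atlas space?")
  }
  want <- if (sign == "positive") 1L else -1L
  sel <- !is.na(mask) & mask == want & atlas$labels > 0
  counts <- tabulate(atlas$labels[sel], nbins = max(atlas$region_names$region_id))
  tibble(
    region_id = atlas$region_names$region_id,
    region_name = atlas$region_names$region_name,
    n_voxels = counts[atlas$region_names$region_id]
  )
}

#' Region-average percent-change time course
#'
#' Averages the scan over the voxels of the requested regions at every
#' acquisition and expresses the course as percent change relative to the
#' mean over the (unflagged) baseline window — the construction behind
#' drug-vs-vehicle time-course figures built from a composite of cortical
#' areas.
#'
#' @param scan A [bold_scan()] in atlas space.
#' @param atlas An [atlas_volume()].
#' @param region_ids Integer region ids to pool (must be nonempty in the
#'   atlas).
#' @param baseline_window Inclusive acquisition range for the reference mean.
#' @return Tibble `acquisition`, `percent_change`, `flagged`.
#' @export
time_course <- function(scan, atlas, region_ids, baseline_window = c(5, 45)) {
  if (!length(region_ids)) abort("empty region set.")
  sel <- atlas$labels %in% region_ids
  if (!any(sel)) abort("requested regions are empty in the atlas.")
  nt <- n_acquisitions(scan)
  m <- matrix(scan$data, ncol = nt)
  course <- colMeans(m[as.vector(sel), , drop = FALSE])
  ib <- window_indices(baseline_window, scan$outlier_flags)
  base <- mean(course[ib])
  if (base <= 0) abort("baseline mean is not positive.")
  tibble(
    acquisition = seq_len(nt),
    percent_change = 100 * (course - base) / base,
    flagged = scan$outlier_flags
  )
}

#' Percent-change contrasts between labelled epochs
#'
#' Summarises percent signal change per epoch relative to a named baseline
#' epoch, e.g. the 50-acquisition baseline / CO2 / post-CO2 design of a
#' hypercapnic-challenge scan.
#'
#' @param scan A [bold_scan()].
#' @param epochs Named list of inclusive acquisition ranges; must not
#'   overlap.
#' @param baseline Name of the reference epoch (default the first).
#' @param region_ids Optional region ids to restrict the spatial average;
#'   needs `atlas`.
#' @param atlas Optional [atlas_volume()].
#' @return Tibble `epoch`, `n_acquisitions`, `mean_percent_change`,
#'   `sd_percent_change` (baseline row included at 0 contrast by
#'   construction of the mean).
#' @export
epoch_contrast <- function(scan, epochs, baseline = names(epochs)[1],
                           region_ids = NULL, atlas = NULL) {
  if (length(epochs) < 2) abort("need at least 2 epochs.")
  if (is.null(names(epochs)) || any(names(epochs) == "")) {
    abort("epochs must be named.")
  }
  all_idx <- unlist(lapply(epochs, function(w) seq.int(w[1], w[2])))
  if (anyDuplicated(all_idx)) abort("epochs must not overlap.")
  if (!baseline %in% names(epochs)) abort("unknown baseline epoch.")
  nt <- n_acquisitions(scan)
  sel <- if (is.null(region_ids)) {
    scan$mask
  } else {
    if (is.null(atlas)) abort("`region_ids` needs an atlas.")
    atlas$labels %in% region_ids
  }
  m <- matrix(scan$data, ncol = nt)
  course <- colMeans(m[as.vector(sel), , drop = FALSE])
  ib <- window_indices(epochs[[baseline]], scan$outlier_flags)
  base <- mean(course[ib])
  pct <- 100 * (course - base) / base
  purrr::map_dfr(names(epochs), function(e) {
    idx <- window_indices(epochs[[e]], scan$outlier_flags)
    tibble(
      epoch = e, n_acquisitions = length(idx),
      mean_percent_change = mean(pct[idx]),
      sd_percent_change = sd(pct[idx])
    )
  })
}
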