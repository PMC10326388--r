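# 4D scan container shared by the phMRI and resting-state pipelines.

#' BOLD scan
#'
#' One subject's 4D time series plus the side-car information the pipeline
#' needs: repetition time, brain mask, motion parameters, motion-outlier
#' flags, and mean tissue (white matter / CSF) time series for nuisance
#' regression.
#'
#' @param data 4D numeric array `(x, y, z, t)`, arbitrary units.
#' @param tr_seconds Repetition time in seconds.
#' @param mask 3D logical array matching the spatial dimensions; defaults to
#'   all-`TRUE`.
#' @param motion_params Optional `t x 6` matrix (3 translations mm, 3
#'   rotations rad).
#' @param outlier_flags Optional logical length-`t` vector.
#' @param tissue_means Optional named list with `white_matter` and `csf`
#'   length-`t` vectors.
#' @param subject_id Optional identifier carried through outputs.
#'
#' @return An object of class `bold_scan`.
#' @export
bold_scan <- function(data, tr_seconds, mask = NULL, motion_params = NULL,
                      outlier_flags = NULL, tissue_means = NULL,
                      subject_id = NA_character_) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) abort("`data` must be a 4D array (x, y, z, t).")
  nt <- dim(data)[4]
  if (nt < 2L) abort("a scan needs at least 2 acquisitions.")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data)[1:3])
  mask <- array(as.logical(mask), dim = dim(data)[1:3])
  if (!identical(dim(mask), dim(data)[1:3])) {
    abort("`mask` shape must equal the spatial shape of `data`.")
  }
  if (!is.null(motion_params)) {
    motion_params <- as.matrix(motion_params)
    if (nrow(motion_params) != nt || ncol(motion_params) != 6L) {
      abort("`motion_params` must be a t x 6 matrix.")
    }
  }
  if (is.null(outlier_flags)) outlier_flags <- rep(FALSE, nt)
  if (length(outlier_flags) != nt) abort("`outlier_flags` must have length t.")
  if (!is.null(tissue_means)) {
    stopifnot(
      all(c("white_matter", "csf") %in% names(tissue_means)),
      length(tissue_means$white_matter) == nt,
      length(tissue_means$csf) == nt
    )
  }
  structure(
    list(
      data = data, tr_seconds = tr_seconds, mask = mask,
      motion_params = motion_params, outlier_flags = as.logical(outlier_flags),
      tissue_means = tissue_means, subject_id = subject_id
    ),
    class = "bold_scan"
  )
}

#' @export
print.bold_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(
    "<bold_scan> ", paste(d[1:3], collapse = " x "), " voxels x ", d[4],
    " acquisitions, TR ", x$tr_seconds, " s, ",
    sum(x$mask), " in-mask voxels, ", sum(x$outlier_flags),
    " flagged outliers\n",
    sep = ""
  )
  invisible(x)
}

#' Number of acquisitions in a scan
#' @param scan A `bold_scan`.
#' @return Integer.
#' @export
n_acquisitions <- function(scan) dim(scan$data)[4]

# in-mask voxels as a (voxel x time) matrix; inverse of unflatten_scan
flatten_scan <- function(scan) {
  nt <- n_acquisitions(scan)
  m <- matrix(scan$data, ncol = nt)
  m[as.vector(scan$mask), , drop = FALSE]
}

# write a (voxel x time) in-mask matrix back to 4D
unflatten_scan <- function(mat, scan) {
  nt <- n_acquisitions(scan)
  out <- array(0, dim = dim(scan$data))
  full <- matrix(0, nrow = prod(dim(scan$data)[1:3]), ncol = nt)
  full[as.vector(scan$mask), ] <- mat
  array(full, dim = dim(scan$data))
}
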