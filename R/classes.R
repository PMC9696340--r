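#' Voxel volume
#'
#' A 3D scalar grid of gray values (arbitrary attenuation units in
#' \[0, 1\]) on an isotropic grid with a physical voxel size. Axis order is
#' (x, y, z) with z the axial (tablet height) direction; voxel indices are
#' 1-based in R and recorded 0-based in manifests.
#'
#' @param values numeric 3D array of finite gray values.
#' @param voxel_size_um voxel edge length in micrometres (> 0).
#' @return An object of class `voxel_volume` with elements `values` and
#'   `voxel_size_um`.
#' @export
voxel_volume <- function(values, voxel_size_um) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("gray values must all be finite", call. = FALSE)
  stop_if_not_scalar_num(voxel_size_um, "voxel_size_um", 0, strict = TRUE)
  structure(list(values = values, voxel_size_um = voxel_size_um),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %.3g um, gray range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary voxel mask
#'
#' @param values logical 3D array.
#' @param voxel_size_um voxel edge length in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, voxel_size_um) {
  if (!is.array(values) || length(dim(values)) != 3L || !is.logical(values))
    stop("`values` must be a logical 3D array", call. = FALSE)
  if (anyNA(values)) stop("mask must not contain NA", call. = FALSE)
  stop_if_not_scalar_num(voxel_size_um, "voxel_size_um", 0, strict = TRUE)
  structure(list(values = values, voxel_size_um = voxel_size_um),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

#' Time-ordered scan series
#'
#' An ordered set of [voxel_volume()]s acquired at strictly increasing
#' times, sharing one grid (shape and voxel size).
#'
#' @param volumes list of `voxel_volume` objects.
#' @param times_h numeric vector of acquisition times in hours.
#' @return An object of class `scan_series`.
#' @export
scan_series <- function(volumes, times_h) {
  if (!is.list(volumes) || length(volumes) == 0L)
    stop("`volumes` must be a non-empty list", call. = FALSE)
  if (!all(vapply(volumes, inherits, logical(1), "voxel_volume")))
    stop("all elements of `volumes` must be voxel_volume objects", call. = FALSE)
  if (length(times_h) != length(volumes))
    stop("`times_h` must have one entry per volume", call. = FALSE)
  if (anyNA(times_h) || is.unsorted(times_h, strictly = TRUE))
    stop("`times_h` must be strictly increasing", call. = FALSE)
  d0 <- dim(volumes[[1]]$values)
  v0 <- volumes[[1]]$voxel_size_um
  for (v in volumes) {
    if (!identical(dim(v$values), d0))
      stop("all volumes in a series must share the same shape", call. = FALSE)
    if (!isTRUE(all.equal(v$voxel_size_um, v0)))
      stop("all volumes in a series must share the same voxel size", call. = FALSE)
  }
  structure(list(volumes = volumes, times_h = as.numeric(times_h)),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  d <- dim(x$volumes[[1]]$values)
  cat(sprintf("<scan_series> %d timesteps (%.2g..%.2g h), %d x %d x %d voxels @ %.3g um\n",
              length(x$times_h), min(x$times_h), max(x$times_h),
              d[1], d[2], d[3], x$volumes[[1]]$voxel_size_um))
  invisible(x)
}

#' @export
length.scan_series <- function(x) length(x$times_h)

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grid shape mismatch: ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Dissolution release profile
#'
#' Validates a data frame with columns `time_h` (strictly increasing,
#' non-negative) and `release_pct` (cumulative % of dose, in \[0, 105\] to
#' tolerate assay noise).
#'
#' @param time_h timepoints in hours.
#' @param release_pct cumulative released percentage of the dose.
#' @return A `data.frame` of class `release_profile`.
#' @export
release_profile <- function(time_h, release_pct) {
  time_h <- as.numeric(time_h)
  release_pct <- as.numeric(release_pct)
  if (length(time_h) != length(release_pct))
    stop("`time_h` and `release_pct` must have equal length", call. = FALSE)
  if (anyNA(time_h) || anyNA(release_pct))
    stop("profile must not contain NA", call. = FALSE)
  if (any(time_h < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing (no duplicates)", call. = FALSE)
  if (any(release_pct < 0 | release_pct > 105))
    stop("release_pct must lie in [0, 105]", call. = FALSE)
  structure(data.frame(time_h = time_h, release_pct = release_pct),
            class = c("release_profile", "data.frame"))
}
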