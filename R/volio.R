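#' Write a scan series to disk
#'
#' One multi-page grayscale TIFF per timestep (page order = increasing z)
#' plus a JSON manifest recording timestamps, voxel size, axis order and
#' bit depth. Gray values must lie in \[0, 1\] and are stored as unsigned
#' integer samples. 16-bit storage (the default) quantizes to 1/(2^16 - 1)
#' steps and round-trips values on that grid bit-exactly. 32-bit storage
#' quantizes to about 2e-10 gray units — far below any scan noise — but the
#' underlying TIFF library scales writes by 2^32 - 1 and reads by 2^32, so
#' a 32-bit round trip is only bit-exact for gray values below 0.5.
#'
#' @param series a [scan_series()].
#' @param dir output directory (created if missing).
#' @param bits 16 or 32 bits per (unsigned integer) sample.
#' @param prefix file-name prefix for the per-timestep TIFFs.
#' @return Invisibly, the manifest path.
#' @export
write_series <- function(series, dir, bits = 16L, prefix = "scan") {
  stopifnot(inherits(series, "scan_series"))
  if (!bits %in% c(16L, 32L)) stop("`bits` must be 16 or 32", call. = FALSE)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir, call. = FALSE)
  files <- character(length(series))
  for (i in seq_along(series$volumes)) {
    v <- series$volumes[[i]]$values
    if (min(v) < 0 || max(v) > 1)
      stop(sprintf("volume %d has gray values outside [0, 1]; rescale before writing", i),
           call. = FALSE)
    pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
    f <- file.path(dir, sprintf("%s_t%03d.tif", prefix, i))
    ok <- try(tiff::writeTIFF(pages, f, bits.per.sample = as.integer(bits)),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("TIFF write failed for ", f, ": ", attr(ok, "condition")$message,
           call. = FALSE)
    files[i] <- basename(f)
  }
  manifest <- list(format = "dissolvis-series/1",
                   timestamps_h = series$times_h,
                   voxel_size_um = series$volumes[[1]]$voxel_size_um,
                   shape = dim(series$volumes[[1]]$values),
                   axis_order = "xyz (z axial, 0-based in manifest)",
                   page_order = "increasing z",
                   bits_per_sample = as.integer(bits),
                   files = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a scan series from a manifest
#'
#' Validates the manifest, loads every referenced multi-page TIFF, and
#' rejects missing files, shape mismatches and unsorted timestamps with
#' distinct errors.
#'
#' @param manifest path to a JSON manifest written by [write_series()].
#' @return A [scan_series()].
#' @export
read_series <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  for (fld in c("timestamps_h", "voxel_size_um", "files"))
    if (is.null(m[[fld]]))
      stop("manifest is missing field `", fld, "`", call. = FALSE)
  times <- as.numeric(m$timestamps_h)
  if (length(times) != length(m$files))
    stop("manifest lists ", length(m$files), " files but ",
         length(times), " timestamps", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("manifest timestamps must be strictly increasing", call. = FALSE)
  dir <- dirname(manifest)
  vols <- vector("list", length(m$files))
  shape <- NULL
  for (i in seq_along(m$files)) {
    f <- file.path(dir, m$files[i])
    if (!file.exists(f)) stop("missing TIFF stack: ", f, call. = FALSE)
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(dim(pages[[1]]), length(pages))
    v <- array(0, dim = d)
    for (k in seq_along(pages)) {
      if (!identical(dim(pages[[k]]), d[1:2]))
        stop("inconsistent page shapes within ", f, call. = FALSE)
      v[, , k] <- pages[[k]]
    }
    if (is.null(shape)) shape <- d
    else if (!identical(d, shape))
      stop(sprintf("shape mismatch: %s is %s, expected %s",
                   m$files[i], paste(d, collapse = "x"),
                   paste(shape, collapse = "x")), call. = FALSE)
    vols[[i]] <- voxel_volume(v, as.numeric(m$voxel_size_um))
  }
  scan_series(vols, times)
}

#' Write / read a single mask as TIFF
#'
#' Masks are stored as 8-bit multi-page TIFFs (0 = background, 1 =
#' foreground scaled to 255).
#'
#' @param mask a [binary_mask()].
#' @param path output TIFF path.
#' @return `write_mask_tiff`: invisibly, `path`.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  pages <- lapply(seq_len(dim(mask$values)[3]),
                  function(k) mask$values[, , k] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param voxel_size_um voxel size to attach on read.
#' @return `read_mask_tiff`: a [binary_mask()].
#' @export
read_mask_tiff <- function(path, voxel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  v <- array(FALSE, dim = d)
  for (k in seq_along(pages)) v[, , k] <- pages[[k]] > 0.5
  binary_mask(v, voxel_size_um)
}

#' Read / write release profiles as CSV
#'
#' CSV contract: UTF-8, header `time_h,release_pct`, one row per timepoint.
#' Parse and validation errors report the offending line.
#'
#' @param path CSV path.
#' @return `read_profile_csv`: a [release_profile()].
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "release_pct") %in% names(df)))
    stop("CSV must have header `time_h,release_pct`: ", path, call. = FALSE)
  for (col in c("time_h", "release_pct")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("non-numeric `%s` at data line %d of %s",
                   col, bad[1], path), call. = FALSE)
    df[[col]] <- vals
  }
  dup <- which(duplicated(df$time_h))
  if (length(dup) > 0)
    stop(sprintf("duplicate time %g at data line %d of %s",
                 df$time_h[dup[1]], dup[1], path), call. = FALSE)
  release_profile(df$time_h, df$release_pct)
}

#' @rdname read_profile_csv
#' @param profile a [release_profile()].
#' @return `write_profile_csv`: invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  profile <- release_profile(profile$time_h, profile$release_pct)
  write.csv(data.frame(time_h = profile$time_h,
                       release_pct = profile$release_pct),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
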