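#' Edge-preserving bilateral filter
#'
#' 3D bilateral filter: a Gaussian spatial kernel (sigma in voxels,
#' truncated at 2.5 sigma) weighted by a Gaussian range kernel (sigma in
#' gray units), so that smoothing does not cross strong gray-level edges.
#'
#' @param vol a [voxel_volume()].
#' @param sigma_spatial spatial standard deviation (voxels, > 0).
#' @param sigma_range range standard deviation (gray units, > 0); should be
#'   a few times the noise level but well below the phase contrast.
#' @return Filtered [voxel_volume()], same shape.
#' @export
bilateral_filter <- function(vol, sigma_spatial = 1.5, sigma_range = 0.1) {
  stopifnot(inherits(vol, "voxel_volume"))
  stop_if_not_scalar_num(sigma_spatial, "sigma_spatial", 0, strict = TRUE)
  stop_if_not_scalar_num(sigma_range, "sigma_range", 0, strict = TRUE)
  d <- dim(vol$values)
  out <- .bilateral3d(as.numeric(vol$values), as.integer(d),
                      sigma_spatial, sigma_range)
  vol$values <- array(out, dim = d)
  vol
}

#' Segment the tablet matrix
#'
#' Thresholds the volume at `threshold` (voxels >= threshold are
#' candidates), keeps only the largest 26-connected component (removing
#' the surrounding holder/debris), and optionally fills internal cavities
#' so the mask covers matrix + pores (the whole tablet).
#'
#' @param vol a [voxel_volume()] (typically bilateral-filtered).
#' @param threshold gray threshold; must lie within the volume's range.
#'   `NULL` selects it automatically by Otsu's method on a 256-bin
#'   histogram (logged to the console, since reproducibility favours an
#'   explicit threshold).
#' @param fill_holes if `TRUE`, internal pores are included (tablet mask);
#'   if `FALSE`, the mask is the solid matrix only.
#' @return A [binary_mask()].
#' @export
segment_matrix <- function(vol, threshold = NULL, fill_holes = TRUE) {
  stopifnot(inherits(vol, "voxel_volume"))
  rng <- range(vol$values)
  if (is.null(threshold)) {
    threshold <- otsu_threshold(vol$values)
    msg("segment_matrix: automatic Otsu threshold = %.5f", threshold)
  }
  stop_if_not_scalar_num(threshold, "threshold")
  if (threshold < rng[1] || threshold > rng[2])
    stop(sprintf("threshold %.4g outside the volume's gray range [%.4g, %.4g]",
                 threshold, rng[1], rng[2]), call. = FALSE)
  d <- dim(vol$values)
  fg <- vol$values >= threshold
  if (!any(fg)) stop("threshold leaves an empty mask", call. = FALSE)
  lab <- .label_components(as.logical(fg), as.integer(d), 26L)
  tab <- tabulate(lab)
  keep <- which.max(tab)
  mask <- array(lab == keep, dim = d)
  if (fill_holes) {
    reach <- array(.flood_background(as.logical(mask), as.integer(d)), dim = d)
    mask <- mask | (!mask & !reach)
  }
  binary_mask(mask, vol$voxel_size_um)
}

# Otsu's threshold (maximum between-class variance) on a 256-bin histogram.
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) stop("constant volume; no threshold exists", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- as.numeric(tabulate(pmin(findInterval(values, edges,
                                                  all.inside = TRUE),
                                     n_bins), nbins = n_bins))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * centers)
  n <- w[n_bins]
  mt <- m[n_bins]
  w0 <- w[-n_bins]; m0 <- m[-n_bins]
  valid <- w0 > 0 & w0 < n
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 /
    (w0[valid] * (n - w0[valid]))
  edges[which.max(bcv) + 1L]
}

#' Structural analysis of a dry scan
#'
#' The static analysis chain applied to the high-quality dry scan:
#' bilateral filtering, tablet segmentation (threshold + largest
#' 26-connected component + hole filling), pore segmentation by a second,
#' adjusted threshold inside the tablet, and voxel-counting porosity.
#'
#' @param dry the dry-scan [voxel_volume()].
#' @param sigma_spatial,sigma_range bilateral-filter parameters.
#' @param matrix_threshold tablet/background threshold; `NULL` selects it
#'   by Otsu's method over the whole volume (logged).
#' @param pore_threshold pore/matrix threshold; `NULL` selects it by Otsu's
#'   method over the voxels inside the tablet mask (logged).
#' @return List of class `dry_scan_analysis`: `filtered`, `tablet_mask`,
#'   `matrix_mask`, `pore_mask`, `porosity` (a `porosity_result`) and the
#'   thresholds used.
#' @export
analyze_dry_scan <- function(dry, sigma_spatial = 1.5, sigma_range = 0.1,
                             matrix_threshold = NULL, pore_threshold = NULL) {
  stopifnot(inherits(dry, "voxel_volume"))
  filt <- bilateral_filter(dry, sigma_spatial, sigma_range)
  if (is.null(matrix_threshold)) {
    matrix_threshold <- otsu_threshold(filt$values)
    msg("analyze_dry_scan: tablet threshold (Otsu) = %.5f", matrix_threshold)
  }
  tablet <- segment_matrix(filt, matrix_threshold, fill_holes = TRUE)
  if (is.null(pore_threshold)) {
    pore_threshold <- otsu_threshold(filt$values[tablet$values])
    msg("analyze_dry_scan: pore threshold (in-tablet Otsu) = %.5f",
        pore_threshold)
  }
  pore <- binary_mask(tablet$values & filt$values < pore_threshold,
                      dry$voxel_size_um)
  matrix_m <- binary_mask(tablet$values & !pore$values, dry$voxel_size_um)
  list(filtered = filt, tablet_mask = tablet, matrix_mask = matrix_m,
       pore_mask = pore, porosity = compute_porosity(tablet, pore),
       matrix_threshold = matrix_threshold, pore_threshold = pore_threshold)
}

#' Voxel-counting porosity
#'
#' Total porosity as the exact ratio of pore voxels to total tablet voxels
#' (matrix + pores).
#'
#' @param tablet_mask [binary_mask()] of the whole tablet (pores included).
#' @param pore_mask [binary_mask()] of the pore space; must be a subset of
#'   `tablet_mask`.
#' @return List of class `porosity_result`: `porosity`, `pore_voxels`,
#'   `tablet_voxels`.
#' @export
compute_porosity <- function(tablet_mask, pore_mask) {
  stopifnot(inherits(tablet_mask, "binary_mask"),
            inherits(pore_mask, "binary_mask"))
  check_same_grid(tablet_mask, pore_mask)
  if (!any(tablet_mask$values)) stop("empty tablet mask", call. = FALSE)
  if (any(pore_mask$values & !tablet_mask$values))
    stop("pore mask must be a subset of the tablet mask", call. = FALSE)
  pv <- sum(pore_mask$values)
  tv <- sum(tablet_mask$values)
  structure(list(porosity = pv / tv, pore_voxels = pv, tablet_voxels = tv),
            class = "porosity_result")
}

#' @export
print.porosity_result <- function(x, ...) {
  cat(sprintf("<porosity_result> %.4f (%d pore / %d tablet voxels)\n",
              x$porosity, x$pore_voxels, x$tablet_voxels))
  invisible(x)
}

# FFT cross-correlation of two equal-shape arrays; returns the integer
# circular shift of `mov` that maximizes correlation with `ref`, plus a
# quadratic sub-voxel refinement per axis.
xcorr_shift <- function(ref, mov) {
  d <- dim(ref)
  cc <- Re(fft(fft(ref) * Conj(fft(mov)), inverse = TRUE))
  peak <- which.max(cc)
  pidx <- arrayInd(peak, d)
  shift <- numeric(3)
  for (ax in 1:3) {
    p <- pidx[ax]
    lo <- if (p == 1) d[ax] else p - 1L
    hi <- if (p == d[ax]) 1L else p + 1L
    i_m <- pidx; i_m[ax] <- lo
    i_p <- pidx; i_p[ax] <- hi
    cm <- cc[matrix(i_m, 1)]; c0 <- cc[matrix(pidx, 1)]; cp <- cc[matrix(i_p, 1)]
    denom <- cm - 2 * c0 + cp
    frac <- if (abs(denom) > .Machine$double.eps) (cm - cp) / (2 * denom) else 0
    frac <- max(min(frac, 0.5), -0.5)
    s <- p - 1L                                   # circular lag, 0-based
    if (s > d[ax] / 2) s <- s - d[ax]
    shift[ax] <- s + frac
  }
  shift
}

#' Rigid registration and resampling onto a reference grid
#'
#' Estimates a 3-degree-of-freedom translation (the sample is fixed in the
#' cell; only source and detector move, so no rotation) by FFT
#' cross-correlation with quadratic sub-voxel refinement, then resamples
#' the moving volume onto the reference grid by trilinear interpolation.
#' Voxel sizes may differ (e.g. a 10.09 um high-quality scan mapped onto
#' the 20.18 um fast-scan grid).
#'
#' @param moving the volume to align (e.g. the dry high-quality scan).
#' @param reference the target-grid volume (e.g. the first fast scan).
#' @param min_correlation floor on the normalized cross-correlation at the
#'   optimum; below it registration fails.
#' @param fill gray value for reference voxels outside the moving volume's
#'   field of view (default: the moving volume's minimum).
#' @return The registered, resampled [voxel_volume()] on the reference
#'   grid, with attributes `shift_vox` (translation in reference voxels)
#'   and `correlation`.
#' @export
register_resample <- function(moving, reference, min_correlation = 0.5,
                              fill = NULL) {
  stopifnot(inherits(moving, "voxel_volume"),
            inherits(reference, "voxel_volume"))
  fill <- fill %||% min(moving$values)
  scale <- reference$voxel_size_um / moving$voxel_size_um
  dref <- dim(reference$values)
  dmov <- dim(moving$values)
  # moving volume expressed on the reference spacing (origin aligned)
  mov_on_ref <- array(
    .resample_trilinear(as.numeric(moving$values), as.integer(dmov),
                        as.integer(dref), origin = rep(0, 3),
                        step = rep(scale, 3), fill = fill),
    dim = dref)
  ref0 <- reference$values - mean(reference$values)
  mov0 <- mov_on_ref - mean(mov_on_ref)
  shift <- xcorr_shift(ref0, mov0)          # ref = mov shifted by `shift`
  out <- array(
    .resample_trilinear(as.numeric(moving$values), as.integer(dmov),
                        as.integer(dref), origin = -shift * scale,
                        step = rep(scale, 3), fill = fill),
    dim = dref)
  cc <- suppressWarnings(stats::cor(as.numeric(out),
                                    as.numeric(reference$values)))
  if (!is.finite(cc) || cc < min_correlation)
    stop(sprintf("registration failure: correlation %.3f below floor %.2f",
                 cc, min_correlation), call. = FALSE)
  res <- voxel_volume(out, reference$voxel_size_um)
  attr(res, "shift_vox") <- shift
  attr(res, "correlation") <- cc
  res
}

#' Resample a volume onto a reference grid with a known shift
#'
#' Trilinear resampling of `vol` onto the grid of `reference`, applying a
#' translation (in reference voxels) estimated elsewhere — e.g. by
#' [register_resample()] on polarity-normalized masks when the two scans
#' have opposite tablet/background contrast.
#'
#' @param vol the volume to resample.
#' @param reference the target-grid volume.
#' @param shift_vox length-3 translation in reference voxels (reference =
#'   moving shifted by `shift_vox`).
#' @param fill gray value outside the moving field of view.
#' @return A [voxel_volume()] on the reference grid.
#' @export
resample_onto <- function(vol, reference, shift_vox = c(0, 0, 0), fill = NULL) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(reference, "voxel_volume"))
  fill <- fill %||% min(vol$values)
  scale <- reference$voxel_size_um / vol$voxel_size_um
  out <- array(
    .resample_trilinear(as.numeric(vol$values), as.integer(dim(vol$values)),
                        as.integer(dim(reference$values)),
                        origin = -as.numeric(shift_vox) * scale,
                        step = rep(scale, 3), fill = fill),
    dim = dim(reference$values))
  voxel_volume(out, reference$voxel_size_um)
}

#' Block-average downsampling
#'
#' Averages non-overlapping `factor^3` blocks, emulating acquisition at a
#' coarser voxel size (e.g. 10.09 -> 20.18 um). Trailing voxels that do not
#' fill a block are dropped.
#'
#' @param vol a [voxel_volume()].
#' @param factor integer downsampling factor (>= 1).
#' @return A [voxel_volume()] with `factor`-fold larger voxels.
#' @export
downsample_volume <- function(vol, factor = 2L) {
  stopifnot(inherits(vol, "voxel_volume"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(vol)
  d <- dim(vol$values)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("volume too small for this factor", call. = FALSE)
  v <- vol$values[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(v, c(2, 4, 6), mean)
  voxel_volume(out, vol$voxel_size_um * factor)
}

#' Shrink a volume of interest
#'
#' Morphological erosion with a 6-connected structuring element, applied
#' `iterations` times; removes a surface layer so that, e.g., voxels wetted
#' at the tablet boundary during the first scan do not contaminate the
#' "dry" training histogram.
#'
#' @param mask a [binary_mask()].
#' @param iterations number of erosion passes (>= 0).
#' @return The eroded [binary_mask()] (always a subset of the input).
#' @export
shrink_voi <- function(mask, iterations = 2L) {
  stopifnot(inherits(mask, "binary_mask"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop("`iterations` must be >= 0", call. = FALSE)
  d <- dim(mask$values)
  m <- mask$values
  for (i in seq_len(iterations)) {
    m <- array(.erode6(as.logical(m), as.integer(d)), dim = d)
    if (!any(m))
      stop(sprintf("mask eroded to empty at iteration %d", i), call. = FALSE)
  }
  binary_mask(m, mask$voxel_size_um)
}

#' @rdname shrink_voi
#' @details `shrink_voi_surface()` removes a surface layer only: it fills
#'   the mask's internal cavities, erodes the filled mask, and intersects
#'   with the original. Eroding a pore-riddled matrix mask directly would
#'   also carve shells around every internal pore and radially bias the
#'   VOI.
#' @export
shrink_voi_surface <- function(mask, iterations = 2L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (iterations == 0L) return(mask)
  d <- dim(mask$values)
  reach <- array(.flood_background(as.logical(mask$values), as.integer(d)),
                 dim = d)
  filled <- binary_mask(mask$values | (!mask$values & !reach),
                        mask$voxel_size_um)
  binary_mask(shrink_voi(filled, iterations)$values & mask$values,
              mask$voxel_size_um)
}
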