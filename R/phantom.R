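#' Phantom specification
#'
#' Full parameterization of the synthetic 4D tablet phantom: a porous
#' cylindrical tablet (matrix + spherical air pores) immersed in
#' contrast-agent brine, wetted by a radially advancing shrinking-core
#' front. Gray values are arbitrary attenuation units constrained to
#' \[0, 1\] (the detector dynamic range used by the TIFF writer).
#'
#' Defaults emulate the experimental conditions: a 10 mm diameter x 2.8 mm
#' tablet with 23.24% total porosity imaged at the 20.18 um fast-scan voxel
#' size, with the brine the brightest phase (the contrast agent raises the
#' attenuation of wetted regions).
#'
#' @param tablet_radius_mm,tablet_height_mm cylinder geometry (mm).
#' @param voxel_size_um isotropic voxel edge (um).
#' @param target_porosity pore volume fraction in \[0, 1).
#' @param pore_radius_mean_um,pore_radius_sd_um pore size distribution (um).
#' @param mu_background,mu_matrix,mu_brine attenuation gray levels for air,
#'   dry polymer matrix and contrast brine; must satisfy
#'   `mu_brine > mu_matrix > mu_background`.
#' @param uplift gray-level increase of wetted matrix over dry matrix
#'   (default: midway towards `mu_brine`); the wetted matrix forms a
#'   distinct second histogram mode below pure brine.
#' @param front_speed_mm_h radial speed of the wetting front (mm/h).
#' @param noise_sd Gaussian image noise, fast (dissolution) scans.
#' @param noise_sd_dry Gaussian image noise, high-quality dry scan.
#' @param bias_sd standard deviation (gray units) of a smooth low-frequency
#'   shading field added to the brine-immersed fast scans, emulating
#'   uncorrected beam-hardening/cupping and scatter from the contrast-agent
#'   filled cell. Absent (`0`) in the dry air scan.
#' @param margin_voxels background margin around the tablet (voxels).
#' @param porosity_tol accepted |realized - target| porosity deviation.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tablet_radius_mm = 5,
                         tablet_height_mm = 2.8,
                         voxel_size_um = 20.18,
                         target_porosity = 0.2324,
                         pore_radius_mean_um = 70,
                         pore_radius_sd_um = 20,
                         mu_background = 0.08,
                         mu_matrix = 0.38,
                         mu_brine = 0.70,
                         uplift = (mu_brine - mu_matrix) / 2,
                         front_speed_mm_h = 0.7,
                         noise_sd = 0.03,
                         noise_sd_dry = 0.015,
                         bias_sd = 0.044,
                         margin_voxels = 4L,
                         porosity_tol = 0.005,
                         seed = 1L) {
  for (nm in c("tablet_radius_mm", "tablet_height_mm", "voxel_size_um",
               "pore_radius_mean_um"))
    stop_if_not_scalar_num(get(nm), nm, 0, strict = TRUE)
  if (!(mu_brine > mu_matrix && mu_matrix > mu_background))
    stop("attenuation levels must satisfy mu_brine > mu_matrix > mu_background",
         call. = FALSE)
  for (nm in c("pore_radius_sd_um", "front_speed_mm_h", "noise_sd",
               "noise_sd_dry", "bias_sd", "porosity_tol", "uplift"))
    stop_if_not_scalar_num(get(nm), nm, 0)
  stop_if_not_scalar_num(target_porosity, "target_porosity", 0)
  if (target_porosity >= 1)
    stop("`target_porosity` must lie in [0, 1)", call. = FALSE)
  if (mu_background < 0 || mu_brine > 1)
    stop("gray levels must lie in [0, 1]", call. = FALSE)
  stop_if_not_scalar_num(seed, "seed")
  spec <- list(tablet_radius_mm = tablet_radius_mm,
               tablet_height_mm = tablet_height_mm,
               voxel_size_um = voxel_size_um,
               target_porosity = target_porosity,
               pore_radius_mean_um = pore_radius_mean_um,
               pore_radius_sd_um = pore_radius_sd_um,
               mu_background = mu_background, mu_matrix = mu_matrix,
               mu_brine = mu_brine, uplift = uplift,
               front_speed_mm_h = front_speed_mm_h,
               noise_sd = noise_sd, noise_sd_dry = noise_sd_dry,
               bias_sd = bias_sd,
               margin_voxels = as.integer(margin_voxels),
               porosity_tol = porosity_tol,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Grid-bounded phantom specification
#'
#' Convenience constructor for desk-scale phantoms: keeps the physical
#' tablet geometry, attenuation levels and kinetics of [phantom_spec()] but
#' enlarges the voxel so the tablet diameter spans a grid of at most
#' `grid` voxels, and enlarges the pores so they stay resolvable
#' (mean radius 2.5 voxels).
#'
#' @param grid maximum lateral grid extent in voxels.
#' @param ... overrides passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_spec_demo <- function(grid = 96L, ...) {
  dots <- list(...)
  margin <- dots$margin_voxels %||% 4L
  radius_mm <- dots$tablet_radius_mm %||% 5
  radius_vox <- grid / 2 - margin
  voxel <- radius_mm * 1000 / radius_vox
  args <- c(list(voxel_size_um = voxel,
                 pore_radius_mean_um = 2.5 * voxel,
                 pore_radius_sd_um = 0.7 * voxel),
            dots)
  args <- args[!duplicated(names(args))]
  do.call(phantom_spec, args)
}

# squared cylindrical radius (voxel units) of every (x, y) grid point
radial_sq_2d <- function(nx, ny, cx, cy) {
  outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, `+`)
}

#' Build a dry synthetic tablet
#'
#' Rasterizes a cylindrical polymer matrix at `mu_matrix` into an air
#' background and carves spherical air pores (rejection-sampled,
#' non-overlapping, fully interior) until the realized voxel-counted
#' porosity reaches the target within `porosity_tol`. The returned volume
#' is noise-free; apply [add_noise()] to emulate a scan.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (clean dry [voxel_volume()]) and `truth`
#'   (class `ground_truth`: `pore_mask`, `matrix_mask`, `tablet_mask`
#'   [binary_mask()]s, realized porosity, axis geometry).
#' @export
build_tablet <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vox <- spec$voxel_size_um
  R <- spec$tablet_radius_mm * 1000 / vox          # voxels
  H <- max(1L, round(spec$tablet_height_mm * 1000 / vox))
  m <- spec$margin_voxels
  nx <- ny <- 2L * ceiling(R) + 2L * m + 1L
  nz <- H + 2L * m
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  z0 <- m + 1L
  z1 <- m + H
  rsq2 <- radial_sq_2d(nx, ny, cx, cy)
  cyl2 <- rsq2 <= R^2
  tablet <- array(FALSE, dim = c(nx, ny, nz))
  tablet[, , z0:z1] <- cyl2
  n_tab <- sum(tablet)
  if (n_tab == 0L) stop("grid too small to contain the tablet", call. = FALSE)

  pore <- array(FALSE, dim = c(nx, ny, nz))
  pores <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      r_vox = numeric(0))
  n_target <- round(spec$target_porosity * n_tab)
  if (n_target > 0) {
    r_mean_vox <- spec$pore_radius_mean_um / vox
    if (r_mean_vox < 0.6)
      stop("pore_radius_mean_um is below the voxel size; pores are not ",
           "resolvable on this grid", call. = FALSE)
    mean_sphere <- 4 / 3 * pi * r_mean_vox^3
    max_attempts <- ceiling(300 * n_target / mean_sphere) + 20000
    placed <- list()
    pore_count <- with_seed(spec$seed, {
      count <- 0L
      attempts <- 0L
      consec_reject <- 0L
      allow_overlap <- FALSE
      while (count < n_target && attempts < max_attempts) {
        attempts <- attempts + 1L
        r_vox <- max(0.6, rnorm(1, spec$pore_radius_mean_um,
                                spec$pore_radius_sd_um) / vox)
        # sphere centre placed so every pore voxel keeps >= 1 voxel of
        # matrix skin towards the background (pores must be true cavities)
        zlo <- z0 + r_vox + 0.5
        zhi <- z1 - r_vox - 0.5
        if (zlo >= zhi) next
        px <- runif(1, cx - R, cx + R)
        py <- runif(1, cy - R, cy + R)
        pz <- runif(1, zlo, zhi)
        if ((px - cx)^2 + (py - cy)^2 > (R - r_vox - 1.2)^2) next
        xi <- max(1L, floor(px - r_vox)):min(nx, ceiling(px + r_vox))
        yi <- max(1L, floor(py - r_vox)):min(ny, ceiling(py + r_vox))
        zi <- max(1L, floor(pz - r_vox)):min(nz, ceiling(pz + r_vox))
        inside <- outer(outer((xi - px)^2, (yi - py)^2, `+`),
                        (zi - pz)^2, `+`) <= r_vox^2
        sel <- which(inside, arr.ind = TRUE)
        if (nrow(sel) == 0L) next
        lin <- xi[sel[, 1]] +
          (yi[sel[, 2]] - 1L) * nx +
          (zi[sel[, 3]] - 1L) * nx * as.double(ny)
        if (!allow_overlap && any(pore[lin])) {
          consec_reject <- consec_reject + 1L
          if (consec_reject > 200L) {
            warning("pore overlap allowed after repeated rejections; ",
                    "target porosity hard to reach without overlap")
            allow_overlap <- TRUE
          }
          next
        }
        consec_reject <- 0L
        new <- lin[!pore[lin]]
        # do not overshoot the target beyond tolerance; wait for a smaller
        # sphere instead
        if (count + length(new) >
              n_target + 0.8 * spec$porosity_tol * n_tab) next
        pore[new] <- TRUE
        count <- count + length(new)
        placed[[length(placed) + 1L]] <- c(px, py, pz, r_vox)
      }
      count
    })
    if (length(placed) > 0) {
      pores <- as.data.frame(do.call(rbind, placed))
      names(pores) <- c("x", "y", "z", "r_vox")
    }
    realized <- pore_count / n_tab
    if (abs(realized - spec$target_porosity) > spec$porosity_tol)
      stop(sprintf(paste0("target porosity %.4f unreachable: realized %.4f ",
                          "after bounded attempts"),
                   spec$target_porosity, realized), call. = FALSE)
  }
  matrix_mask <- tablet & !pore
  values <- array(spec$mu_background, dim = c(nx, ny, nz))
  values[matrix_mask] <- spec$mu_matrix
  truth <- structure(list(
    pore_mask = binary_mask(pore, vox),
    matrix_mask = binary_mask(matrix_mask, vox),
    tablet_mask = binary_mask(tablet, vox),
    porosity = sum(pore) / n_tab,
    pores = pores,
    center_vox = c(cx, cy),
    radius_vox = R,
    z_range = c(z0, z1),
    spec = spec), class = "ground_truth")
  list(volume = voxel_volume(values, vox), truth = truth)
}

#' Analytic wetting state of the phantom
#'
#' The shrinking-core front sits at cylindrical radius
#' `r(t) = R - front_speed * t` (floored at 0); a voxel is wet iff its
#' cylindrical radius exceeds `r(t)`. Because the front is a deterministic
#' geometric object, the true wet/dry state of any voxel at any time can be
#' reconstructed exactly, for any volume of interest.
#'
#' @param truth a `ground_truth` from [build_tablet()].
#' @param time_h time in hours.
#' @return `truth_wet_mask`: logical 3D array (TRUE = wet).
#' @export
truth_wet_mask <- function(truth, time_h) {
  stopifnot(inherits(truth, "ground_truth"))
  spec <- truth$spec
  r_mm <- max(spec$tablet_radius_mm - spec$front_speed_mm_h * time_h, 0)
  r_vox <- r_mm * 1000 / spec$voxel_size_um
  d <- dim(truth$matrix_mask$values)
  if (r_mm <= 0) return(array(TRUE, dim = d))   # fully penetrated
  rsq2 <- radial_sq_2d(d[1], d[2], truth$center_vox[1], truth$center_vox[2])
  array(rsq2 > r_vox^2, dim = d)
}

#' @rdname truth_wet_mask
#' @param times_h vector of times (hours).
#' @param mask optional [binary_mask()] (default: the ground-truth matrix
#'   mask) over which the wet fraction is counted.
#' @return `truth_wet_fraction`: numeric vector of wet fractions in \[0, 1\].
#' @export
truth_wet_fraction <- function(truth, times_h, mask = truth$matrix_mask) {
  sel <- mask$values
  n <- sum(sel)
  if (n == 0L) stop("empty mask", call. = FALSE)
  vapply(times_h, function(t) sum(truth_wet_mask(truth, t)[sel]) / n,
         numeric(1))
}

# Smooth zero-mean low-order polynomial shading field, standardized to unit
# sd over the tablet and clamped at 2.5 sd. Emulates uncorrected
# beam-hardening/cupping/scatter shading in the brine-filled cell.
shading_field <- function(dims, center, radius_vox, z_range, tablet, seed) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xt <- (seq_len(nx) - center[1]) / radius_vox
  yt <- (seq_len(ny) - center[2]) / radius_vox
  zm <- (z_range[1] + z_range[2]) / 2
  zh <- max((z_range[2] - z_range[1]) / 2, 1)
  zt <- (seq_len(nz) - zm) / zh
  co <- with_seed(seed, rnorm(9))
  f2d <- co[1] * outer(xt, rep(1, ny)) + co[2] * outer(rep(1, nx), yt) +
    co[4] * outer(xt, yt) +
    co[7] * outer(xt^2, rep(1, ny)) + co[8] * outer(rep(1, nx), yt^2)
  field <- array(0, dim = dims)
  for (k in seq_len(nz))
    field[, , k] <- f2d + co[3] * zt[k] + co[9] * zt[k]^2 +
      (co[5] * xt) %o% rep(1, ny) * zt[k] +
      rep(1, nx) %o% (co[6] * yt) * zt[k]
  mu <- mean(field[tablet])
  s <- sd(field[tablet])
  if (s < .Machine$double.eps) return(array(0, dim = dims))
  field <- (field - mu) / s
  pmax(pmin(field, 2.5), -2.5)
}

#' Simulate brine ingress (4D scan series)
#'
#' Generates one fast scan per timestep: outside the tablet the cell is
#' flooded with brine at `mu_brine`; within the tablet a radial
#' shrinking-core front at `r(t) = R - front_speed * t` wets the material
#' (wet matrix takes `mu_matrix + uplift`, wet pores fill with brine at
#' `mu_brine`, dry pores stay at air level). Each timestep receives the
#' experiment's fixed shading field (`bias_sd`) plus fresh Gaussian noise
#' (`noise_sd`), and is clamped to the \[0, 1\] detector range. Noise seeds
#' derive deterministically from `spec$seed` and the timestep index.
#'
#' @param dry clean dry [voxel_volume()] from [build_tablet()].
#' @param truth matching `ground_truth`.
#' @param spec the [phantom_spec()].
#' @param times_h sorted times in hours, starting at 0.
#' @return A list with `series` ([scan_series()]) and `truth` (the input
#'   ground truth augmented with `times_h`, `wet_fraction_per_time`, and
#'   `front_radius_per_time_mm`).
#' @export
simulate_ingress <- function(dry, truth, spec, times_h) {
  stopifnot(inherits(dry, "voxel_volume"), inherits(truth, "ground_truth"),
            inherits(spec, "phantom_spec"))
  if (length(times_h) == 0L) stop("`times_h` must be non-empty", call. = FALSE)
  if (is.unsorted(times_h, strictly = TRUE))
    stop("`times_h` must be strictly increasing", call. = FALSE)
  if (times_h[1] != 0) stop("`times_h` must start at 0", call. = FALSE)
  d <- dim(dry$values)
  matrix_m <- truth$matrix_mask$values
  pore_m <- truth$pore_mask$values
  tablet_m <- truth$tablet_mask$values
  field <- if (spec$bias_sd > 0)
    spec$bias_sd * shading_field(d, truth$center_vox, truth$radius_vox,
                                 truth$z_range, tablet_m, spec$seed + 11L)
  else NULL
  vols <- vector("list", length(times_h))
  wet_frac <- numeric(length(times_h))
  n_matrix <- sum(matrix_m)
  for (ti in seq_along(times_h)) {
    wet <- truth_wet_mask(truth, times_h[ti])
    vals <- array(spec$mu_brine, dim = d)
    vals[matrix_m] <- spec$mu_matrix + spec$uplift * wet[matrix_m]
    vals[pore_m] <- ifelse(wet[pore_m], spec$mu_brine, spec$mu_background)
    if (!is.null(field)) vals <- vals + field
    vol <- voxel_volume(vals, spec$voxel_size_um)
    vol <- add_noise(vol, spec$noise_sd, seed = spec$seed + 7919L * ti)
    vol$values[] <- pmin(pmax(vol$values, 0), 1)
    vols[[ti]] <- vol
    wet_frac[ti] <- sum(wet & matrix_m) / n_matrix
  }
  truth$times_h <- as.numeric(times_h)
  truth$wet_fraction_per_time <- wet_frac
  truth$front_radius_per_time_mm <-
    pmax(spec$tablet_radius_mm - spec$front_speed_mm_h * times_h, 0)
  list(series = scan_series(vols, times_h), truth = truth)
}

#' Beer-Lambert attenuation
#'
#' Transmitted intensity of a monochromatic beam through a homogeneous
#' slab: `I_out = I_in * exp(-mu * T)`.
#'
#' @param I_in incident intensity (> 0, counts).
#' @param mu linear attenuation coefficient (>= 0, 1/length).
#' @param T_ path thickness (>= 0, length; units must match `mu`).
#' @return Transmitted intensity, vectorized over the inputs.
#' @export
beer_lambert <- function(I_in, mu, T_) {
  if (any(!is.finite(I_in)) || any(I_in <= 0))
    stop("`I_in` must be > 0", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu < 0)) stop("`mu` must be >= 0", call. = FALSE)
  if (any(!is.finite(T_)) || any(T_ < 0)) stop("`T_` must be >= 0", call. = FALSE)
  I_in * exp(-mu * T_)
}

#' Simulated radiograph of a volume
#'
#' Treats gray values as linear attenuation coefficients (per mm) and
#' integrates Beer-Lambert attenuation along one grid axis (a parallel-beam
#' projection), producing a 2D intensity image. Demonstration only; no
#' tomographic reconstruction is attempted.
#'
#' @param vol a [voxel_volume()].
#' @param I_in incident intensity.
#' @param axis projection axis: `"x"`, `"y"` or `"z"`.
#' @return 2D matrix of transmitted intensities.
#' @export
radiograph <- function(vol, I_in = 1000, axis = c("y", "x", "z")) {
  stopifnot(inherits(vol, "voxel_volume"))
  axis <- match.arg(axis)
  t_mm <- vol$voxel_size_um / 1000
  path <- apply(vol$values, switch(axis, x = c(2, 3), y = c(1, 3), z = c(1, 2)),
                sum) * t_mm
  beer_lambert(I_in, path, 1)
}

#' Additive Gaussian image noise
#'
#' @param vol a [voxel_volume()].
#' @param noise_sd noise standard deviation in gray units (>= 0); `0`
#'   returns the input unchanged.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return A noisy [voxel_volume()].
#' @export
add_noise <- function(vol, noise_sd, seed) {
  stopifnot(inherits(vol, "voxel_volume"))
  stop_if_not_scalar_num(noise_sd, "noise_sd", 0)
  if (noise_sd == 0) return(vol)
  vol$values <- vol$values +
    with_seed(seed, array(rnorm(length(vol$values), 0, noise_sd),
                          dim = dim(vol$values)))
  vol
}

#' Standard dissolution sampling timepoints
#'
#' The paddle/flow-cell sampling schedule used throughout: 0.25, 0.5, 0.75,
#' 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8 and 10 h.
#'
#' @return Numeric vector of hours.
#' @export
dissolution_timepoints <- function() {
  c(0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8, 10)
}

#' Simulate a matched sustained-release experiment
#'
#' Generates the UV-side ground truth paired with the imaging phantom:
#' cumulative release proportional to the analytically wetted volume
#' fraction of the shrinking-core front, with a wetting-to-dissolution lag.
#' Released mass is converted to medium concentration under the sequential
#' withdrawal scheme (closed loop, no medium replacement) and then to
#' absorbances through the forward calibration map, with optional
#' measurement noise.
#'
#' @param spec a [phantom_spec()] (supplies geometry and front speed).
#' @param times_h sampling timepoints (hours, > 0, strictly increasing);
#'   default [dissolution_timepoints()].
#' @param dose_mg drug dose in the tablet (mg); default 65.6 mg (40% w/w of
#'   a 164 mg tablet).
#' @param calib a [calibration_curve] (see [fit_calibration()]).
#' @param scheme a [sampling_scheme()].
#' @param lag_h lag between wetting and dissolution (hours).
#' @param abs_noise_sd absorbance measurement noise (AU).
#' @param seed integer seed for the measurement noise.
#' @return List with `profile` (the true [release_profile()]),
#'   `concentration_ug_ml`, and `absorbance` (data frame `time_h`,
#'   `absorbance`).
#' @export
simulate_release <- function(spec, times_h = dissolution_timepoints(),
                             dose_mg = 65.6, calib = demo_calibration(),
                             scheme = sampling_scheme(timepoints = times_h),
                             lag_h = 0.25, abs_noise_sd = 0.002, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  stop_if_not_scalar_num(dose_mg, "dose_mg", 0, strict = TRUE)
  if (length(times_h) == 0L || any(times_h <= 0) ||
      is.unsorted(times_h, strictly = TRUE))
    stop("`times_h` must be positive and strictly increasing", call. = FALSE)
  R <- spec$tablet_radius_mm
  v <- spec$front_speed_mm_h
  wf <- function(t) 1 - (pmax(R - v * t, 0) / R)^2
  rel_frac <- wf(pmax(times_h - lag_h, 0))
  mass_mg <- dose_mg * rel_frac
  n <- length(times_h)
  conc <- numeric(n)
  withdrawn <- 0
  for (i in seq_len(n)) {
    v_i <- scheme$medium_volume_ml - (i - 1) * scheme$sample_volume_ml
    conc[i] <- (mass_mg[i] * 1000 - withdrawn) / v_i   # ug/mL
    withdrawn <- withdrawn + conc[i] * scheme$sample_volume_ml
  }
  absorb <- calib$intercept + calib$slope * conc
  if (abs_noise_sd > 0)
    absorb <- absorb + with_seed(seed, rnorm(n, 0, abs_noise_sd))
  list(profile = release_profile(times_h, 100 * rel_frac),
       concentration_ug_ml = conc,
       absorbance = data.frame(time_h = times_h, absorbance = absorb))
}
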