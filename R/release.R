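#' Fit a UV calibration line
#'
#' Ordinary least-squares line of absorbance versus concentration from
#' standard solutions (e.g. 5-40 ug/mL at the drug's absorption maximum).
#'
#' @param standards data frame with columns `concentration_ug_ml` and
#'   `absorbance` (>= 3 points spanning a nonzero concentration range).
#' @param lambda_max_nm detection wavelength (recorded, not used in math).
#' @return Object of class `calibration_curve`: `slope` (AU per ug/mL,
#'   > 0), `intercept` (AU), `r_squared`, `lambda_max_nm`, `valid_range`
#'   (the standards' concentration range).
#' @export
fit_calibration <- function(standards, lambda_max_nm = 222) {
  if (!is.data.frame(standards) ||
      !all(c("concentration_ug_ml", "absorbance") %in% names(standards)))
    stop("`standards` needs columns concentration_ug_ml and absorbance",
         call. = FALSE)
  conc <- standards$concentration_ug_ml
  absb <- standards$absorbance
  if (length(conc) < 3L) stop("need at least 3 standards", call. = FALSE)
  if (anyNA(conc) || anyNA(absb)) stop("standards contain NA", call. = FALSE)
  if (diff(range(conc)) <= 0)
    stop("standards have zero concentration spread", call. = FALSE)
  fit <- lm(absb ~ conc)
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stop("calibration slope must be positive", call. = FALSE)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 lambda_max_nm = lambda_max_nm,
                 valid_range = range(conc)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> A = %.5g * C + %.5g (R^2 = %.5f, %g nm, valid %g-%g ug/mL)\n",
              x$slope, x$intercept, x$r_squared, x$lambda_max_nm,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Synthetic demonstration calibration
#'
#' An exact calibration line (slope 0.02 AU per ug/mL, intercept 0.001 AU,
#' standards at 5, 10, 20, 30, 40 ug/mL) used by the phantom's simulated
#' release experiment. Synthetic: not fitted to any measured spectra.
#'
#' @param slope,intercept line parameters.
#' @param lambda_max_nm recorded wavelength.
#' @return A `calibration_curve`.
#' @export
demo_calibration <- function(slope = 0.02, intercept = 0.001,
                             lambda_max_nm = 222) {
  conc <- c(5, 10, 20, 30, 40)
  fit_calibration(data.frame(concentration_ug_ml = conc,
                             absorbance = intercept + slope * conc),
                  lambda_max_nm = lambda_max_nm)
}

#' Convert absorbance to concentration
#'
#' `(absorbance - intercept) / slope`; values outside the calibration's
#' valid range are flagged (attribute `extrapolated`) and a warning is
#' raised, but conversion proceeds.
#'
#' @param absorbance numeric vector of absorbances (AU).
#' @param calib a `calibration_curve`.
#' @param warn warn on extrapolation (default TRUE).
#' @return Concentrations (ug/mL) with logical attribute `extrapolated`.
#' @export
to_concentration <- function(absorbance, calib, warn = TRUE) {
  stopifnot(inherits(calib, "calibration_curve"))
  conc <- (absorbance - calib$intercept) / calib$slope
  extra <- conc < calib$valid_range[1] | conc > calib$valid_range[2]
  if (warn && any(extra))
    warning(sprintf("%d of %d concentrations outside the calibrated range [%g, %g] ug/mL",
                    sum(extra), length(extra),
                    calib$valid_range[1], calib$valid_range[2]), call. = FALSE)
  attr(conc, "extrapolated") <- extra
  conc
}

#' Sampling scheme of the dissolution experiment
#'
#' @param medium_volume_ml initial medium volume (default 900 mL).
#' @param sample_volume_ml volume withdrawn per timepoint (default 5 mL).
#' @param timepoints sampling times (hours).
#' @param replaced whether withdrawn medium is replaced by fresh medium
#'   (default `FALSE`: closed loop, the volume shrinks).
#' @return Object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(medium_volume_ml = 900, sample_volume_ml = 5,
                            timepoints = dissolution_timepoints(),
                            replaced = FALSE) {
  stop_if_not_scalar_num(medium_volume_ml, "medium_volume_ml", 0, strict = TRUE)
  stop_if_not_scalar_num(sample_volume_ml, "sample_volume_ml", 0, strict = TRUE)
  if (sample_volume_ml * length(timepoints) >= medium_volume_ml)
    stop("total withdrawn volume must stay below the medium volume",
         call. = FALSE)
  structure(list(medium_volume_ml = medium_volume_ml,
                 sample_volume_ml = sample_volume_ml,
                 timepoints = as.numeric(timepoints),
                 replaced = isTRUE(replaced)),
            class = "sampling_scheme")
}

#' Cumulative release with withdrawal correction
#'
#' Converts per-timepoint medium concentrations into cumulative released
#' percentage of the dose, correcting for the drug removed by earlier
#' samples. With `replaced = FALSE` (closed loop) the medium volume shrinks
#' by one sample per withdrawal, so the released mass at timepoint `i` is
#' `C_i * (V - (i-1) * Vs) + sum_{j<i} C_j * Vs`; with replacement the
#' volume stays at `V` and the first term is `C_i * V`.
#'
#' Measurement noise can push near-blank absorbances slightly below the
#' calibration blank; the resulting negative masses are floored at zero.
#'
#' @param concentrations ug/mL, one per scheme timepoint.
#' @param scheme a [sampling_scheme()].
#' @param dose_mg dose in the dosage form (mg, > 0).
#' @return A [release_profile()].
#' @export
cumulative_release <- function(concentrations, scheme, dose_mg) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  stop_if_not_scalar_num(dose_mg, "dose_mg", 0, strict = TRUE)
  n <- length(scheme$timepoints)
  if (length(concentrations) != n)
    stop("need one concentration per scheme timepoint", call. = FALSE)
  mass_ug <- numeric(n)
  withdrawn <- 0
  for (i in seq_len(n)) {
    v_i <- if (scheme$replaced) scheme$medium_volume_ml
           else scheme$medium_volume_ml - (i - 1) * scheme$sample_volume_ml
    mass_ug[i] <- concentrations[i] * v_i + withdrawn
    withdrawn <- withdrawn + concentrations[i] * scheme$sample_volume_ml
  }
  release_profile(scheme$timepoints, pmax(100 * mass_ug / (dose_mg * 1000), 0))
}

#' f2 similarity factor of two dissolution profiles
#'
#' The regulatory profile-comparison metric
#' `f2 = 50 * log10(100 * (1 + mean((R_t - T_t)^2))^(-1/2))`
#' over the timepoints shared by both profiles (interpolation is refused:
#' profiles must share >= 3 timepoints). 100 means identical; >= 50 is
#' conventionally "similar".
#'
#' @param reference,test [release_profile()]s (order does not matter:
#'   f2 is symmetric).
#' @param fda_rule if `TRUE`, shared timepoints are truncated one point
#'   beyond the first at which the reference exceeds 85% release
#'   (regulatory convention).
#' @return f2 in percent, with attribute `n_points`.
#' @export
similarity_f2 <- function(reference, test, fda_rule = FALSE) {
  ref <- release_profile(reference$time_h, reference$release_pct)
  tst <- release_profile(test$time_h, test$release_pct)
  shared <- intersect(ref$time_h, tst$time_h)
  if (isTRUE(fda_rule) && length(shared) > 0) {
    r <- ref$release_pct[match(shared, ref$time_h)]
    over <- which(r > 85)
    if (length(over) > 0) shared <- shared[seq_len(min(over[1] + 1L, length(shared)))]
  }
  if (length(shared) < 3L)
    stop("profiles share fewer than 3 timepoints; interpolation is refused",
         call. = FALSE)
  r <- ref$release_pct[match(shared, ref$time_h)]
  t <- tst$release_pct[match(shared, tst$time_h)]
  msd <- mean((r - t)^2)
  f2 <- 50 * log10(100 / sqrt(1 + msd))
  attr(f2, "n_points") <- length(shared)
  f2
}

#' Align and compare penetration and release profiles
#'
#' Linearly interpolates both curves onto the union of their timepoints
#' inside the overlapping time range and reports the per-time difference
#' (penetration% - release%) and the first time its absolute value exceeds
#' `band`.
#'
#' @param pen a `penetration_profile` (wet fraction in \[0, 1\]) or a data
#'   frame with `time_h` and `wet_fraction`.
#' @param rel a [release_profile()] (percent).
#' @param band divergence band in percentage points (default 10).
#' @return List of class `penetration_release_comparison`: `table` (data
#'   frame `time_h, penetration_pct, release_pct, difference_pct`),
#'   `divergence_time_h` (`NA` if the curves never diverge), and
#'   `max_abs_difference_pct`.
#' @export
compare_penetration_release <- function(pen, rel, band = 10) {
  if (!all(c("time_h", "wet_fraction") %in% names(pen)))
    stop("`pen` needs columns time_h and wet_fraction", call. = FALSE)
  rel <- release_profile(rel$time_h, rel$release_pct)
  lo <- max(min(pen$time_h), min(rel$time_h))
  hi <- min(max(pen$time_h), max(rel$time_h))
  if (lo > hi) stop("profiles do not overlap in time", call. = FALSE)
  times <- sort(unique(c(pen$time_h, rel$time_h)))
  times <- times[times >= lo & times <= hi]
  p <- approx(pen$time_h, 100 * pen$wet_fraction, xout = times)$y
  r <- approx(rel$time_h, rel$release_pct, xout = times)$y
  diff_pct <- p - r
  over <- which(abs(diff_pct) > band)
  structure(list(
    table = data.frame(time_h = times, penetration_pct = p,
                       release_pct = r, difference_pct = diff_pct),
    divergence_time_h = if (length(over)) times[over[1]] else NA_real_,
    band_pct = band,
    max_abs_difference_pct = max(abs(diff_pct))),
    class = "penetration_release_comparison")
}

#' @export
print.penetration_release_comparison <- function(x, ...) {
  cat(sprintf("<penetration vs release> max |diff| %.2f%%; divergence (> %g%%) at %s h\n",
              x$max_abs_difference_pct, x$band_pct,
              ifelse(is.na(x$divergence_time_h), "none",
                     format(x$divergence_time_h))))
  invisible(x)
}
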