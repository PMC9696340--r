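#' Gray-value histogram of a volume of interest
#'
#' Equal-width binning of the masked voxels over a fixed gray range, so
#' that histograms taken at different timesteps of one series share bins
#' and their peaks are directly comparable.
#'
#' @param vol a [voxel_volume()].
#' @param mask non-empty [binary_mask()] on the same grid.
#' @param n_bins number of bins (default 256).
#' @param range gray range `c(lo, hi)` shared across the series; default is
#'   the masked range of this volume.
#' @return Object of class `histogram_model`: `bin_edges` (length
#'   `n_bins + 1`), `counts` (summing to the VOI voxel count), `centers`,
#'   `bin_width`.
#' @export
voi_histogram <- function(vol, mask, n_bins = 256L, range = NULL) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(mask, "binary_mask"))
  check_same_grid(vol, mask)
  if (!any(mask$values)) stop("empty mask", call. = FALSE)
  vals <- vol$values[mask$values]
  range <- range %||% base::range(vals)
  if (range[2] <= range[1]) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  idx <- findInterval(vals, edges, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 bin_width = diff(range) / n_bins),
            class = "histogram_model")
}

#' Local maxima of a histogram
#'
#' Modes of a (lightly smoothed) histogram, filtered by relative
#' prominence; used to follow the unimodal -> bimodal -> unimodal evolution
#' of the VOI histogram as brine displaces the dry phase.
#'
#' @param hist a `histogram_model`.
#' @param smooth half-width (bins) of the moving-average smoother.
#' @param min_prominence modes whose smoothed height is below this fraction
#'   of the tallest mode, or that do not rise by this fraction above the
#'   deepest valley separating them from a taller mode, are discarded.
#' @return Integer vector of bin indices of the retained modes.
#' @export
histogram_modes <- function(hist, smooth = 3L, min_prominence = 0.2) {
  stopifnot(inherits(hist, "histogram_model"))
  x <- as.numeric(hist$counts)
  if (smooth > 0) {
    kern <- rep(1, 2 * smooth + 1)
    x <- as.numeric(stats::filter(c(rep(x[1], smooth), x,
                                    rep(x[length(x)], smooth)),
                                  kern / sum(kern), sides = 2))
    x <- x[(smooth + 1):(smooth + length(hist$counts))]
  }
  n <- length(x)
  cand <- which(x > c(-Inf, x[-n]) & x >= c(x[-1], -Inf))
  cand <- cand[x[cand] >= min_prominence * max(x)]
  if (length(cand) <= 1L) return(cand)
  # prominence: height above the deepest valley towards a taller mode
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    taller <- cand[x[cand] > x[p]]
    if (length(taller) == 0L) { keep[i] <- TRUE; next }
    valley <- min(vapply(taller, function(q)
      min(x[seq(min(p, q), max(p, q))]), numeric(1)))
    keep[i] <- (x[p] - valley) >= min_prominence * max(x)
  }
  cand[keep]
}

#' Fit a Gaussian component to a histogram window
#'
#' Nonlinear least squares of `weight * bin_width * dnorm(center, mean,
#' sd)` against the bin counts inside the window; `weight` is therefore the
#' voxel count attributed to the component.
#'
#' @param hist a `histogram_model`.
#' @param window gray range `c(lo, hi)` to fit within (default: all bins);
#'   must contain at least 5 nonzero bins.
#' @return Object of class `gaussian_component`: `mean`, `sd`, `weight`,
#'   plus fit diagnostics (`converged`, `rss`).
#' @export
fit_gaussian <- function(hist, window = NULL) {
  stopifnot(inherits(hist, "histogram_model"))
  window <- window %||% range(hist$bin_edges)
  sel <- hist$centers >= window[1] & hist$centers <= window[2]
  x <- hist$centers[sel]
  y <- hist$counts[sel]
  if (sum(y > 0) < 5L)
    stop("window must contain at least 5 nonzero bins", call. = FALSE)
  w0 <- sum(y)
  m0 <- sum(x * y) / w0
  s0 <- sqrt(max(sum((x - m0)^2 * y) / w0, (hist$bin_width / 2)^2))
  bw <- hist$bin_width
  fit <- try(minpack.lm::nlsLM(
    y ~ w * bw * dnorm(x, m, s),
    start = list(w = w0, m = m0, s = s0),
    lower = c(w = 1e-12, m = window[1] - 10 * s0, s = bw / 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Gaussian fit failed to converge: ",
         attr(fit, "condition")$message,
         sprintf(" (start mean %.4g, sd %.4g, mass %.4g)", m0, s0, w0),
         call. = FALSE)
  cf <- coef(fit)
  structure(list(mean = unname(cf["m"]), sd = unname(cf["s"]),
                 weight = unname(cf["w"]),
                 converged = fit$convInfo$isConv %||% TRUE,
                 rss = sum(residuals(fit)^2)),
            class = "gaussian_component")
}

#' Gaussian component
#'
#' Plain constructor for a weighted Gaussian histogram component.
#'
#' @param mean,sd,weight component mean and standard deviation (gray
#'   units; `sd > 0`) and mass (voxel count, > 0).
#' @return Object of class `gaussian_component`.
#' @export
gaussian_component <- function(mean, sd, weight) {
  stop_if_not_scalar_num(mean, "mean")
  stop_if_not_scalar_num(sd, "sd", 0, strict = TRUE)
  stop_if_not_scalar_num(weight, "weight", 0, strict = TRUE)
  structure(list(mean = mean, sd = sd, weight = weight,
                 converged = TRUE, rss = 0),
            class = "gaussian_component")
}

#' Intersection threshold of two Gaussian components
#'
#' Gray value, strictly between the two means, where the weighted densities
#' `weight_i * dnorm(x, mean_i, sd_i)` are equal. Voxels at or above the
#' threshold are classified wet (the contrast agent raises attenuation).
#' Closed form: equal-density points solve a quadratic in `x` (linear for
#' equal variances).
#'
#' @param a component with the lower mean (dry phase).
#' @param b component with the higher mean (wet phase); `a$mean < b$mean`
#'   is required.
#' @return The threshold (gray units).
#' @export
gaussian_intersection <- function(a, b) {
  stopifnot(inherits(a, "gaussian_component"), inherits(b, "gaussian_component"))
  if (!(a$mean < b$mean))
    stop("`a$mean` must be strictly below `b$mean`", call. = FALSE)
  # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
  A <- 1 / a$sd^2 - 1 / b$sd^2
  B <- -2 * (a$mean / a$sd^2 - b$mean / b$sd^2)
  C <- a$mean^2 / a$sd^2 - b$mean^2 / b$sd^2 -
    2 * log((a$weight * b$sd) / (b$weight * a$sd))
  if (abs(A) < 1e-12 * (1 / a$sd^2)) {
    if (abs(B) < .Machine$double.eps)
      stop("identical components have no intersection", call. = FALSE)
    roots <- -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0)
      stop("no real intersection between the components", call. = FALSE)
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > a$mean & roots < b$mean]
  if (length(inside) == 0L)
    stop("no density intersection strictly between the means", call. = FALSE)
  inside[1]
}

#' Threshold wet/dry classification
#'
#' Wet = masked voxels with gray >= `threshold`.
#'
#' @param vol a [voxel_volume()].
#' @param mask VOI [binary_mask()].
#' @param threshold finite gray value.
#' @return [binary_mask()] of wet voxels (subset of `mask`).
#' @export
threshold_classify <- function(vol, mask, threshold) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(mask, "binary_mask"))
  check_same_grid(vol, mask)
  stop_if_not_scalar_num(threshold, "threshold")
  binary_mask(mask$values & vol$values >= threshold, vol$voxel_size_um)
}

#' Per-voxel classification features
#'
#' For every foreground (VOI) voxel: its (x, y, z) index, gray value, and
#' exact Euclidean distance (voxel units) to the closest background voxel
#' (the complement of the mask).
#'
#' @param vol a [voxel_volume()].
#' @param mask non-empty VOI [binary_mask()].
#' @return Object of class `voxel_features`: numeric matrix `features` with
#'   columns `x, y, z, gray, edt` (one row per VOI voxel, in linear scan
#'   order) and `index` (linear voxel indices into the volume).
#' @export
extract_features <- function(vol, mask) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(mask, "binary_mask"))
  check_same_grid(vol, mask)
  if (!any(mask$values)) stop("empty mask", call. = FALSE)
  d <- dim(vol$values)
  edt <- array(.edt3d(as.logical(mask$values), as.integer(d)), dim = d)
  idx <- which(mask$values)
  co <- arrayInd(idx, d)
  feats <- cbind(x = co[, 1], y = co[, 2], z = co[, 3],
                 gray = vol$values[idx], edt = edt[idx])
  structure(list(features = feats, index = idx, dim = d,
                 voxel_size_um = vol$voxel_size_um),
            class = "voxel_features")
}

#' Euclidean distance transform
#'
#' Exact EDT of a binary mask: per foreground voxel, the distance (voxel
#' units) to the nearest background voxel; 0 on the background.
#'
#' @param mask a [binary_mask()].
#' @return Numeric 3D array of distances.
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$values)
  array(.edt3d(as.logical(mask$values), as.integer(d)), dim = d)
}

#' Train the wet/dry k-nearest-neighbour classifier
#'
#' Training data are the VOI voxels of the first timestep (all labelled
#' dry) and the last timestep (all labelled wet). Features are
#' standardized per-feature (z-score from the training data); distances
#' are Euclidean in the standardized space. A random `validation_fraction`
#' of the training voxels is held out (seeded) and its misclassification
#' rate reported. `max_train` caps the training set by seeded subsampling
#' to bound the exact brute-force search.
#'
#' Tie-breaks are deterministic: neighbours are ordered by (distance,
#' training index); an evenly split vote falls back to the label of the
#' single nearest neighbour.
#'
#' @param first `voxel_features` of the first timestep (labelled dry).
#' @param last `voxel_features` of the last timestep (labelled wet).
#' @param k neighbour count (default 10).
#' @param validation_fraction held-out fraction (default 0.10).
#' @param seed integer seed for the subsample and the split.
#' @param max_train cap on the training-set size (`Inf` to disable).
#' @return Object of class `wetting_classifier`: standardization constants,
#'   training matrix + labels, `k`, and `validation_error`.
#' @export
train_knn <- function(first, last, k = 10L, validation_fraction = 0.10,
                      seed = 1L, max_train = 20000L) {
  stopifnot(inherits(first, "voxel_features"), inherits(last, "voxel_features"))
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  X <- rbind(first$features, last$features)
  y <- c(rep(0L, nrow(first$features)), rep(1L, nrow(last$features)))
  if (nrow(X) == 0L) stop("empty training data", call. = FALSE)
  n <- nrow(X)
  sel <- if (is.finite(max_train) && n > max_train)
    with_seed(seed, sort(sample.int(n, max_train))) else seq_len(n)
  X <- X[sel, , drop = FALSE]
  y <- y[sel]
  n <- nrow(X)
  centers <- colMeans(X)
  scales <- apply(X, 2, sd)
  scales[scales < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2, centers), 2, scales, `/`)
  n_val <- round(validation_fraction * n)
  val_idx <- if (n_val > 0)
    with_seed(seed + 1L, sort(sample.int(n, n_val))) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (k > length(tr_idx))
    stop(sprintf("k = %d exceeds the training size %d", k, length(tr_idx)),
         call. = FALSE)
  val_err <- NA_real_
  if (n_val > 0) {
    pred <- .knn_predict(Xs[tr_idx, , drop = FALSE], y[tr_idx],
                         Xs[val_idx, , drop = FALSE], k)
    val_err <- mean(pred != y[val_idx])
  }
  structure(list(k = k, centers = centers, scales = scales,
                 train = Xs[tr_idx, , drop = FALSE], labels = y[tr_idx],
                 validation_error = val_err,
                 validation_fraction = validation_fraction, seed = seed),
            class = "wetting_classifier")
}

#' @export
print.wetting_classifier <- function(x, ...) {
  cat(sprintf("<wetting_classifier> k = %d, %d training voxels, validation error %.4f\n",
              x$k, nrow(x$train), x$validation_error))
  invisible(x)
}

#' Predict wet/dry labels for a feature set
#'
#' @param object a `wetting_classifier`.
#' @param features a `voxel_features` object or a numeric feature matrix
#'   with the training columns.
#' @param chunk probes are classified in chunks of this size to bound
#'   memory; chunking does not affect the result.
#' @param ... unused.
#' @return Integer vector (0 = dry, 1 = wet), one per probe row.
#' @export
predict.wetting_classifier <- function(object, features, chunk = 262144L, ...) {
  P <- if (inherits(features, "voxel_features")) features$features else features
  if (!is.matrix(P)) stop("`features` must be a matrix or voxel_features",
                          call. = FALSE)
  Ps <- sweep(sweep(P, 2, object$centers), 2, object$scales, `/`)
  out <- integer(nrow(Ps))
  start <- 1L
  while (start <= nrow(Ps)) {
    end <- min(start + chunk - 1L, nrow(Ps))
    out[start:end] <- .knn_predict(object$train, object$labels,
                                   Ps[start:end, , drop = FALSE], object$k)
    start <- end + 1L
  }
  out
}

#' Classify every timestep of a series
#'
#' Applies a trained [train_knn()] classifier to each VOI voxel of every
#' volume in the series. The coordinate and distance-transform features
#' depend only on the (fixed) VOI mask and are computed once; the gray
#' feature is taken from each timestep.
#'
#' @param clf a `wetting_classifier`.
#' @param series a [scan_series()].
#' @param mask the VOI [binary_mask()] (same grid as the series).
#' @return List of wet [binary_mask()]s, one per timestep.
#' @export
classify_series <- function(clf, series, mask) {
  stopifnot(inherits(clf, "wetting_classifier"),
            inherits(series, "scan_series"), inherits(mask, "binary_mask"))
  check_same_grid(series$volumes[[1]], mask)
  base <- extract_features(series$volumes[[1]], mask)
  feats <- base$features
  lapply(seq_along(series$volumes), function(ti) {
    feats[, "gray"] <- series$volumes[[ti]]$values[base$index]
    lab <- predict(clf, feats)
    wet <- array(FALSE, dim = base$dim)
    wet[base$index[lab == 1L]] <- TRUE
    binary_mask(wet, mask$voxel_size_um)
  })
}

#' Water-penetration profile
#'
#' Fraction of VOI voxels classified wet, per timestep.
#'
#' @param wet_masks list of wet [binary_mask()]s (one per timestep).
#' @param mask the VOI [binary_mask()].
#' @param times_h timepoints in hours (same length as `wet_masks`).
#' @return Data frame of class `penetration_profile` with columns `time_h`
#'   and `wet_fraction` (in \[0, 1\]).
#' @export
penetration_profile <- function(wet_masks, mask, times_h) {
  if (length(wet_masks) == 0L) stop("at least one timestep required", call. = FALSE)
  if (length(times_h) != length(wet_masks))
    stop("`times_h` must match the number of wet masks", call. = FALSE)
  n <- sum(mask$values)
  if (n == 0L) stop("empty VOI mask", call. = FALSE)
  wf <- vapply(wet_masks, function(w) sum(w$values & mask$values) / n,
               numeric(1))
  structure(data.frame(time_h = as.numeric(times_h), wet_fraction = wf),
            class = c("penetration_profile", "data.frame"))
}
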