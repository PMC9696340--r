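test_that("voi_histogram counts masked voxels into shared bins", {
  v <- voxel_volume(array(0.5, dim = c(6, 6, 4)), 10)
  m <- binary_mask(array(rep(c(TRUE, FALSE), 72), dim = c(6, 6, 4)), 10)
  h <- voi_histogram(v, m, n_bins = 64, range = c(0, 1))
  expect_identical(sum(h$counts), sum(m$values))
  expect_identical(sum(h$counts > 0), 1L)
  expect_length(h$bin_edges, 65L)
  expect_error(voi_histogram(v, binary_mask(array(FALSE, dim = c(6, 6, 4)), 10)),
               "empty mask")
})

test_that("mid-dissolution VOI histogram is bimodal with well-separated modes", {
  exp_ <- demo_experiment()
  voi <- exp_$truth$matrix_mask
  gr <- range(vapply(exp_$series$volumes,
                     function(v) range(v$values[voi$values]), numeric(2)))
  mid <- which.min(abs(exp_$truth$wet_fraction_per_time - 0.5))
  h <- voi_histogram(exp_$series$volumes[[mid]], voi, range = gr)
  modes <- histogram_modes(h)
  expect_gte(length(modes), 2L)
  expect_gte(max(diff(sort(modes))), 3L)
})

test_that("fit_gaussian recovers mean, sd and mass from a sampled Gaussian", {
  set.seed(21)
  v <- voxel_volume(array(rnorm(1e6, 100, 5), dim = c(100, 100, 100)), 10)
  m <- binary_mask(array(TRUE, dim = c(100, 100, 100)), 10)
  h <- voi_histogram(v, m, n_bins = 256)
  g <- fit_gaussian(h)
  expect_lt(abs(g$mean - 100), 0.2)
  expect_lt(abs(g$sd - 5), 0.2)
  expect_lt(abs(g$weight - 1e6) / 1e6, 0.02)
  expect_true(g$converged)
  narrow <- list(bin_edges = h$bin_edges, counts = rep(0L, 256),
                 centers = h$centers, bin_width = h$bin_width)
  class(narrow) <- "histogram_model"
  expect_error(fit_gaussian(narrow), "5 nonzero bins")
})

test_that("gaussian_intersection has the closed-form equal-sd midpoint,
           is symmetric, and guards its preconditions", {
  a <- gaussian_component(10, 2, 500)
  b <- gaussian_component(20, 2, 500)
  expect_identical(gaussian_intersection(a, b), 15)
  expect_error(gaussian_intersection(b, a), "strictly below")
  expect_error(gaussian_intersection(a, a), "strictly below")

  set.seed(33)
  for (i in 1:25) {
    a <- gaussian_component(runif(1, 0, 50), runif(1, 0.5, 5),
                            runif(1, 100, 1e5))
    b <- gaussian_component(a$mean + runif(1, 2, 40), runif(1, 0.5, 5),
                            runif(1, 100, 1e5))
    thr <- try(gaussian_intersection(a, b), silent = TRUE)
    if (inherits(thr, "try-error")) next   # no root between means
    ref <- scan_gaussian_intersection(a, b, n = 2e5)
    expect_lt(abs(thr - ref), (b$mean - a$mean) / 2e4)
    # symmetry under reordering by mean
    expect_equal(gaussian_intersection(a, b), thr)
  }
})

test_that("threshold_classify matches the ground truth exactly on the
           noise-free phantom and handles extreme thresholds", {
  exp_ <- clean_experiment()
  voi <- exp_$truth$matrix_mask
  mid <- 2L                                  # partially wetted timestep
  vol <- exp_$series$volumes[[mid]]
  thr <- exp_$spec$mu_matrix + exp_$spec$uplift / 2
  wet <- threshold_classify(vol, voi, thr)
  want <- truth_wet_mask(exp_$truth, exp_$series$times_h[mid]) & voi$values
  expect_identical(wet$values, want)

  expect_false(any(threshold_classify(vol, voi, 2)$values))
  expect_identical(threshold_classify(vol, voi, -1)$values, voi$values)
})

test_that("extract_features reports exact Euclidean distances", {
  d <- c(10, 10, 10)
  # 3x3x3 cube: centre voxel is 2 away from the nearest background voxel
  cube <- array(FALSE, dim = d)
  cube[4:6, 4:6, 4:6] <- TRUE
  v <- voxel_volume(array(0.5, dim = d), 10)
  f <- extract_features(v, binary_mask(cube, 10))
  expect_identical(nrow(f$features), sum(cube))
  centre <- f$features[, "x"] == 5 & f$features[, "y"] == 5 &
    f$features[, "z"] == 5
  expect_identical(unname(f$features[centre, "edt"]), 2)
  corner <- f$features[, "x"] == 4 & f$features[, "y"] == 4 &
    f$features[, "z"] == 4
  expect_identical(unname(f$features[corner, "edt"]), 1)

  set.seed(5)
  for (i in 1:3) {
    m <- array(runif(1000) > 0.4, dim = d)
    if (!any(m) || all(m)) next
    got <- distance_transform(binary_mask(m, 10))
    expect_equal(got, brute_force_dt(m, "euclidean"), tolerance = 1e-12)
  }
})

test_that("KNN predictions equal the exhaustive-distance oracle, including
           distance and vote tie-breaks", {
  set.seed(8)
  # integer-grid features force exact distance ties
  train <- matrix(sample(0:4, 600 * 3, replace = TRUE), ncol = 3)
  labels <- sample(0:1, 600, replace = TRUE)
  probes <- matrix(sample(0:4, 150 * 3, replace = TRUE), ncol = 3)
  for (k in c(1L, 3L, 10L)) {
    got <- dissolvis:::.knn_predict(train * 1.0, as.integer(labels),
                                    probes * 1.0, k)
    expect_identical(got, brute_force_knn(train, labels, probes, k))
  }
})

test_that("train_knn standardizes features, reports a zero validation error for
           separable classes, and rejects oversized k", {
  set.seed(13)
  mk <- function(gray_mu, n = 400) {
    f <- cbind(x = runif(n, 1, 30), y = runif(n, 1, 30), z = runif(n, 1, 10),
               gray = rnorm(n, gray_mu, 0.01), edt = runif(n, 0, 4))
    structure(list(features = f, index = seq_len(n), dim = c(30, 30, 10),
                   voxel_size_um = 10), class = "voxel_features")
  }
  clf <- train_knn(mk(0.2), mk(0.8), k = 10, seed = 2)
  expect_identical(clf$validation_error, 0)
  expect_equal(unname(colMeans(clf$train)), rep(0, 5), tolerance = 0.2)
  expect_error(train_knn(mk(0.2, 5), mk(0.8, 5), k = 50), "exceeds")
})

test_that("KNN validation error sits near the oracle overlap misclassification
           rate for overlapping gray modes", {
  exp_ <- demo_experiment()
  spec <- exp_$spec
  voi <- exp_$truth$matrix_mask
  n <- length(exp_$series$volumes)
  f1 <- extract_features(exp_$series$volumes[[1]], voi)
  fn <- extract_features(exp_$series$volumes[[n]], voi)
  clf <- train_knn(f1, fn, k = 10, seed = 3, max_train = 12000)
  # oracle: classify by likelihood under the true local gray levels
  # (bias field cancelled), i.e. distance to the dry vs wet level
  oracle_rate <- local({
    g1 <- f1$features[, "gray"]; gn <- fn$features[, "gray"]
    dry_mu <- spec$mu_matrix; wet_mu <- spec$mu_matrix + spec$uplift
    thr <- (dry_mu + wet_mu) / 2
    # remove the shared per-voxel shading before comparing to the levels
    bias_hat <- (g1 + gn - dry_mu - wet_mu) / 2
    mean(c((g1 - bias_hat) >= thr, (gn - bias_hat) < thr))
  })
  expect_lt(abs(clf$validation_error - oracle_rate), 0.02)
})

test_that("classify_series recovers the phantom's penetration profile and the
           training-label assumption holds at the endpoints", {
  exp_ <- demo_experiment()
  voi <- shrink_voi_surface(exp_$truth$matrix_mask, 2)
  n <- length(exp_$series$volumes)
  clf <- train_knn(extract_features(exp_$series$volumes[[1]], voi),
                   extract_features(exp_$series$volumes[[n]], voi),
                   k = 10, seed = 4, max_train = 12000)
  wet <- classify_series(clf, exp_$series, voi)
  pen <- penetration_profile(wet, voi, exp_$series$times_h)
  truth <- truth_wet_fraction(exp_$truth, exp_$series$times_h, voi)
  expect_lte(pen$wet_fraction[1], 0.02)
  expect_gte(pen$wet_fraction[n], 0.98)
  expect_true(all(abs(pen$wet_fraction - truth) <= 0.02))
  expect_true(all(diff(pen$wet_fraction) >= -0.01))   # monotone up to jitter
})

test_that("penetration_profile handles the degenerate all-dry / all-wet cases", {
  d <- c(4, 4, 4)
  voi <- binary_mask(array(TRUE, dim = d), 10)
  none <- binary_mask(array(FALSE, dim = d), 10)
  expect_identical(penetration_profile(list(none, none), voi, c(0, 1))$wet_fraction,
                   c(0, 0))
  expect_identical(penetration_profile(list(voi, voi), voi, c(0, 1))$wet_fraction,
                   c(1, 1))
  expect_error(penetration_profile(list(), voi, numeric(0)), "at least one")
})
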