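test_that("phantom_spec validates its invariants", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(target_porosity = 1), "porosity")
  expect_error(phantom_spec(target_porosity = -0.1), ">=")
  expect_error(phantom_spec(mu_brine = 0.2), "mu_brine > mu_matrix")
  expect_error(phantom_spec(tablet_radius_mm = 0), "> 0")
})

test_that("zero-porosity spec yields no pores and porosity exactly 0", {
  spec <- phantom_spec_demo(grid = 32, target_porosity = 0, seed = 1)
  bt <- build_tablet(spec)
  expect_false(any(bt$truth$pore_mask$values))
  por <- compute_porosity(bt$truth$tablet_mask, bt$truth$pore_mask)
  expect_identical(por$porosity, 0)
  expect_identical(bt$truth$matrix_mask$values, bt$truth$tablet_mask$values)
})

test_that("realized porosity hits the target and pores match an independent
           sphere-union rasterization", {
  spec <- phantom_spec_demo(grid = 40, seed = 2)
  bt <- suppressWarnings(build_tablet(spec))
  expect_lt(abs(bt$truth$porosity - spec$target_porosity), spec$porosity_tol)

  # re-rasterize the recorded sphere union over the whole grid
  d <- dim(bt$truth$pore_mask$values)
  co <- arrayInd(seq_len(prod(d)), d)
  oracle <- rep(FALSE, prod(d))
  for (s in seq_len(nrow(bt$truth$pores))) {
    p <- bt$truth$pores[s, ]
    oracle <- oracle | ((co[, 1] - p$x)^2 + (co[, 2] - p$y)^2 +
                          (co[, 3] - p$z)^2 <= p$r_vox^2)
  }
  expect_identical(array(oracle, dim = d), bt$truth$pore_mask$values)
})

test_that("porosity error shrinks (and stays in tolerance) as the grid refines", {
  err <- vapply(c(36, 72), function(g) {
    spec <- phantom_spec_demo(grid = g, seed = 5)
    bt <- suppressWarnings(build_tablet(spec))
    abs(bt$truth$porosity - spec$target_porosity)
  }, numeric(1))
  expect_true(all(err <= 0.005))
  expect_lte(err[2], err[1] + 1e-6)
})

test_that("phantom output is bit-identical under identical spec + seed", {
  spec <- phantom_spec_demo(grid = 32, seed = 9)
  a <- suppressWarnings(build_tablet(spec))
  b <- suppressWarnings(build_tablet(spec))
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$pore_mask$values, b$truth$pore_mask$values)
  ia <- simulate_ingress(a$volume, a$truth, spec, c(0, 2, 5))
  ib <- simulate_ingress(b$volume, b$truth, spec, c(0, 2, 5))
  for (i in 1:3)
    expect_identical(ia$series$volumes[[i]]$values,
                     ib$series$volumes[[i]]$values)
})

test_that("ingress wet fractions are 0 at t=0, 1 after full penetration, and
           match a brute-force voxel count in between", {
  exp_ <- demo_experiment()
  spec <- exp_$spec
  truth <- exp_$truth
  wf <- truth$wet_fraction_per_time
  expect_identical(wf[1], 0)
  expect_identical(wf[length(wf)], 1)   # 7.5 h > R / front_speed
  expect_true(all(diff(wf) >= 0))

  # independent count: matrix voxels whose cylindrical radius > r(t)
  d <- dim(truth$matrix_mask$values)
  co <- arrayInd(which(truth$matrix_mask$values), d)
  rad <- sqrt((co[, 1] - truth$center_vox[1])^2 +
                (co[, 2] - truth$center_vox[2])^2)
  for (ti in seq_along(truth$times_h)) {
    r_vox <- truth$front_radius_per_time_mm[ti] * 1000 / spec$voxel_size_um
    want <- if (r_vox <= 0) 1 else mean(rad > r_vox)
    expect_equal(wf[ti], want)
  }
})

test_that("at t=0 the volume inside the tablet equals dry + noise while the
           background is flooded with brine", {
  spec <- phantom_spec_demo(grid = 32, seed = 3, bias_sd = 0)
  bt <- suppressWarnings(build_tablet(spec))
  ing <- simulate_ingress(bt$volume, bt$truth, spec, c(0, 4))
  v0 <- ing$series$volumes[[1]]$values
  inside <- bt$truth$tablet_mask$values
  # reconstruct the expected t=0 scan: clean config + the same seeded noise
  clean <- array(spec$mu_brine, dim = dim(v0))
  clean[inside] <- bt$volume$values[inside]
  expected <- add_noise(voxel_volume(clean, spec$voxel_size_um),
                        spec$noise_sd, seed = spec$seed + 7919L)
  expected$values[] <- pmin(pmax(expected$values, 0), 1)
  expect_identical(v0, expected$values)
  expect_gt(mean(v0[!inside]), spec$mu_brine - 0.05)
})

test_that("simulate_ingress validates its time vector", {
  exp_ <- clean_experiment()
  expect_error(simulate_ingress(exp_$built$volume, exp_$truth, exp_$spec,
                                numeric(0)), "non-empty")
  expect_error(simulate_ingress(exp_$built$volume, exp_$truth, exp_$spec,
                                c(1, 2)), "start at 0")
  expect_error(simulate_ingress(exp_$built$volume, exp_$truth, exp_$spec,
                                c(0, 2, 2)), "strictly increasing")
})

test_that("beer_lambert obeys the closed form and rejects bad input", {
  expect_identical(beer_lambert(123.4, 0.7, 0), 123.4)
  expect_equal(beer_lambert(1000, log(2) / 10, 10), 500)
  expect_error(beer_lambert(-1, 1, 1), "I_in")
  expect_error(beer_lambert(1, -1, 1), "mu")
  expect_error(beer_lambert(1, 1, -1), "T_")
  # multiplicativity over slabs
  mus <- c(0.1, 0.4, 0.25)
  ts <- c(2, 1, 3)
  seq_I <- Reduce(function(I, i) beer_lambert(I, mus[i], ts[i]),
                  seq_along(mus), accumulate = FALSE, init = 1000)
  expect_equal(seq_I, 1000 * exp(-sum(mus * ts)))
})

test_that("radiograph equals a discretized Beer-Lambert line integral", {
  exp_ <- clean_experiment()
  vol <- exp_$series$volumes[[2]]
  rg <- radiograph(vol, I_in = 2000, axis = "y")
  t_mm <- vol$voxel_size_um / 1000
  i <- 11; k <- 9
  expect_equal(rg[i, k], 2000 * exp(-sum(vol$values[i, , k]) * t_mm))
  expect_equal(dim(rg), dim(vol$values)[c(1, 3)])
})

test_that("add_noise is exact for sd 0, reproducible, and has the stated variance", {
  vol <- voxel_volume(array(0.5, dim = c(50, 50, 50)), 10)
  expect_identical(add_noise(vol, 0, seed = 1)$values, vol$values)
  n1 <- add_noise(vol, 0.05, seed = 42)
  n2 <- add_noise(vol, 0.05, seed = 42)
  expect_identical(n1$values, n2$values)
  resid <- n1$values - vol$values
  expect_gte(length(resid), 1e5)
  expect_lt(abs(var(as.numeric(resid)) / 0.05^2 - 1), 0.05)
  expect_lt(abs(mean(resid)), 1e-3)
})

test_that("simulate_release produces a monotone curve tied to the wetting front
           and survives the quantification round trip", {
  spec <- phantom_spec_demo(grid = 32, seed = 1)
  # zero front speed: nothing wets, nothing releases
  spec0 <- phantom_spec_demo(grid = 32, seed = 1, front_speed_mm_h = 0)
  rel0 <- simulate_release(spec0, abs_noise_sd = 0)
  expect_true(all(rel0$profile$release_pct == 0))

  rel <- simulate_release(spec, abs_noise_sd = 0)
  expect_true(all(diff(rel$profile$release_pct) >= 0))
  expect_equal(tail(rel$profile$release_pct, 1), 100)

  # noise-free round trip through the quantification chain is exact
  calib <- demo_calibration()
  conc <- to_concentration(rel$absorbance$absorbance, calib, warn = FALSE)
  got <- cumulative_release(conc,
                            sampling_scheme(timepoints = rel$profile$time_h),
                            dose_mg = 65.6)
  expect_equal(got$release_pct, rel$profile$release_pct, tolerance = 1e-9)
  expect_error(simulate_release(spec, dose_mg = 0), "dose")
})
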