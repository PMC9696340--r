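test_that("bilateral filter leaves constant volumes unchanged and reduces
           noise variance in flat regions", {
  v <- voxel_volume(array(0.4, dim = c(12, 12, 8)), 10)
  out <- bilateral_filter(v, 1.5, 0.1)
  expect_equal(out$values, v$values, tolerance = 1e-12)

  set.seed(4)
  noisy <- voxel_volume(array(0.4 + rnorm(12^3, 0, 0.03), dim = rep(12, 3)), 10)
  sm <- bilateral_filter(noisy, 1.5, 0.1)
  inner <- sm$values[4:9, 4:9, 4:9]
  expect_lt(var(as.numeric(inner)),
            var(as.numeric(noisy$values[4:9, 4:9, 4:9])))
  expect_error(bilateral_filter(noisy, 0, 0.1), "> 0")
})

test_that("bilateral filter preserves a strong two-level step: plateau means
           within 1% and the maximum-gradient edge unmoved", {
  d <- c(24, 10, 10)
  v <- array(0.2, dim = d)
  v[13:24, , ] <- 0.8                         # step between x = 12 and 13
  set.seed(9)
  v <- v + array(rnorm(prod(d), 0, 0.02), dim = d)
  out <- bilateral_filter(voxel_volume(v, 10), 1.5, 0.08)$values
  expect_lt(abs(mean(out[1:10, , ]) - 0.2) / 0.2, 0.01)
  expect_lt(abs(mean(out[15:24, , ]) - 0.8) / 0.8, 0.01)
  prof <- apply(out, 1, mean)
  expect_equal(which.max(abs(diff(prof))), 12L)
})

test_that("segment_matrix recovers the exact tablet on a noise-free phantom and
           drops detached debris", {
  exp_ <- clean_experiment()
  spec <- exp_$spec
  vol <- exp_$built$volume
  thr <- (spec$mu_background + spec$mu_matrix) / 2
  tab <- segment_matrix(vol, thr, fill_holes = TRUE)
  expect_identical(tab$values, exp_$truth$tablet_mask$values)
  mat <- segment_matrix(vol, thr, fill_holes = FALSE)
  expect_identical(mat$values, exp_$truth$matrix_mask$values)

  # a detached bright speck is removed by the largest-component rule
  v2 <- vol
  v2$values[2, 2, 2] <- spec$mu_matrix
  tab2 <- segment_matrix(v2, thr, fill_holes = TRUE)
  expect_identical(tab2$values, exp_$truth$tablet_mask$values)

  expect_error(segment_matrix(vol, 2), "outside the volume's gray range")
})

test_that("segmenting the filtered noisy phantom reproduces the ground-truth
           tablet with Dice >= 0.99", {
  exp_ <- demo_experiment()
  dry <- add_noise(exp_$built$volume, exp_$spec$noise_sd_dry, seed = 123)
  dsa <- suppressMessages(analyze_dry_scan(dry))
  a <- dsa$tablet_mask$values
  b <- exp_$truth$tablet_mask$values
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice, 0.99)
  expect_lt(abs(dsa$porosity$porosity - exp_$truth$porosity), 0.005)
})

test_that("compute_porosity is an exact voxel-count ratio with guarded inputs", {
  d <- c(2, 2, 2)
  tab <- binary_mask(array(TRUE, dim = d), 10)
  none <- binary_mask(array(FALSE, dim = d), 10)
  expect_identical(compute_porosity(tab, none)$porosity, 0)
  one <- array(FALSE, dim = d); one[1, 1, 1] <- TRUE
  p <- compute_porosity(tab, binary_mask(one, 10))
  expect_identical(p$porosity, 0.125)
  expect_identical(p$porosity * p$tablet_voxels, as.numeric(p$pore_voxels))
  expect_error(compute_porosity(none, none), "empty tablet")
  expect_error(compute_porosity(binary_mask(one, 10), tab), "subset")
})

test_that("registration recovers zero, integer and sub-voxel shifts", {
  # smooth test object: an off-centre Gaussian blob
  d <- c(32, 32, 20)
  co <- arrayInd(seq_len(prod(d)), d)
  blob <- function(cx, cy, cz)
    array(0.1 + 0.8 * exp(-((co[, 1] - cx)^2 + (co[, 2] - cy)^2 +
                              (co[, 3] - cz)^2) / 30), dim = d)
  ref <- voxel_volume(blob(17, 15, 11), 10)

  same <- register_resample(ref, ref)
  expect_lt(max(abs(attr(same, "shift_vox"))), 1e-4)
  expect_equal(same$values, ref$values, tolerance = 1e-3)
  expect_gt(attr(same, "correlation"), 0.999)

  mov_int <- voxel_volume(blob(14, 15, 11), 10)   # ref = mov shifted +3 in x
  reg_int <- register_resample(mov_int, ref)
  expect_equal(attr(reg_int, "shift_vox")[1], 3, tolerance = 0.05)
  expect_equal(attr(reg_int, "shift_vox")[2:3], c(0, 0), tolerance = 0.05)

  mov_sub <- voxel_volume(blob(16.6, 15, 11), 10) # sub-voxel shift of 0.4
  reg_sub <- register_resample(mov_sub, ref)
  expect_lt(abs(attr(reg_sub, "shift_vox")[1] - 0.4), 0.25)

  # structurally unrelated content falls below the correlation floor
  set.seed(77)
  junk <- voxel_volume(array(runif(prod(d)), dim = d), 10)
  expect_error(register_resample(junk, ref, min_correlation = 0.5),
               "registration failure")
})

test_that("registration maps a coarser-voxel volume onto a finer reference grid", {
  exp_ <- clean_experiment()
  fine <- exp_$built$volume
  coarse <- downsample_volume(fine, 2)
  reg <- register_resample(coarse, fine, min_correlation = 0.5)
  expect_identical(dim(reg$values), dim(fine$values))
  expect_gt(attr(reg, "correlation"), 0.8)
})

test_that("downsample_volume averages non-overlapping blocks exactly", {
  v <- array(as.numeric(1:24), dim = c(4, 3, 2))
  got <- downsample_volume(voxel_volume(v / 24, 10), 2)
  expect_equal(got$voxel_size_um, 20)
  expect_identical(dim(got$values), c(2L, 1L, 1L))
  expect_equal(got$values[1, 1, 1], mean(v[1:2, 1:2, 1:2] / 24))
  expect_equal(got$values[2, 1, 1], mean(v[3:4, 1:2, 1:2] / 24))
})

test_that("shrink_voi is anti-extensive, matches the city-block
           distance-transform oracle, and fails on erosion to empty", {
  # solid Euclidean ball
  d <- c(15, 15, 15)
  co <- arrayInd(seq_len(prod(d)), d)
  ball <- array((co[, 1] - 8)^2 + (co[, 2] - 8)^2 + (co[, 3] - 8)^2 <= 36,
                dim = d)
  m <- binary_mask(ball, 10)
  expect_identical(shrink_voi(m, 0)$values, ball)
  for (k in 1:3) {
    er <- shrink_voi(m, k)$values
    expect_true(all(er <= ball))
    # iterated 6-connected erosion keeps exactly the voxels whose
    # city-block distance to the background exceeds k
    dt <- brute_force_dt(ball, metric = "cityblock")
    expect_identical(er, dt > k)
    if (k > 1) expect_true(all(er <= shrink_voi(m, k - 1)$values))
  }
  shell <- binary_mask(array(ball & brute_force_dt(ball, "cityblock") <= 1,
                             dim = d), 10)
  expect_error(shrink_voi(shell, 1), "iteration 1")
  expect_error(shrink_voi(m, -1), ">= 0")
})

test_that("surface shrinking removes the outer rim only, not shells around
           internal pores", {
  exp_ <- clean_experiment()
  matrix_m <- exp_$truth$matrix_mask
  got <- shrink_voi_surface(matrix_m, 2)
  want <- binary_mask(shrink_voi(exp_$truth$tablet_mask, 2)$values &
                        matrix_m$values, matrix_m$voxel_size_um)
  expect_identical(got$values, want$values)
  expect_true(all(got$values <= matrix_m$values))
  # plain erosion of the porous matrix keeps far fewer voxels
  expect_gt(sum(got$values), sum(shrink_voi(matrix_m, 2)$values))
})
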