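test_that("axis densification fills points at uniform arc length", {
  straight <- axis_model(rbind(c(0, 0, 0), c(0, 44, 0)))
  pts <- interpolate_axis_points(straight, 4.5)
  expect_equal(nrow(pts), 10)   # floor(44 / 4.5) + 1
  expect_equal(diff(pts[, 2]), rep(4.5, 9), tolerance = 1e-9)
  ## spacing equal to the length keeps only the endpoints
  ends <- interpolate_axis_points(straight, 44)
  expect_equal(nrow(ends), 2)
  expect_equal(ends[2, ], c(0, 44, 0))
  ## spacing beyond the length degrades to a single point with a warning
  expect_warning(one <- interpolate_axis_points(straight, 60), "spacing")
  expect_equal(nrow(one), 1)
  ## bent two-segment axis: uniform arc-length spacing; the one chord that
  ## crosses the corner is shorter than the arc, all others equal it
  bent <- axis_model(rbind(c(0, 0, 0), c(0, 20, 0), c(10, 20, 0)))
  pts_b <- interpolate_axis_points(bent, 3)
  expect_equal(nrow(pts_b), 11)  # floor(30 / 3) + 1
  d <- sqrt(rowSums((pts_b[-1, ] - pts_b[-nrow(pts_b), ])^2))
  crosses <- which(pts_b[-1, 1] > 0 & pts_b[-nrow(pts_b), 1] == 0 &
                     pts_b[-nrow(pts_b), 2] < 20)
  expect_equal(d[-crosses], rep(3, length(d) - length(crosses)),
               tolerance = 1e-6)
  expect_true(all(d[crosses] < 3))
})

test_that("subvolume extraction drops clipped points and centers on voxels", {
  truth <- tube_chunk_volume()
  tomo <- bmtsim:::new_tomogram(truth, 0.8)
  pts <- cbind(0, seq(-4, 4, length.out = 5), 0)
  set <- extract_subvolumes(tomo, pts, box_nm = 8)
  expect_equal(length(set$volumes), 5)
  ## the center voxel of each cube is the tomogram voxel at the point
  half <- (set$box_voxels + 1) / 2
  d <- dim(truth); ctr <- (d + 1) / 2
  for (i in seq_along(set$volumes)) {
    cv <- round(pts[i, ] / 0.8 + ctr)
    expect_equal(set$volumes[[i]][half, half, half],
                 truth[cv[1], cv[2], cv[3]])
  }
  ## an edge point is dropped with a warning; all-clipped errors
  expect_warning(
    set2 <- extract_subvolumes(tomo, rbind(pts, c(0, 9.6, 0)), box_nm = 8),
    "dropped")
  expect_equal(length(set2$volumes), 5)
  expect_error(
    suppressWarnings(extract_subvolumes(tomo, matrix(c(0, 50, 0), 1), box_nm = 8)),
    "clipped")
})

test_that("alignment of identical subvolumes is the identity", {
  truth <- tube_chunk_volume()
  set <- as_subvolume_set(replicate(3, truth, simplify = FALSE))
  res <- align_and_average(set, rotation_limit_deg = 6,
                           translation_limit_nm = 1.6, rotation_step_deg = 2)
  expect_true(all(res$transforms$rotation_deg == 0))
  expect_true(all(res$transforms[, c("shift_x_nm", "shift_y_nm", "shift_z_nm")] == 0))
  expect_equal(res$average, truth, tolerance = 1e-9)
})

test_that("constrained alignment recovers applied rotations within 2 degrees", {
  truth <- tube_chunk_volume()
  applied <- c(-10, -5, 0, 5, 10)
  vols <- lapply(applied, function(a)
    bmtsim:::rotate_about_y(truth, bmtsim:::deg2rad(a)))
  set <- as_subvolume_set(vols)
  res <- align_and_average(set, rotation_limit_deg = 15,
                           translation_limit_nm = 0.8,
                           rotation_step_deg = 1, reference = truth,
                           max_iter = 3)
  ## the recovered transform is the correction, i.e. minus the applied spin
  expect_true(all(abs(res$transforms$rotation_deg + applied) <= 2))
  ## the search respects the published +/-15 degree limit
  expect_true(all(abs(res$transforms$rotation_deg) <= 15))
})

test_that("averaging independent noise shrinks the background like sqrt(n)", {
  truth <- tube_chunk_volume()
  sd_n <- stats::sd(truth)
  vols <- with_seed_list(25, truth, sd_n)
  set <- as_subvolume_set(vols)
  res <- align_and_average(set, rotation_limit_deg = 0,
                           translation_limit_nm = 0, max_iter = 1)
  resid_one <- stats::sd(vols[[1]] - truth)
  resid_avg <- stats::sd(res$average - truth)
  expect_equal(resid_one / resid_avg, 5, tolerance = 0.2 * 5)
})

test_that("cross-section consistency separates straight from scrambled", {
  ## long enough that the probed slabs stay clear of the staggered ends
  truth <- tube_chunk_volume(box_nm = 26, tube_length_nm = 17.6)
  res_straight <- align_and_average(as_subvolume_set(replicate(3, truth,
                                                               simplify = FALSE)),
                                    rotation_limit_deg = 0,
                                    translation_limit_nm = 0, max_iter = 1)
  rep_s <- average_cross_section_consistency(res_straight,
                                             positions_nm = c(-2, 0, 2),
                                             r_expected_nm = ring_radius(5, 4.6))
  expect_equal(rep_s$verdict, "straight")
  ## single position is trivially consistent
  rep_1 <- average_cross_section_consistency(res_straight, positions_nm = 0,
                                             r_expected_nm = ring_radius(5, 4.6))
  expect_equal(rep_1$verdict, "straight")
  ## scrambled control: average of copies spun far beyond the limit
  spun <- lapply(c(0, 100, 200), function(a)
    bmtsim:::rotate_about_y(truth, bmtsim:::deg2rad(a)))
  res_spun <- align_and_average(as_subvolume_set(spun),
                                rotation_limit_deg = 0,
                                translation_limit_nm = 0, max_iter = 1)
  rep_x <- average_cross_section_consistency(res_spun,
                                             positions_nm = c(-2, 0, 2),
                                             r_expected_nm = ring_radius(5, 4.6))
  a_straight <- mean(abs(rep_s$profile$signed))
  a_spun <- mean(abs(rep_x$profile$signed))
  expect_lt(a_spun, a_straight)
})
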