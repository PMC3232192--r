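test_that("cross-section extraction averages planes perpendicular to the axis", {
  am <- annulus_map(n = 40)
  tomo <- bmtsim:::new_tomogram(am$data, am$voxel_size_nm)
  one <- extract_cross_section(tomo, slab_nm = am$voxel_size_nm)
  expect_equal(one$slab_nm, am$voxel_size_nm)
  ## annular before the wedge: side and top walls equally strong
  pk <- wall_peak_intensities(one, 3.9)
  expect_equal(pk$topbottom / pk$side, 1, tolerance = 0.05)
  ## after the wedge: side arcs dominate
  pk_w <- wall_peak_intensities(extract_cross_section(wedge_tomogram(am, 60),
                                                      slab_nm = 10), 3.9)
  expect_lt(pk_w$topbottom / pk_w$side, 0.85)
  ## straight tube: different slab lengths give the same section
  spec <- quick_spec(tube_length_nm = 52.8)
  model <- orient_model(build_tube(spec), tilt_geometry())
  wt <- wedge_tomogram(rasterize(model, 0.5), 60)
  s_short <- extract_cross_section(wt, slab_nm = 20)
  s_long <- extract_cross_section(wt, slab_nm = 44)
  expect_gt(stats::cor(as.vector(s_short$data), as.vector(s_long$data)), 0.95)
  expect_error(extract_cross_section(tomo,
                                     axis = list(point = c(100, 0, 0),
                                                 direction = c(0, 1, 0))),
               "outside")
})

test_that("diameter measurement finds wall peaks to sub-pixel precision", {
  ## continuous annulus: peak separation equals the ring diameter
  am <- annulus_map(n = 48, radius_nm = 3.9)
  sec <- extract_cross_section(bmtsim:::new_tomogram(am$data, 0.5), slab_nm = 10)
  dm <- measure_diameter(sec)
  expect_equal(dm$status, "ok")
  expect_equal(dm$diameter_nm, 7.8, tolerance = 0.25)
  ## blank section is unresolved
  blank <- structure(list(data = matrix(0, 20, 20), pixel_size_nm = 0.5,
                          slab_nm = 1, axes = c("lateral", "beam")),
                     class = "cross_section")
  expect_equal(measure_diameter(blank)$status, "unresolved")
})

test_that("5-pf wall-peak separation matches a 1-D mixture oracle", {
  ## independent oracle: lateral profile of the blob mixture along the
  ## beam-center row, computed directly from the lattice geometry
  spec <- quick_spec()
  r <- ring_radius(5, 4.6)
  phi <- 2 * pi * (0:4) / 5
  xs <- r * cos(phi); zs <- -r * sin(phi)
  sigma <- 1.2
  lat <- seq(-8, 8, by = 0.01)
  prof <- colSums(exp(-(outer(xs, lat, `-`))^2 / (2 * sigma^2)) *
                  exp(-zs^2 / (2 * sigma^2)))
  pk <- which(diff(sign(diff(prof))) == -2) + 1
  oracle_sep <- diff(range(lat[pk]))
  ## measured through the imaging pipeline (no wedge: geometry check)
  model <- orient_model(build_tube(spec), tilt_geometry())
  map <- rasterize(model, 0.5)
  sec <- extract_cross_section(bmtsim:::new_tomogram(map$data, 0.5),
                               slab_nm = 27)
  dm <- measure_diameter(sec)
  expect_equal(dm$status, "ok")
  expect_equal(dm$diameter_nm, oracle_sep, tolerance = 0.5)
})

test_that("left-right asymmetry scores behave as a mirror statistic", {
  ## mirror-symmetric section scores zero under both metrics
  n <- 41
  ax <- (seq_len(n) - 21) * 0.5
  rr <- sqrt(outer(ax^2, ax^2, `+`))
  ring <- exp(-((rr - 3.9)^2) / (2 * 0.8^2))
  sec <- structure(list(data = ring, pixel_size_nm = 0.5, slab_nm = 1,
                        axes = c("lateral", "beam")), class = "cross_section")
  expect_equal(left_right_asymmetry(sec, 3.9)$score, 0, tolerance = 1e-9)
  expect_equal(left_right_asymmetry(sec, 3.9, metric = "pointwise")$score, 0,
               tolerance = 1e-9)
  ## intensity scaling leaves the score unchanged
  sec10 <- sec; sec10$data <- 10 * sec$data
  skew <- ring; skew[ax > 2, ] <- skew[ax > 2, ] * 2
  sec_skew <- sec; sec_skew$data <- skew
  sec_skew10 <- sec; sec_skew10$data <- 10 * skew
  expect_equal(left_right_asymmetry(sec_skew10, 3.9)$score,
               left_right_asymmetry(sec_skew, 3.9)$score, tolerance = 1e-12)
  ## translation invariance with re-centering
  shifted <- sec_skew
  shifted$data <- rbind(matrix(0, 4, n), skew[1:(n - 4), ])
  expect_equal(left_right_asymmetry(shifted, 3.9)$score,
               left_right_asymmetry(sec_skew, 3.9)$score, tolerance = 0.02)
})

test_that("classification rejects degenerate candidates and even-only sets", {
  protocol <- pf_protocol(voxel_size_nm = 0.6, tube_length_nm = 26.4)
  expect_error(classify_protofilament_number(
    list(quick_spec(4), quick_spec(4)), protocol, c(0, 9)), "distinct")
  cls46 <- classify_protofilament_number(
    list(quick_spec(4, 26.4), quick_spec(6, 26.4)), protocol,
    rotations_deg = c(0, 18, 36))
  expect_false(any(cls46$summary$asymmetric))
  expect_true(is.na(cls46$inferred_n_pf))
})

test_that("axial asymmetry profiles flag too-short tubes and full windows", {
  spec <- quick_spec(tube_length_nm = 52.8)
  model <- orient_model(build_tube(spec), tilt_geometry())
  wt <- wedge_tomogram(rasterize(model, 0.5), 60)
  expect_error(asymmetry_profile_along_axis(wt, window_nm = 40, step_nm = 40),
               ">= 2 windows")
  prof <- asymmetry_profile_along_axis(wt, window_nm = 12, step_nm = 10,
                                       r_expected_nm = model$ring_radius_nm)
  expect_gte(nrow(prof$profile), 2)
  ## a single full-length window equals the global score
  glob <- left_right_asymmetry(extract_cross_section(wt, slab_nm = 44),
                               r_expected_nm = model$ring_radius_nm)
  sec1 <- extract_cross_section(wt, slab_nm = 44)
  expect_equal(left_right_asymmetry(sec1,
                                    r_expected_nm = model$ring_radius_nm)$score,
               glob$score)
})
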