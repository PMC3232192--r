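test_that("rasterize conserves mass and centers blobs", {
  model <- build_tube(quick_spec(tube_length_nm = 52.8))
  map <- rasterize(model, 0.5)
  expect_equal(sum(map$data) * 0.5^3, 60, tolerance = 0.005 * 60)
  ## single subunit: maximum at the origin, radially symmetric
  m1 <- build_tube(tube_lattice_spec(n_pf = 1, tube_length_nm = 8.8))
  one <- m1
  one$placements <- one$placements[1, ]
  one$placements$z <- 0
  map1 <- rasterize(one, 0.5, box_nm = c(12, 12, 12))
  d <- dim(map1$data)
  peak <- which(map1$data == max(map1$data), arr.ind = TRUE)[1, ]
  ## even-dimension grid: the origin falls between voxels, so the peak
  ## sits within half a voxel of the geometric center
  expect_true(all(abs(peak - (d + 1) / 2) <= 0.5))
  expect_equal(map1$data[peak[1] + 3, peak[2], peak[3]],
               map1$data[peak[1], peak[2] + 3, peak[3]], tolerance = 1e-9)
  ## sphere kernel also integrates to unit mass per subunit
  maps <- rasterize(one, 0.5, box_nm = c(12, 12, 12), kernel = "sphere")
  expect_equal(sum(maps$data) * 0.5^3, 1, tolerance = 1e-9)
  ## too-small box names the clipped subunits
  expect_error(rasterize(model, 0.5, box_nm = c(5, 5, 5)), "clipped")
})

test_that("orient_model follows the lab-frame conventions", {
  model <- build_tube(quick_spec())
  g0 <- tilt_geometry()
  lab <- orient_model(model, g0)
  expect_equal(lab$axis_lab, c(0, 1, 0), tolerance = 1e-12)
  ## model z becomes lab y
  expect_equal(sort(lab$placements$y), sort(model$placements$z),
               tolerance = 1e-9)
  ## 90 degrees to the tilt axis: tube along x
  g90 <- tilt_geometry(angle_to_tilt_axis_deg = 90)
  expect_equal(orient_model(model, g90)$axis_lab, c(1, 0, 0),
               tolerance = 1e-12)
  ## C5 lattice symmetry: a 72-degree spin carries protofilament j onto
  ## the azimuth of protofilament j+1, shifted down by one stagger (the
  ## finite tube is congruent up to that axial shift)
  g72 <- tilt_geometry(rotation_about_tube_axis_deg = 72)
  a <- orient_model(model, g0)$placements
  b <- orient_model(model, g72)$placements
  for (j in 0:3) {
    rot_j <- b[b$pf == j, ]
    orig_next <- a[a$pf == j + 1, ]
    expect_equal(rot_j$x, orig_next$x, tolerance = 1e-9)
    expect_equal(rot_j$z, orig_next$z, tolerance = 1e-9)
    expect_equal(rot_j$y, orig_next$y - 0.88, tolerance = 1e-9)
  }
})

test_that("tilt-series projection is a mass-preserving line integral", {
  map <- rasterize(orient_model(build_tube(quick_spec()), tilt_geometry()), 0.5)
  geom <- tilt_geometry(-60, 60, 10)
  ts <- project_tilt_series(map, geom)
  expect_equal(dim(ts$images)[3], length(geom$angles_deg))
  mass <- sum(map$data) * map$voxel_size_nm^3
  for (a in seq_along(geom$angles_deg)) {
    expect_equal(sum(ts$images[, , a]) * ts$pixel_size_nm^2, mass,
                 tolerance = 0.01 * mass,
                 label = sprintf("mass at %d deg", geom$angles_deg[a]))
  }
  ## a centered symmetric blob projects to a centrally symmetric image
  bm <- blob_map()
  p0 <- project_tilt_series(bm, tilt_geometry(-1, 1, 1))$images[, , 2]
  expect_equal(p0, p0[rev(seq_len(nrow(p0))), rev(seq_len(ncol(p0)))],
               tolerance = 1e-9)
  ## 5-pf tube projected along the beam: the wall-line positions match an
  ## independent 1-D Gaussian-mixture oracle built from the ring geometry
  proj <- tube_projection(quick_spec())
  prof <- rowMeans(proj)
  pk <- which(diff(sign(diff(prof))) == -2) + 1
  pk <- pk[prof[pk] > 0.3 * max(prof)]
  sep <- diff(range(pk)) * 0.4
  r <- ring_radius(5, 4.6)
  xs <- r * cos(2 * pi * (0:4) / 5)
  lat <- seq(-8, 8, by = 0.01)
  oracle <- colSums(exp(-(outer(xs, lat, `-`))^2 / (2 * 1.2^2)))
  opk <- which(diff(sign(diff(oracle))) == -2) + 1
  opk <- opk[oracle[opk] > 0.3 * max(oracle)]
  expect_equal(sep, diff(range(lat[opk])), tolerance = 0.5)
})

test_that("CTF evaluation matches the closed form and its brute-force scan", {
  expect_equal(electron_wavelength_nm(300), 0.00197, tolerance = 1e-3)
  ctf <- ctf_params()
  expect_equal(ctf_eval(ctf, 0), -0.07)
  ## first zero: root bracketing agrees with a dense scan
  f <- seq(1e-4, 1, by = 1e-5)
  v <- ctf_eval(ctf, f)
  scan_zero <- f[which(v[-1] * v[-length(v)] <= 0)[1]]
  expect_equal(ctf_first_zero(ctf), scan_zero, tolerance = 1e-4)
  ## zero amplitude contrast: zero transfer at DC, image mean goes to zero
  ctf0 <- ctf_params(amplitude_contrast = 0)
  img <- matrix(runif(48 * 48), 48, 48)
  series <- bmtsim:::new_tilt_series(array(img, c(48, 48, 1)), 0, 0.5)
  out <- apply_ctf(series, ctf0)
  expect_equal(mean(out$images[, , 1]), 0, tolerance = 1e-10)
})

test_that("Fourier resampling decimates band-limited images cleanly", {
  img <- matrix(rnorm(60 * 80), 60, 80)
  series <- bmtsim:::new_tilt_series(array(img, c(60, 80, 1)), 0, 0.096)
  out <- resample_series(series, 10)
  expect_equal(out$pixel_size_nm, 0.96)
  expect_equal(dim(out$images)[1:2], c(6, 8))
  expect_equal(mean(out$images), mean(img), tolerance = 1e-12)
  expect_identical(resample_series(series, 1), series)
  const <- bmtsim:::new_tilt_series(array(3, c(20, 20, 1)), 0, 0.5)
  expect_equal(resample_series(const, 2)$images[, , 1],
               matrix(3, 10, 10), tolerance = 1e-12)
  expect_error(resample_series(series, 7), "does not divide")
  ## crop-then-pad is the identity on band-limited input
  bl <- bmtsim:::fourier_resize(bmtsim:::fourier_resize(img, c(30, 40)),
                                c(60, 80))
  bl2 <- bmtsim:::fourier_resize(bmtsim:::fourier_resize(bl, c(30, 40)),
                                 c(60, 80))
  expect_lt(max(abs(bl2 - bl)) / max(abs(bl)), 1e-6)
})

test_that("additive noise hits the requested SNR and is reproducible", {
  img <- matrix(sin(seq_len(256) / 5), 256, 256)
  series <- bmtsim:::new_tilt_series(array(img, c(256, 256, 1)), 0, 1)
  expect_identical(add_noise(series, Inf, 1), series)
  noisy <- add_noise(series, 2, seed = 7)
  emp_snr <- stats::var(as.vector(img)) /
    stats::var(as.vector(noisy$images[, , 1] - img))
  expect_equal(emp_snr, 2, tolerance = 0.1 * 2)
  expect_identical(add_noise(series, 2, seed = 7), noisy)
  expect_false(identical(add_noise(series, 2, seed = 8)$images,
                         noisy$images))
})
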