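test_that("power spectra have fiber-diffraction layout and symmetry", {
  ## pure axial cosine stripe: one off-DC peak pair at 1/period
  period <- 4.4; pix <- 0.5
  y <- (seq_len(128) - 1) * pix
  img <- matrix(rep(cos(2 * pi * y / period), each = 64), 64, 128)
  ps <- power_spectrum(img, pix)
  ## centrosymmetry of the magnitudes (even-dimension grids pair all
  ## frequencies except the unmatched Nyquist row/column)
  m <- ps$mag[-1, -1]
  expect_equal(m, m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))],
               tolerance = 1e-10)
  ## the peak sits on the meridian at the stripe frequency
  mer <- ps$mag[ps$dc[1], ]
  mer[ps$dc[2]] <- 0
  pk <- which.max(mer)
  f_pk <- (pk - ps$dc[2]) * ps$freq_step_invnm[2]
  expect_equal(abs(f_pk), 1 / period, tolerance = ps$freq_step_invnm[2])
})

test_that("estimate_repeat reads the subunit repeat off the layer line", {
  ## synthetic stripe at 5.0 nm
  pix <- 0.5
  y <- (seq_len(128) - 1) * pix
  stripe <- matrix(rep(cos(2 * pi * y / 5), each = 64), 64, 128) +
    matrix(rep(exp(-((seq_len(64) - 32)^2) / 50), times = 128), 64, 128)
  est <- estimate_repeat(power_spectrum(stripe, pix))
  expect_equal(est$status, "ok")
  expect_lt(abs(est$repeat_nm - 5), est$uncertainty_nm)
  ## white noise carries no layer line
  set.seed(3)
  noise <- matrix(rnorm(64 * 128), 64, 128)
  expect_equal(estimate_repeat(power_spectrum(noise, pix))$status,
               "no layer line")
})

test_that("repeat recovery tracks the generator rise from 3.5 to 5.5 nm", {
  for (rise in c(3.5, 4.4, 5.5)) {
    spec <- tube_lattice_spec(axial_stagger_nm = rise / 5,
                              dimer_rise_nm = 2 * rise,
                              tube_length_nm = 16 * rise)
    est <- estimate_repeat(power_spectrum(tube_projection(spec), 0.4))
    expect_equal(est$status, "ok", label = sprintf("status at rise %.1f", rise))
    expect_lt(abs(est$repeat_nm - rise), est$uncertainty_nm)
  }
})

test_that("the helical selection rule yields the published Bessel families", {
  spec <- quick_spec()
  expect_identical(allowed_bessel_orders(1, spec, 8), c(-4L, 1L, 6L))
  expect_identical(allowed_bessel_orders(0, spec, 8), c(-5L, 0L, 5L))
  ## N = 1: the congruence admits every order; within |n| <= 1 that is -1, 0, 1
  s1 <- tube_lattice_spec(n_pf = 1, tube_length_nm = 30)
  expect_identical(allowed_bessel_orders(1, s1, 1), c(-1L, 0L, 1L))
})

test_that("Bessel first maxima are located to 1e-6", {
  expect_identical(bessel_first_max(0), 0)
  ## frozen from a dense brute-force scan of J1 refined by golden section
  expect_equal(bessel_first_max(1), 1.841184, tolerance = 1e-6)
  xs <- vapply(c(1, 4, 5, 6), bessel_first_max, numeric(1))
  expect_true(all(diff(xs) > 0))
  ## independent check: J1 derivative changes sign at the reported maximum
  x1 <- bessel_first_max(1)
  expect_gt(besselJ(x1 - 1e-4, 1), besselJ(x1, 1) - 1e-8)
  expect_gt(besselJ(x1, 1), besselJ(x1 + 1e-3, 1))
})

test_that("layer-line predictions use the outer-radius convention", {
  spec <- quick_spec()
  pred <- predict_layer_line_pattern(spec, "outer")
  expect_equal(unique(pred$radius_nm), ring_radius(5, 4.6) + 2.0)
  j1 <- pred[pred$layer_index == 1 & pred$order == 1, ]
  expect_equal(j1$radial_frequency_invnm, 1.8412 / (2 * pi * 5.913),
               tolerance = 1e-3)
  q1 <- pred[pred$layer_index == 1, ]
  expect_identical(sort(q1$order), allowed_bessel_orders(1, spec, 8))
  expect_lt(q1$radial_frequency_invnm[q1$order == 1],
            q1$radial_frequency_invnm[q1$order == 6])
})

test_that("spot matching finds J1 and tracks rotation-dependent asymmetry", {
  spec <- tube_lattice_spec(tube_length_nm = 70.4)
  proj <- tube_projection(spec)
  ps <- power_spectrum(proj, 0.4)
  pred <- predict_layer_line_pattern(spec, "outer")
  rep_match <- match_spots(ps, pred, tolerance_invnm = 0.02)
  j1 <- rep_match$matches[rep_match$matches$layer_index == 1 &
                          rep_match$matches$order == 1, ]
  expect_true(j1$matched)
  ## rotating the tube about its axis moves the layer-line asymmetry
  proj_rot <- {
    model <- orient_model(build_tube(spec),
                          tilt_geometry(rotation_about_tube_axis_deg = 36))
    map <- rasterize(model, 0.4)
    project_tilt_series(map, tilt_geometry(-1, 1, 1))$images[, , 2]
  }
  asym0 <- rep_match$layer_asymmetry
  asym36 <- match_spots(power_spectrum(proj_rot, 0.4), pred,
                        tolerance_invnm = 0.02)$layer_asymmetry
  a0 <- asym0$meridian_asymmetry[asym0$layer_index == 1]
  a36 <- asym36$meridian_asymmetry[asym36$layer_index == 1]
  expect_gt(abs(a0 - a36), 1e-4)
  ## empty prediction, empty report
  empty <- match_spots(ps, data.frame())
  expect_equal(nrow(empty$matches), 0)
})

test_that("layer-line power sits off-meridian for helical tubes only", {
  meridian_split <- function(stagger) {
    spec <- tube_lattice_spec(axial_stagger_nm = stagger,
                              tube_length_nm = 70.4)
    ps <- power_spectrum(tube_projection(spec), 0.4)
    est <- estimate_repeat(ps)
    col <- ps$dc[2] + round(est$axial_frequency_invnm / ps$freq_step_invnm[2])
    prof <- rowMeans(ps$mag[, (col - 1):(col + 1)])^2
    mer <- abs(seq_along(prof) - ps$dc[1]) <= 2
    c(on = max(prof[mer]), off = max(prof[!mer]))
  }
  helical <- meridian_split(0.88)
  expect_gt(helical["off"], helical["on"])
  rings <- meridian_split(1e-9)   # ring stacking, no helical climb
  expect_gt(rings["on"], rings["off"])
})
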