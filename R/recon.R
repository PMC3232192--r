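new_tomogram <- function(data, voxel_size_nm, provenance = list()) {
  structure(list(data = data, voxel_size_nm = voxel_size_nm,
                 provenance = provenance),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("tomogram %d x %d x %d, voxel %.3f nm (%s)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              if (length(x$provenance)) paste(names(x$provenance), collapse = ", ")
              else "no provenance"))
  invisible(x)
}

#' Weighted backprojection reconstruction
#'
#' Each image is ramp-filtered along the direction perpendicular to the
#' tilt axis (|f| weighting with a Hann rolloff ending at
#' `rolloff_frac` x Nyquist, to suppress ringing) and smeared back through
#' the volume along its beam direction. A tilt range short of +/-90
#' degrees leaves the missing wedge: reconstructed points elongate along
#' the beam (z) and the top and bottom walls of tubes fade, leaving the
#' two facing side arcs seen in cryotomograms of these tubes.
#'
#' @param series a `tilt_series` with angle metadata.
#' @param thickness_voxels output extent along the beam axis; defaults to
#'   the image x-dimension.
#' @param rolloff_frac Hann rolloff end as a fraction of Nyquist.
#' @return a `tomogram` with dims (nx, ny, thickness).
#' @export
weighted_backprojection <- function(series, thickness_voxels = NULL,
                                    rolloff_frac = 0.9) {
  stopifnot(inherits(series, "tilt_series"))
  if (is.null(series$angles_deg) || length(series$angles_deg) < 3)
    stop("tilt series must carry at least 3 tilt angles")
  d <- dim(series$images)
  nx <- d[1]; ny <- d[2]; na <- d[3]
  nz <- if (is.null(thickness_voxels)) nx else as.integer(thickness_voxels)
  ## filter on a 2x zero-padded axis to avoid circular-convolution wrap
  npad <- 2L * nx
  fx <- fft_freq(npad, series$pixel_size_nm)
  f_ny <- 1 / (2 * series$pixel_size_nm)
  w <- 0.5 * (1 + cos(pi * pmin(abs(fx) / (rolloff_frac * f_ny), 1)))
  H <- abs(fx) * w
  dth <- deg2rad(if (na > 1) diff(series$angles_deg[1:2]) else 1)
  cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
  xg <- rep(seq_len(nx) - cx, times = nz)
  zg <- rep(seq_len(nz) - cz, each = nx)
  B <- matrix(0, nx * nz, ny)
  for (a in seq_len(na)) {
    img <- rbind(series$images[, , a], matrix(0, nx, ny))
    filt <- (Re(stats::mvfft(stats::mvfft(img) * H, inverse = TRUE)) /
               npad)[seq_len(nx), , drop = FALSE]
    th <- deg2rad(series$angles_deg[a])
    xd <- xg * cos(th) + zg * sin(th) + cx
    i0 <- floor(xd); fxw <- xd - i0
    ok0 <- i0 >= 1 & i0 <= nx
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= nx
    r0 <- ifelse(ok0, i0, 1L); r1 <- ifelse(ok1, i0 + 1L, 1L)
    w0 <- ifelse(ok0, 1 - fxw, 0); w1 <- ifelse(ok1, fxw, 0)
    B <- B + (w0 * filt[r0, , drop = FALSE] + w1 * filt[r1, , drop = FALSE]) * dth
  }
  vol <- aperm(array(B, c(nx, nz, ny)), c(1, 3, 2))
  new_tomogram(vol, series$pixel_size_nm,
               provenance = list(method = "weighted_backprojection",
                                 angles_deg = series$angles_deg,
                                 rolloff_frac = rolloff_frac))
}

#' Fourier missing-wedge mask
#'
#' Oracle shortcut for the tomographic missing wedge: zeroes every Fourier
#' coefficient lying closer than (90 - `half_angle_deg`) degrees to the
#' beam axis in the plane perpendicular to the tilt axis, i.e. the
#' reciprocal-space region a +/-`half_angle_deg` tilt series never
#' samples. The mask is centro-symmetric so the output stays real.
#'
#' @param map a [density_map()] or `tomogram` (beam = z).
#' @param half_angle_deg tilt half-range; 90 returns the input unchanged.
#' @param tilt_axis `"y"` (default) or `"x"`.
#' @return same class as the input, wedge-filtered.
#' @export
apply_missing_wedge <- function(map, half_angle_deg = 60, tilt_axis = c("y", "x")) {
  tilt_axis <- match.arg(tilt_axis)
  stopifnot(half_angle_deg > 0, half_angle_deg <= 90)
  if (half_angle_deg == 90) return(map)
  arr <- map$data
  d <- dim(arr)
  F <- stats::fft(arr)
  fx <- fft_freq(d[1]); fy <- fft_freq(d[2]); fz <- fft_freq(d[3])
  fperp <- if (tilt_axis == "y") fx else fy
  t_half <- tan(deg2rad(half_angle_deg))
  perp_grid <- if (tilt_axis == "y") {
    array(rep(abs(fperp), times = d[2] * d[3]), d)
  } else {
    array(rep(rep(abs(fperp), each = d[1]), times = d[3]), d)
  }
  beam_grid <- array(rep(abs(fz), each = d[1] * d[2]), d)
  mask <- beam_grid > t_half * perp_grid
  F[mask] <- 0
  out <- Re(stats::fft(F, inverse = TRUE)) / prod(d)
  map$data <- out
  if (inherits(map, "tomogram"))
    map$provenance <- c(map$provenance,
                        list(wedge_half_angle_deg = half_angle_deg))
  map
}

#' Convert a wedge-filtered density map into a tomogram container
#'
#' Convenience for analyses that use the Fourier wedge mask as the fast
#' stand-in for a full projection + backprojection cycle.
#'
#' @param map a [density_map()].
#' @param half_angle_deg tilt half-range passed to [apply_missing_wedge()].
#' @param tilt_axis tilt axis.
#' @return a `tomogram`.
#' @export
wedge_tomogram <- function(map, half_angle_deg = 60, tilt_axis = "y") {
  filt <- apply_missing_wedge(map, half_angle_deg, tilt_axis)
  new_tomogram(filt$data, map$voxel_size_nm,
               provenance = list(method = "wedge_mask",
                                 wedge_half_angle_deg = half_angle_deg))
}
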