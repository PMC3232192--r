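#' @keywords internal
"_PACKAGE"

deg2rad <- function(x) x * pi / 180

## FFT sample frequencies in cycles per unit, standard (unshifted) order.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

## Index of the DC sample after fftshift-style centering.
fft_center <- function(n) floor(n / 2) + 1L

## Reorder an unshifted FFT axis so DC sits at fft_center(n).
fftshift_idx <- function(n) {
  c(seq(ceiling(n / 2) + 1L, n), seq_len(ceiling(n / 2)))
}

ifftshift_idx <- function(n) order(fftshift_idx(n))

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]

ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m)), drop = FALSE]

## Rotation matrices (right-handed, active, angles in radians).
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

## round-half-away-from-zero; base round() is banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## Evaluate a scalar-valued function on a local seed without disturbing
## the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Parabolic (three-point) sub-sample peak refinement. Returns the offset
## of the vertex relative to the middle sample, clamped to [-0.5, 0.5].
parabolic_offset <- function(y_left, y_mid, y_right) {
  denom <- y_left - 2 * y_mid + y_right
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (y_left - y_right) / denom
  max(-0.5, min(0.5, off))
}
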