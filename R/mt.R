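# Model area MT: spatial integration with downsampling, and the
# velocity-domain center-surround "soft" competition that lets multiple
# motions coexist at one location (the substrate of motion transparency).

#' MT first stage: spatial integration and downsampling
#'
#' Each (speed, direction) channel of the V1 output is convolved with an
#' isotropic anti-alias Gaussian (sigma = `mt_sigma_xy`), sampled every
#' `mt_sampling_rate`-th pixel by linear interpolation, raised to the power
#' `alpha`, and finally smoothed in velocity space with `Lambda_vel`.
#'
#' @param z3_v1 nonnegative `H x W x ns x nd` array from [v1_stage3()].
#' @param params a [motion_model_params()].
#' @return array `ceil(H/r) x ceil(W/r) x ns x nd`.
#' @export
mt_integrate <- function(z3_v1, params) {
  r <- params$mt_sampling_rate
  if (r < 1) stop("sampling rate must be >= 1")
  d <- dim(z3_v1)
  H <- d[1]; W <- d[2]
  h <- ceiling(H / r); w <- ceiling(W / r)
  kf <- periodic_gaussian_fft(H, W, params$mt_sigma_xy)
  # sampling positions (1-based, possibly fractional for non-integer r)
  py <- (seq_len(h) - 1) * r + 1
  px <- (seq_len(w) - 1) * r + 1
  out <- array(0, c(h, w, d[3], d[4]))
  for (i in seq_len(d[3])) {
    for (j in seq_len(d[4])) {
      sm <- conv2_circ(z3_v1[, , i, j], kf)
      out[, , i, j] <- sample_linear(sm, py, px)
    }
  }
  out <- out^params$alpha
  g <- grid_from_params(params)
  S <- speed_kernel_matrix(g$speeds, g$sigma_speed)
  D <- dir_kernel_matrix(length(g$directions), g$dir_step, g$sigma_dir)
  vel_smooth(out, S, D)
}

# Bilinear sampling of a matrix at the (1-based) row/col position grids,
# wrapping at the borders to match the circular convolution.
sample_linear <- function(m, py, px) {
  H <- nrow(m); W <- ncol(m)
  y0 <- floor(py); fy <- py - y0
  x0 <- floor(px); fx <- px - x0
  iy0 <- ((y0 - 1) %% H) + 1; iy1 <- (y0 %% H) + 1
  ix0 <- ((x0 - 1) %% W) + 1; ix1 <- (x0 %% W) + 1
  m00 <- m[iy0, ix0, drop = FALSE]; m10 <- m[iy1, ix0, drop = FALSE]
  m01 <- m[iy0, ix1, drop = FALSE]; m11 <- m[iy1, ix1, drop = FALSE]
  wy <- matrix(fy, length(py), length(px))
  wx <- matrix(fx, length(py), length(px), byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m10 * wy * (1 - wx) +
    m01 * (1 - wy) * wx + m11 * wy * wx
}

#' MT third stage: soft center-surround competition in velocity space
#'
#' The second cascade stage is the identity (no feedback into MT is
#' modeled), so this operates directly on the first-stage output. The
#' excitatory centre pools over nearby directions only (no kernel along
#' speed); the inhibitory surround pools broadly over speed and direction;
#' the output is `center / (A_MT + B_MT * surround)`, clipped at zero.
#' Because the surround is local in velocity space rather than a pool over
#' everything, sufficiently different motions survive side by side.
#'
#' @param z1_mt nonnegative array from [mt_integrate()].
#' @param params a [motion_model_params()].
#' @return array `z3_mt` of the same shape.
#' @export
mt_compete <- function(z1_mt, params) {
  g <- grid_from_params(params)
  nd <- length(g$directions)
  z2 <- z1_mt  # identity second stage
  Dc <- dir_kernel_matrix(nd, g$dir_step, params$mt_center_sigma_dir)
  Sc <- diag(length(g$speeds))  # Dirac along speed
  center <- vel_smooth(z2, Sc, Dc)
  Ds <- dir_kernel_matrix(nd, g$dir_step, params$mt_surround_sigma_dir)
  Ss <- speed_kernel_matrix(g$speeds, params$mt_surround_sigma_speed)
  surround <- vel_smooth(z2, Ss, Ds)
  pmax(center / (params$A_MT + params$B_MT * surround), 0)
}

# Full MT pass for one V1 output frame.
mt_frame <- function(z3_v1, params) {
  mt_compete(mt_integrate(z3_v1, params), params)
}

#' Anti-alias attenuation of the MT downsampling filter
#'
#' Relative spectral power remaining at the maximum normalized frequency
#' pi after Gaussian low-pass filtering with width `sigma` at sampling rate
#' `r`, as a percentage of the peak (zero-frequency) power:
#' `100 * exp(-(pi * sigma / r)^2 / 2)`. With the defaults sigma = 5 px and
#' r = 5 this evaluates to `100 * exp(-pi^2 / 2)`, about 0.72%.
#'
#' @param sigma Gaussian width in pixels.
#' @param r sampling rate.
#' @return attenuation in percent.
#' @examples
#' mt_antialias_attenuation()  # ~0.72
#' @export
mt_antialias_attenuation <- function(sigma = 5, r = 5) {
  100 * exp(-(pi * sigma / r)^2 / 2)
}
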