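# Gabor filter bank in the spatial-frequency domain and phase extraction.
#
# Each filter is a unit-sum Gaussian in the 2-D frequency plane, centred at
# radius omega_l = 2*pi/lambda_l along orientation psi_k, with radial width
# sigma_r = 1.26 * omega_l * (beta - 1) / (beta + 1) and tangential width
# sigma_psi = 1.5 * omega_l * sin(delta_psi). Because the kernel occupies a
# single side of the frequency plane (no mirrored lobe), filtering yields an
# analytic-signal-like complex response whose argument is the local image
# phase - the only quantity the motion detector consumes.

#' Build a Gabor filter bank
#'
#' @param H,W frame size in pixels; must exceed the largest wavelength.
#' @param params a [motion_model_params()] (or arguments to build one).
#' @return object of class `"gabor_bank"`: a list with `kernels[[l]]`, a
#'   `H x W x n_orientations` array of frequency-domain kernels for ring
#'   `l`; `lambda` (wavelengths), `omega` (peak radial frequencies, rad/px),
#'   `speeds`, `psi` (orientations, degrees), `sigma_r`, `sigma_psi`.
#' @examples
#' bank <- build_gabor_bank(32, 32, motion_model_params())
#' sum(bank$kernels[[1]][, , 1])  # unit integral
#' @export
build_gabor_bank <- function(H, W, params = motion_model_params()) {
  p <- params
  lambda <- p$eta * p$speeds
  if (any(lambda < 2)) stop("wavelengths below 2 px exceed the Nyquist limit")
  if (H <= max(lambda) || W <= max(lambda)) {
    stop("frame must be larger than the largest Gabor wavelength")
  }
  omega <- 2 * pi / lambda
  dpsi <- 180 / p$n_orientations
  psi <- (seq_len(p$n_orientations) - 1) * dpsi
  sigma_psi <- 1.5 * omega * sin(dpsi * pi / 180)
  sigma_r <- 1.26 * omega * (p$beta - 1) / (p$beta + 1)

  # angular frequency grids (rad/px), FFT layout
  fy <- 2 * pi * ifelse(0:(H - 1) <= H / 2, 0:(H - 1), 0:(H - 1) - H) / H
  fx <- 2 * pi * ifelse(0:(W - 1) <= W / 2, 0:(W - 1), 0:(W - 1) - W) / W
  wy <- matrix(rep(fy, W), H, W)
  wx <- matrix(rep(fx, each = H), H, W)

  kernels <- vector("list", length(lambda))
  for (l in seq_along(lambda)) {
    arr <- array(0, c(H, W, p$n_orientations))
    for (k in seq_len(p$n_orientations)) {
      ps <- psi[k] * pi / 180
      w_par <- wx * cos(ps) + wy * sin(ps)
      w_perp <- -wx * sin(ps) + wy * cos(ps)
      g <- exp(-(w_par - omega[l])^2 / (2 * sigma_r[l]^2) -
                 w_perp^2 / (2 * sigma_psi[l]^2))
      g[1, 1] <- 0  # band-pass: no DC response (constant frames map to 0)
      arr[, , k] <- g / sum(g)
    }
    kernels[[l]] <- arr
  }
  structure(list(kernels = kernels, lambda = lambda, omega = omega,
                 speeds = p$speeds, psi = psi, sigma_r = sigma_r,
                 sigma_psi = sigma_psi, H = H, W = W),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf(
    "<gabor_bank> %d rings (lambda %s px) x %d orientations on %d x %d px\n",
    length(x$lambda), paste(x$lambda, collapse = ", "), length(x$psi),
    x$H, x$W
  ))
  invisible(x)
}

#' Apply the Gabor bank to a single frame
#'
#' Multiplies the spatial FFT of the frame with every frequency-domain
#' kernel and inverse-transforms, retaining the complex responses.
#'
#' @param frame `H x W` numeric matrix.
#' @param bank a [build_gabor_bank()] result of matching size.
#' @return list over rings; each element a complex `H x W x n_orientations`
#'   array.
#' @export
gabor_responses <- function(frame, bank) {
  stopifnot(nrow(frame) == bank$H, ncol(frame) == bank$W)
  if (!all(is.finite(frame))) stop("non-finite frame intensities")
  Fhat <- stats::fft(frame)
  lapply(bank$kernels, function(karr) {
    out <- array(complex(real = 0), dim(karr))
    freq <- array(complex(real = 0), dim(karr))
    for (k in seq_len(dim(karr)[3])) {
      freq[, , k] <- Fhat * karr[, , k]
      out[, , k] <- ifft2(freq[, , k])
    }
    # frequency-domain product kept alongside for exact sub-pixel shifts
    attr(out, "freq") <- freq
    out
  })
}

# Sample a ring response at positions displaced by (dx, dy) with
# wrap-around: integer shifts are index rolls; fractional shifts use the
# exact spectral shift theorem on the retained frequency-domain product
# (the responses are narrowband, so this is the faithful interpolant -
# bilinear interpolation would crush the amplitude of the finest ring).
shift_ring <- function(resp, dx, dy) {
  if (abs(dx - round(dx)) < 1e-9 && abs(dy - round(dy)) < 1e-9) {
    return(roll2(resp, -round(dy), -round(dx)))
  }
  freq <- attr(resp, "freq")
  if (is.null(freq)) return(shift_bilinear(resp, dx, dy))
  d <- dim(freq)
  H <- d[1]; W <- d[2]
  fy <- 2 * pi * ifelse(0:(H - 1) <= H / 2, 0:(H - 1), 0:(H - 1) - H) / H
  fx <- 2 * pi * ifelse(0:(W - 1) <= W / 2, 0:(W - 1), 0:(W - 1) - W) / W
  ph <- exp(1i * (outer(fy, rep(1, W)) * dy + outer(rep(1, H), fx) * dx))
  out <- array(complex(real = 0), d)
  for (k in seq_len(d[3])) out[, , k] <- ifft2(freq[, , k] * ph)
  out
}

#' Apply the Gabor bank to a frame stack
#'
#' @param frames a [frame_stack()] (or `H x W x T` array).
#' @param bank a [build_gabor_bank()] result.
#' @return list over frames of [gabor_responses()] results. The local image
#'   phase of ring `l`, orientation `k` at frame `t` is
#'   `Arg(result[[t]][[l]][, , k])`.
#' @export
apply_gabor <- function(frames, bank) {
  frames <- as_frame_stack(frames)
  lapply(seq_len(n_frames(frames)), function(t) {
    gabor_responses(frames[, , t], bank)
  })
}
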