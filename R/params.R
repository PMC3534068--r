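#' Model parameters
#'
#' All tunable constants of the motion model in one place, with the
#' published cascade constants as defaults. Units: speeds in pixels/frame,
#' direction angles in degrees, spatial sigmas in pixels.
#'
#' @param n_orientations number of Gabor orientations (angular spacing is
#'   180 / n_orientations degrees).
#' @param speeds speed ladder in pixels/frame; each speed is paired with one
#'   Gabor ring of wavelength `eta * speed`.
#' @param eta speed-to-wavelength factor in frames; must be >= 2 so tested
#'   displacements respect the half-wavelength (sampling) constraint.
#' @param beta radial bandwidth ratio of the Gabor rings (2 = one octave).
#' @param directions motion directions in degrees.
#' @param sigma_speed,sigma_dir velocity-space interaction widths of the
#'   Gaussian `Lambda_vel` (pixels/frame, degrees).
#' @param alpha nonlinearity exponent of the cascades.
#' @param gamma feedback amplification constant.
#' @param A_V1,B_V1 V1 normalization constants.
#' @param mt_sampling_rate V1-to-MT downsampling factor r.
#' @param mt_sigma_xy anti-alias Gaussian width before downsampling
#'   (pixels).
#' @param A_MT,B_MT MT normalization constants.
#' @param mt_center_sigma_dir direction width of the MT excitatory centre
#'   kernel (degrees); the centre applies no kernel along speed.
#' @param mt_surround_sigma_dir,mt_surround_sigma_speed widths of the MT
#'   inhibitory surround kernel.
#' @param A_MST,B_MST MSTd normalization constants.
#' @param lambda_temp leak of the MSTd temporal integration in (0, 1].
#' @param sigma_pat_frac MSTd template envelope sigma as a fraction of the
#'   visual-field extent.
#' @param theta_motion read-out threshold; `NULL` means calibrate as
#'   `theta_motion_frac` of the peak response to a reference translating
#'   stimulus.
#' @param theta_motion_frac calibration fraction for `theta_motion`.
#' @param theta_slow slow-speed cutoff of the danger rule (pixels/frame).
#' @param max_motions maximum number of motions read out per location.
#' @return a named list of class `"motion_model_params"`.
#' @export
motion_model_params <- function(
    n_orientations = 8,
    speeds = c(1, 2, 4),
    eta = 2.5,
    beta = 2,
    directions = seq(0, 315, by = 45),
    sigma_speed = 0.5,
    sigma_dir = 30,
    alpha = 2,
    gamma = 100,
    A_V1 = 0.01,
    B_V1 = 100 / 112,
    mt_sampling_rate = 5,
    mt_sigma_xy = 5,
    A_MT = 0.01,
    B_MT = 10,
    mt_center_sigma_dir = 25,
    mt_surround_sigma_dir = 60,
    mt_surround_sigma_speed = 1.5,
    A_MST = 0.01,
    B_MST = 10,
    lambda_temp = 0.5,
    sigma_pat_frac = 0.8,
    theta_motion = NULL,
    theta_motion_frac = 0.2,
    theta_slow = 0.5,
    max_motions = 2) {
  if (eta < 2) stop("eta must be >= 2 (sampling theorem)")
  if (is.unsorted(speeds, strictly = TRUE)) {
    stop("speeds must be strictly increasing")
  }
  if (alpha <= 0 || A_V1 <= 0 || A_MT <= 0 || A_MST <= 0 || gamma < 0) {
    stop("cascade constants out of range: need alpha > 0, A > 0, gamma >= 0")
  }
  p <- list(
    n_orientations = n_orientations, speeds = speeds, eta = eta, beta = beta,
    directions = directions, sigma_speed = sigma_speed, sigma_dir = sigma_dir,
    alpha = alpha, gamma = gamma, A_V1 = A_V1, B_V1 = B_V1,
    mt_sampling_rate = mt_sampling_rate, mt_sigma_xy = mt_sigma_xy,
    A_MT = A_MT, B_MT = B_MT,
    mt_center_sigma_dir = mt_center_sigma_dir,
    mt_surround_sigma_dir = mt_surround_sigma_dir,
    mt_surround_sigma_speed = mt_surround_sigma_speed,
    A_MST = A_MST, B_MST = B_MST, lambda_temp = lambda_temp,
    sigma_pat_frac = sigma_pat_frac,
    theta_motion = theta_motion, theta_motion_frac = theta_motion_frac,
    theta_slow = theta_slow, max_motions = max_motions
  )
  class(p) <- "motion_model_params"
  p
}

#' @export
print.motion_model_params <- function(x, ...) {
  cat("<motion_model_params>\n")
  cat(sprintf("  %d orientations, speeds {%s} px/frame (eta = %g)\n",
              x$n_orientations, paste(x$speeds, collapse = ", "), x$eta))
  cat(sprintf("  %d directions; Lambda_vel: sigma_speed %g, sigma_dir %g\n",
              length(x$directions), x$sigma_speed, x$sigma_dir))
  cat(sprintf("  V1: alpha %g, gamma %g, A %g, B %.4g\n",
              x$alpha, x$gamma, x$A_V1, x$B_V1))
  cat(sprintf("  MT: r %d, sigma_xy %g, A %g, B %g\n",
              x$mt_sampling_rate, x$mt_sigma_xy, x$A_MT, x$B_MT))
  cat(sprintf("  MSTd: A %g, B %g, lambda_temp %g\n",
              x$A_MST, x$B_MST, x$lambda_temp))
  invisible(x)
}

#' Velocity grid
#'
#' The polar velocity space shared by V1 and MT: a list of speeds (paired
#' one-to-one with the Gabor rings) and evenly spaced directions, plus the
#' Gaussian interaction widths along each axis. The direction axis is
#' circular; the speed axis uses a reflecting (Neumann) boundary.
#'
#' @param speeds speeds in pixels/frame.
#' @param directions directions in degrees, evenly covering `[0, 360)`.
#' @param sigma_speed,sigma_dir interaction widths.
#' @return object of class `"velocity_grid"`.
#' @export
velocity_grid <- function(speeds = c(1, 2, 4),
                          directions = seq(0, 315, by = 45),
                          sigma_speed = 0.5, sigma_dir = 30) {
  step <- 360 / length(directions)
  if (max(abs(diff(directions) - step)) > 1e-9) {
    stop("directions must be evenly spaced over [0, 360)")
  }
  structure(list(speeds = speeds, directions = directions,
                 sigma_speed = sigma_speed, sigma_dir = sigma_dir,
                 dir_step = step),
            class = "velocity_grid")
}

# Grid implied by a parameter set.
grid_from_params <- function(p) {
  velocity_grid(p$speeds, p$directions, p$sigma_speed, p$sigma_dir)
}

#' @export
print.velocity_grid <- function(x, ...) {
  cat(sprintf("<velocity_grid> speeds {%s} px/frame x directions {%s} deg\n",
              paste(x$speeds, collapse = ", "),
              paste(x$directions, collapse = ", ")))
  invisible(x)
}
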