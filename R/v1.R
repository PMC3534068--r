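# Model area V1: phase-based extended Hassenstein-Reichardt initial motion
# detection and the three-stage cascade (velocity-space integration,
# feedback modulation, divisive normalization).

#' Initial motion detection (extended Hassenstein-Reichardt correlator)
#'
#' Correlates local image phase between two successive frames. For each
#' speed `s` (served by the Gabor ring of wavelength `eta * s`) and each
#' direction `phi`, the tested displacement is
#' `(dx, dy) = s * (cos(phi), -sin(phi))`. The forward correlation sums the
#' half-wave rectified cosine of the phase difference between the shifted
#' earlier frame and the unshifted later frame over all orientations of the
#' matched ring; the backward correlation swaps the temporal order; their
#' rectified difference cancels flicker and responds only to coherent
#' displacement. Phases at non-integer displacements are obtained by
#' bilinear interpolation of the complex responses (interpolating wrapped
#' phase directly is ill-defined).
#'
#' Phase is undefined where the Gabor amplitude vanishes (untextured
#' regions), so each orientation's contribution is gated by amplitude
#' validity: both compared responses must exceed `amp_frac` times the
#' ring's mean amplitude, the usual low-amplitude masking of phase-based
#' motion estimation.
#'
#' @param gab_t0,gab_t1 [gabor_responses()] of the earlier/later frame.
#' @param bank the [build_gabor_bank()] used.
#' @param grid a [velocity_grid()]; its speeds must match the bank's ring
#'   speeds one-to-one, and every tested displacement must satisfy the
#'   half-wavelength constraint `s <= lambda / 2`.
#' @param amp_frac amplitude-validity threshold as a fraction of the mean
#'   ring amplitude.
#' @param tuning exponent sharpening the rectified-cosine phase tuning.
#'   With speeds one octave apart, first-order cosine tuning leaves a
#'   neighboring ring substantial response to an unmatched displacement
#'   (the residual phase error is only `pi / eta` radians); squaring the
#'   tuning curve restores the speed selectivity of the ladder.
#' @return nonnegative array `H x W x n_speeds x n_directions` of initial
#'   motion likelihoods c.
#' @export
initial_motion <- function(gab_t0, gab_t1, bank, grid, amp_frac = 0.1,
                           tuning = 2) {
  if (!isTRUE(all.equal(grid$speeds, bank$speeds))) {
    stop("grid speeds must match the Gabor bank's ring speeds one-to-one")
  }
  if (any(grid$speeds > bank$lambda / 2 + 1e-9)) {
    stop("tested displacement exceeds half the ring wavelength")
  }
  H <- bank$H; W <- bank$W
  ns <- length(grid$speeds); nd <- length(grid$directions)
  cc <- array(0, c(H, W, ns, nd))
  for (l in seq_len(ns)) {
    s <- grid$speeds[l]
    ph0 <- Arg(gab_t0[[l]])
    ph1 <- Arg(gab_t1[[l]])
    a0 <- Mod(gab_t0[[l]])
    a1 <- Mod(gab_t1[[l]])
    eps <- amp_frac * mean(c(mean(a0), mean(a1)))
    v0 <- a0 > eps
    v1 <- a1 > eps
    for (j in seq_len(nd)) {
      phi <- grid$directions[j] * pi / 180
      dx <- s * cos(phi)
      dy <- -s * sin(phi)
      sf0 <- shift_ring(gab_t0[[l]], dx, dy)
      sf1 <- shift_ring(gab_t1[[l]], dx, dy)
      # one symmetric validity mask for both temporal orders, so that
      # forward and backward correlations cancel exactly on static input
      ok <- v0 & v1 & (Mod(sf0) > eps) & (Mod(sf1) > eps)
      # forward: content at x in the earlier frame reappears at x + (dx,dy)
      # in the later frame; backward inverts the temporal order
      fwd <- rowSums(pmax(cos(Arg(sf1) - ph0), 0)^tuning * ok, dims = 2)
      bwd <- rowSums(pmax(cos(Arg(sf0) - ph1), 0)^tuning * ok, dims = 2)
      cc[, , l, j] <- pmax(fwd - bwd, 0)
    }
  }
  cc
}

#' V1 cascade, first stage: velocity-space integration
#'
#' Steady state of the integration ODE: the input is raised to the power
#' `alpha` (default quadratic) and convolved with the velocity-space
#' Gaussian `Lambda_vel`, circular along direction and reflecting (Neumann)
#' along speed.
#'
#' @param c_init nonnegative `H x W x n_speeds x n_directions` array.
#' @param params a [motion_model_params()].
#' @return array `z1` of the same shape.
#' @export
v1_stage1 <- function(c_init, params) {
  g <- grid_from_params(params)
  S <- speed_kernel_matrix(g$speeds, g$sigma_speed)
  D <- dir_kernel_matrix(length(g$directions), g$dir_step, g$sigma_dir)
  vel_smooth(c_init^params$alpha, S, D)
}

#' V1 cascade, second stage: feedback modulation
#'
#' Multiplicative re-entry: `z2 = z1 * (1 + gamma * z_fb)`. Feedback alone
#' cannot create activity - where the driving signal is zero the output
#' stays zero.
#'
#' @param z1 first-stage output.
#' @param z_fb feedback field of the same shape (values in `[0, 1]`), or
#'   `NULL` for no feedback.
#' @param params a [motion_model_params()].
#' @return array `z2`.
#' @export
v1_stage2 <- function(z1, z_fb, params) {
  if (is.null(z_fb)) return(z1)
  if (any(z_fb < 0)) stop("feedback values must be nonnegative")
  z1 * (1 + params$gamma * z_fb)
}

#' V1 cascade, third stage: divisive normalization
#'
#' `z3 = z2 / (A_V1 + B_V1 * sum(z2))`, the sum running over all speeds and
#' directions at each location. Because the pool spans the whole velocity
#' space, this normalization favors a single motion vector; with
#' `B_V1 >= 1` the output cannot exceed one.
#'
#' @param z2 second-stage output.
#' @param params a [motion_model_params()].
#' @return array `z3` of the same shape.
#' @export
v1_stage3 <- function(z2, params) {
  d <- dim(z2)
  pool <- rowSums(z2, dims = 2)
  z2 / (params$A_V1 + params$B_V1 * array(pool, d))
}

# One V1 pass for a single frame pair (internal; run_v1 drives it).
v1_frame <- function(gab_t0, gab_t1, bank, params, z_fb = NULL) {
  grid <- grid_from_params(params)
  c_init <- initial_motion(gab_t0, gab_t1, bank, grid)
  z1 <- v1_stage1(c_init, params)
  z2 <- v1_stage2(z1, z_fb, params)
  v1_stage3(z2, params)
}

#' Run model area V1 over a frame stack
#'
#' Applies the Gabor bank per frame and the initial motion detector plus
#' cascade per frame pair. When `feedback = TRUE` each frame pair after the
#' first is modulated by the previous frame's MT output (third MT stage),
#' upsampled to V1 resolution by nearest neighbor; the first pair gets no
#' feedback.
#'
#' @param frames a [frame_stack()].
#' @param params a [motion_model_params()].
#' @param bank optional pre-built [build_gabor_bank()].
#' @param feedback logical; include MT-to-V1 feedback.
#' @return list with `z3_v1` (list over frame pairs of `H x W x ns x nd`
#'   arrays), `z3_mt` (list of MT outputs per pair, computed when feedback
#'   is on, else `NULL`), and `bank`.
#' @export
run_v1 <- function(frames, params = motion_model_params(), bank = NULL,
                   feedback = TRUE) {
  frames <- as_frame_stack(frames)
  H <- dim(frames)[1]; W <- dim(frames)[2]; T <- n_frames(frames)
  if (is.null(bank)) bank <- build_gabor_bank(H, W, params)
  z3_v1 <- vector("list", T - 1)
  z3_mt <- if (feedback) vector("list", T - 1) else NULL
  fb <- NULL
  gab_prev <- gabor_responses(frames[, , 1], bank)
  for (t in 2:T) {
    gab_cur <- gabor_responses(frames[, , t], bank)
    z3 <- v1_frame(gab_prev, gab_cur, bank, params, fb)
    z3_v1[[t - 1]] <- z3
    if (feedback) {
      mt <- mt_frame(z3, params)
      z3_mt[[t - 1]] <- mt
      fb <- upsample_velocity_field(mt, c(H, W))
      fb <- pmin(fb, 1)  # feedback values range between zero and one
    }
    gab_prev <- gab_cur
  }
  list(z3_v1 = z3_v1, z3_mt = z3_mt, bank = bank)
}

# Nearest-neighbor upsampling of an MT-resolution velocity field
# (h x w x ns x nd) to V1 resolution (H x W x ns x nd). MT cell (i, j)
# covers V1 rows/cols around ((i-1)*r + 1).
upsample_velocity_field <- function(field, size_hw) {
  d <- dim(field)
  H <- size_hw[1]; W <- size_hw[2]
  ry <- H / d[1]; rx <- W / d[2]
  iy <- pmin(pmax(round((seq_len(H) - 1) / ry) + 1, 1), d[1])
  ix <- pmin(pmax(round((seq_len(W) - 1) / rx) + 1, 1), d[2])
  field[iy, ix, , , drop = FALSE]
}
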