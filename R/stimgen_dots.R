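# Random-dot stimulus generators: translating fields, transparent overlays,
# lane stimuli and parametric flow-pattern movies. All dots are rendered as
# anti-aliased bright discs (linear edge falloff over one pixel) on a dark
# background so that sub-pixel displacements remain representable, and all
# stimuli use wrap-around spatial boundaries to match the circular boundary
# handling of the FFT-based motion detector.

# Render discs of radius `radius` centred at continuous positions (x, y)
# (column, row; 0-based) into an H x W intensity image, with wrap-around.
render_dots <- function(xs, ys, H, W, radius, base = NULL, value = 1) {
  img <- if (is.null(base)) matrix(0, H, W) else base
  if (length(xs) == 0) return(img)
  ext <- ceiling(radius + 1)
  off <- seq.int(-ext, ext)
  for (i in seq_along(xs)) {
    cx <- xs[i] %% W
    cy <- ys[i] %% H
    px <- round(cx) + off
    py <- round(cy) + off
    dx <- outer(rep(1, length(py)), px - cx)
    dy <- outer(py - cy, rep(1, length(px)))
    a <- pmin(pmax(radius + 0.5 - sqrt(dx^2 + dy^2), 0), 1) * value
    iy <- (py %% H) + 1
    ix <- (px %% W) + 1
    img[iy, ix] <- pmax(img[iy, ix], a)
  }
  img
}

#' Translating random-dot stimulus
#'
#' Generates a random-dot kinematogram in which every dot translates
#' coherently at a fixed speed and direction, with wrap-around at the frame
#' borders. Dots are bright anti-aliased discs on a dark background.
#'
#' @param n_dots number of dots (>= 1).
#' @param speed dot speed in pixels per frame (>= 0).
#' @param direction motion direction in degrees (0 = rightward, 90 = upward).
#' @param size frame size `c(H, W)` in pixels.
#' @param n_frames number of frames T (>= 2).
#' @param dot_radius disc radius in pixels; must be smaller than
#'   `min(size) / 2`.
#' @param seed integer seed for the dot layout, or `NULL`.
#' @return a [frame_stack()].
#' @examples
#' fs <- make_translating_dots(30, speed = 1, direction = 0,
#'                             size = c(32, 32), n_frames = 4, seed = 1)
#' @export
make_translating_dots <- function(n_dots, speed, direction, size, n_frames,
                                  dot_radius = 1.5, seed = NULL) {
  stopifnot(n_dots >= 1, speed >= 0, n_frames >= 2)
  H <- size[1]; W <- size[2]
  if (dot_radius >= min(H, W) / 2) {
    stop("dot_radius must be smaller than half the smallest frame dimension")
  }
  th <- direction * pi / 180
  pos <- with_seed(seed, cbind(stats::runif(n_dots, 0, W),
                               stats::runif(n_dots, 0, H)))
  out <- array(0, c(H, W, n_frames))
  for (t in seq_len(n_frames)) {
    dx <- (t - 1) * speed * cos(th)
    dy <- (t - 1) * speed * (-sin(th))
    out[, , t] <- render_dots(pos[, 1] + dx, pos[, 2] + dy, H, W, dot_radius)
  }
  frame_stack(out)
}

#' Transparent (superimposed) random-dot stimulus
#'
#' Overlays two or more independently moving dot fields into a single
#' stimulus; where discs overlap the union (pixelwise maximum) is taken, so
#' intensities stay in `[0, 1]`. With directions different enough to
#' separate, such stimuli are perceived - and represented by the model - as
#' motion transparency.
#'
#' @param components list of components, each a list with elements `n_dots`,
#'   `speed`, `direction` and optionally `seed`.
#' @param size,n_frames,dot_radius as in [make_translating_dots()].
#' @param seed integer master seed; components without their own seed get
#'   `seed + index`.
#' @return a [frame_stack()].
#' @export
make_transparent_dots <- function(components, size, n_frames,
                                  dot_radius = 1.5, seed = NULL) {
  stopifnot(length(components) >= 1)
  H <- size[1]; W <- size[2]
  out <- array(0, c(H, W, n_frames))
  for (i in seq_along(components)) {
    comp <- components[[i]]
    cseed <- comp$seed
    if (is.null(cseed) && !is.null(seed)) cseed <- seed + i
    fs <- make_translating_dots(comp$n_dots, comp$speed, comp$direction,
                                size, n_frames, dot_radius, cseed)
    out <- pmax(out, unclass(fs))
  }
  frame_stack(out)
}

#' Counterphase flicker stimulus
#'
#' A static dot layout whose contrast polarity reverses every frame
#' (bright dots on dark ground in odd frames, the inverted image in even
#' frames). Under polarity reversal every band-pass filter response flips
#' sign, i.e. the local phase jumps by pi everywhere, so forward and
#' backward phase correlations appear simultaneously and an opponent
#' (forward minus backward) motion detector stays silent.
#'
#' @inheritParams make_translating_dots
#' @return a [frame_stack()].
#' @export
make_flicker_dots <- function(n_dots, size, n_frames, dot_radius = 1.5,
                              seed = NULL) {
  H <- size[1]; W <- size[2]
  pos <- with_seed(seed, cbind(stats::runif(n_dots, 0, W),
                               stats::runif(n_dots, 0, H)))
  fa <- render_dots(pos[, 1], pos[, 2], H, W, dot_radius)
  out <- array(0, c(H, W, n_frames))
  for (t in seq_len(n_frames)) out[, , t] <- if (t %% 2 == 1) fa else 1 - fa
  frame_stack(out)
}

#' Lane stimulus of alternating motion direction
#'
#' Horizontal lanes of dots moving alternately rightward and leftward, the
#' lane boundaries at integer multiples of `lane_width` rows. Varying the
#' lane width moves the stimulus between segregated "striped" motion (wide
#' lanes) and motion transparency (lanes narrower than the model's spatial
#' integration).
#'
#' @param lane_width lane height in pixels (1 <= lane_width <= H).
#' @param speed dot speed in pixels per frame.
#' @param size,n_frames,dot_radius,seed as in [make_translating_dots()].
#' @param dot_density expected dots per square pixel.
#' @return a [frame_stack()]. The attribute `lane_direction` gives the
#'   per-row true direction (0 or 180 degrees).
#' @export
make_lane_stimulus <- function(lane_width, speed, size, n_frames,
                               dot_density = 0.02, dot_radius = 1.5,
                               seed = NULL) {
  H <- size[1]; W <- size[2]
  if (lane_width < 1 || lane_width > H) {
    stop("lane_width must lie between 1 and the frame height")
  }
  n_dots <- round(dot_density * H * W)
  out <- array(0, c(H, W, n_frames))
  if (n_dots > 0) {
    pos <- with_seed(seed, cbind(stats::runif(n_dots, 0, W),
                                 stats::runif(n_dots, 0, H)))
    lane <- floor(pos[, 2] / lane_width)
    dirsign <- ifelse(lane %% 2 == 0, 1, -1)  # even lanes rightward
    for (t in seq_len(n_frames)) {
      xs <- pos[, 1] + (t - 1) * speed * dirsign
      out[, , t] <- render_dots(xs, pos[, 2], H, W, dot_radius)
    }
  }
  fs <- frame_stack(out)
  rowlane <- floor((seq_len(H) - 1) / lane_width)
  attr(fs, "lane_direction") <- ifelse(rowlane %% 2 == 0, 0, 180)
  fs
}

#' Global flow-pattern dot movie
#'
#' Advects a random dot field along a linear spiral-pattern flow
#' \eqn{v(p) = g R(\delta) (p - c)} about the centre `c`, where
#' \eqn{R(\delta)} rotates by the pattern angle \eqn{\delta} (counted
#' counter-clockwise with y up): \eqn{\delta = 0} gives expansion (EXP),
#' 180\eqn{^\circ} contraction (CON), 90\eqn{^\circ} counter-clockwise
#' rotation (CCW), 270\eqn{^\circ} clockwise rotation (CW), and the
#' intermediate 45\eqn{^\circ} steps spiral mixtures. Dots are advected by
#' explicit Euler steps of one frame.
#'
#' @param pattern one of `"EXP"`, `"CON"`, `"CW"`, `"CCW"`, or a numeric
#'   pattern angle delta in degrees.
#' @param center flow centre `c(u, v)` in (column, row) pixels; must lie
#'   inside the frame.
#' @param size,n_frames,dot_radius,seed as in [make_translating_dots()].
#' @param gain flow gain in pixels/frame per pixel of distance from the
#'   centre; keep `gain * max radius` at or below the largest detectable
#'   speed.
#' @param n_dots number of dots.
#' @return a [frame_stack()] with attribute `flow`, a list of `vx`, `vy`
#'   matrices (pixels/frame, image coordinates: vy positive downward) giving
#'   the ground-truth flow sampled at every pixel.
#' @export
make_pattern_movie <- function(pattern, center, size, n_frames, gain = 0.05,
                               n_dots = 300, dot_radius = 1.5, seed = NULL) {
  H <- size[1]; W <- size[2]
  delta <- pattern_angle(pattern)
  u <- center[1]; v <- center[2]
  if (u < 0 || u >= W || v < 0 || v >= H) stop("center outside frame")
  dl <- delta * pi / 180
  Rm <- matrix(c(cos(dl), sin(dl), -sin(dl), cos(dl)), 2, 2)
  flow_at <- function(x, y) {
    # math coords: y up
    rel <- rbind(x - u, -(y - v))
    vm <- gain * (Rm %*% rel)
    list(vx = vm[1, ], vy = -vm[2, ])  # back to image coords
  }
  pos <- with_seed(seed, cbind(stats::runif(n_dots, 0, W),
                               stats::runif(n_dots, 0, H)))
  out <- array(0, c(H, W, n_frames))
  for (t in seq_len(n_frames)) {
    keep <- pos[, 1] >= -dot_radius & pos[, 1] < W + dot_radius &
      pos[, 2] >= -dot_radius & pos[, 2] < H + dot_radius
    out[, , t] <- render_dots_noclip(pos[keep, 1], pos[keep, 2], H, W,
                                     dot_radius)
    fl <- flow_at(pos[, 1], pos[, 2])
    pos[, 1] <- pos[, 1] + fl$vx
    pos[, 2] <- pos[, 2] + fl$vy
  }
  fs <- frame_stack(out)
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  gy <- matrix(rep(0:(H - 1), W), H, W)
  fl <- flow_at(as.vector(gx), as.vector(gy))
  attr(fs, "flow") <- list(vx = matrix(fl$vx, H, W), vy = matrix(fl$vy, H, W),
                           delta = delta, center = c(u, v), gain = gain)
  fs
}

# As render_dots but without wrap-around: dots near the border are clipped
# instead of reappearing on the opposite side (pattern flows are not cyclic).
render_dots_noclip <- function(xs, ys, H, W, radius) {
  img <- matrix(0, H, W)
  if (length(xs) == 0) return(img)
  ext <- ceiling(radius + 1)
  off <- seq.int(-ext, ext)
  for (i in seq_along(xs)) {
    px <- round(xs[i]) + off
    py <- round(ys[i]) + off
    ok_x <- px >= 0 & px < W
    ok_y <- py >= 0 & py < H
    if (!any(ok_x) || !any(ok_y)) next
    px <- px[ok_x]; py <- py[ok_y]
    dx <- outer(rep(1, length(py)), px - xs[i])
    dy <- outer(py - ys[i], rep(1, length(px)))
    a <- pmin(pmax(radius + 0.5 - sqrt(dx^2 + dy^2), 0), 1)
    img[py + 1, px + 1] <- pmax(img[py + 1, px + 1], a)
  }
  img
}

# Map a pattern name (or numeric angle) to the pattern angle delta in
# degrees: EXP 0, CCW 90, CON 180, CW 270.
pattern_angle <- function(pattern) {
  if (is.numeric(pattern)) return(pattern %% 360)
  num <- suppressWarnings(as.numeric(pattern))
  if (!is.na(num)) return(num %% 360)
  switch(toupper(pattern),
    EXP = 0, CCW = 90, CON = 180, CW = 270,
    stop("unknown pattern: ", pattern)
  )
}
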