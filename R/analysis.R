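# Read-out of the MT velocity representation into explicit motions, the
# no/single/multiple classification with its temporal consistency filter,
# velocity-gradient fields in local gauge coordinates, the danger-zone
# decision rule and region direction histograms.

#' Iterative read-out of motions from a velocity-space activation
#'
#' Finds the activation maximum; below `theta_motion` nothing is returned
#' ("no motion", a flat distribution). Otherwise a discretized Gaussian
#' (widths `sigma_speed`, `sigma_dir`) is anchored at the peak, the motion
#' is the Gaussian-weighted vector average of the grid velocities weighted
#' by activation (normalized by the summed weights), the consumed
#' likelihoods - all cells within three standard deviations of the peak -
#' are set to zero, and the procedure repeats up to `max_motions` times.
#' Three standard deviations cover the full lobe of a unimodal peak, so its
#' shoulders are not re-read as a spurious second motion, while genuinely
#' distinct motions (well beyond 3 sigma in velocity space) survive.
#'
#' Successive peaks whose direction lies within `merge_angle` of an
#' already-extracted motion are treated as part of that motion (their
#' likelihoods are consumed but no new motion is added): motions closer in
#' direction than about 20 degrees are a single percept, and the speed
#' crosstalk between rings of the correlator lands exactly there.
#'
#' @param activation nonnegative `n_speeds x n_directions` matrix.
#' @param grid a [velocity_grid()].
#' @param theta_motion read-out threshold.
#' @param max_motions maximum number of motions to extract.
#' @param merge_angle direction difference (degrees) below which a
#'   candidate is absorbed into an existing motion.
#' @return data frame with one row per extracted motion: `speed`,
#'   `direction` (degrees in `[0, 360)`), `weight` (summed weighted
#'   activation), in extraction order (peak height descending). Zero rows
#'   mean "no motion".
#' @export
read_out <- function(activation, grid, theta_motion, max_motions = 2,
                     merge_angle = 20) {
  stopifnot(all(activation >= 0))
  a <- activation
  sp <- grid$speeds
  dir <- grid$directions
  vx_grid <- outer(sp, cos(dir * pi / 180))
  vy_grid <- outer(sp, sin(dir * pi / 180))  # y up
  res <- list()
  for (iter in seq_len(max_motions + length(sp))) {
    if (length(res) >= max_motions) break
    pk <- which.max(a)
    if (a[pk] < theta_motion) break
    i0 <- ((pk - 1) %% length(sp)) + 1
    j0 <- ((pk - 1) %/% length(sp)) + 1
    zs <- (sp - sp[i0]) / grid$sigma_speed
    zd <- circ_diff_deg(dir, dir[j0]) / grid$sigma_dir
    g <- exp(-outer(zs^2, zd^2, "+") / 2)
    w <- g * a
    sw <- sum(w)
    vx <- sum(w * vx_grid) / sw
    vy <- sum(w * vy_grid) / sw
    cand_dir <- (atan2(vy, vx) * 180 / pi) %% 360
    a[outer(zs^2, zd^2, "+") <= 9] <- 0  # suppress what was read out
    prev_dirs <- vapply(res, function(r) r$direction, numeric(1))
    if (length(prev_dirs) > 0 &&
        any(circ_diff_deg(prev_dirs, cand_dir) < merge_angle)) {
      next  # same percept as an extracted motion; consumed, not counted
    }
    res[[length(res) + 1]] <- data.frame(
      speed = sqrt(vx^2 + vy^2),
      direction = cand_dir,
      weight = sw
    )
  }
  if (length(res) == 0) {
    data.frame(speed = numeric(0), direction = numeric(0),
               weight = numeric(0))
  } else {
    do.call(rbind, res)
  }
}

#' Read out a whole MT frame
#'
#' Applies [read_out()] at every MT location.
#'
#' @param z3_mt MT output `h x w x ns x nd`.
#' @param grid a [velocity_grid()].
#' @param theta_motion read-out threshold.
#' @param max_motions maximum motions per location.
#' @return object of class `"readout_field"`: list with `motions` (h x w
#'   list matrix of data frames), `n` (h x w count matrix), and per-cell
#'   primary motion matrices `speed1`, `dir1`, `vx1`, `vy1` (y up; `NA`
#'   where no motion), and `speed_max` (largest read-out speed, `NA` where
#'   none).
#' @export
read_out_field <- function(z3_mt, grid, theta_motion, max_motions = 2) {
  d <- dim(z3_mt)
  h <- d[1]; w <- d[2]
  motions <- vector("list", h * w)
  dim(motions) <- c(h, w)
  n <- matrix(0L, h, w)
  speed1 <- dir1 <- speed_max <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      mo <- read_out(matrix(z3_mt[i, j, , ], d[3], d[4]), grid,
                     theta_motion, max_motions)
      motions[[i, j]] <- mo
      n[i, j] <- nrow(mo)
      if (nrow(mo) > 0) {
        speed1[i, j] <- mo$speed[1]
        dir1[i, j] <- mo$direction[1]
        speed_max[i, j] <- max(mo$speed)
      }
    }
  }
  structure(list(
    motions = motions, n = n, speed1 = speed1, dir1 = dir1,
    vx1 = speed1 * cos(dir1 * pi / 180),
    vy1 = speed1 * sin(dir1 * pi / 180),
    speed_max = speed_max, theta_motion = theta_motion, grid = grid
  ), class = "readout_field")
}

#' @export
print.readout_field <- function(x, ...) {
  tab <- table(factor(pmin(x$n, 2), levels = 0:2))
  cat(sprintf(
    "<readout_field> %d x %d MT cells: %d none / %d single / %d multiple\n",
    nrow(x$n), ncol(x$n), tab[1], tab[2], tab[3]
  ))
  invisible(x)
}

#' Classify read-out counts into motion classes
#'
#' Zero motions map to `"none"`, one to `"single"`, two or more to
#' `"multiple"`.
#'
#' @param readout a [read_out_field()] result (or an integer matrix of
#'   motion counts).
#' @return character matrix of labels.
#' @export
classify_motions <- function(readout) {
  n <- if (inherits(readout, "readout_field")) readout$n else readout
  lab <- matrix("none", nrow(n), ncol(n))
  lab[n == 1] <- "single"
  lab[n >= 2] <- "multiple"
  lab
}

#' Temporal stabilization and upsampling of motion class maps
#'
#' Each MT-resolution label map is upsampled to frame resolution by nearest
#' neighbor; a pixel keeps its label only if the label is identical in
#' three successive frames (t-2, t-1, t), otherwise it becomes `"none"`.
#' The first two frames carry no stabilized labels.
#'
#' @param labels list over frames of label matrices (from
#'   [classify_motions()]).
#' @param size target `c(H, W)` in pixels.
#' @return list over frames of `motion_class_map` objects: character
#'   matrices of `"none"/"single"/"multiple"` at frame resolution.
#' @export
stabilize_and_upsample <- function(labels, size) {
  if (length(labels) < 3) {
    warning("fewer than 3 frames of labels: all pixels set to 'none'")
  }
  H <- size[1]; W <- size[2]
  up <- lapply(labels, function(l) {
    iy <- pmin(pmax(round((seq_len(H) - 1) / (H / nrow(l))) + 1, 1), nrow(l))
    ix <- pmin(pmax(round((seq_len(W) - 1) / (W / ncol(l))) + 1, 1), ncol(l))
    l[iy, ix, drop = FALSE]
  })
  out <- vector("list", length(labels))
  for (t in seq_along(labels)) {
    if (t < 3) {
      m <- matrix("none", H, W)
    } else {
      m <- up[[t]]
      m[!(up[[t]] == up[[t - 1]] & up[[t]] == up[[t - 2]])] <- "none"
    }
    class(m) <- c("motion_class_map", class(m))
    out[[t]] <- m
  }
  out
}

#' Encode a motion class map as 8-bit gray values
#'
#' `none` is black (0), `single` mid-gray (128), `multiple` white (255).
#'
#' @param map a motion class map (character matrix).
#' @return integer matrix of 0/128/255.
#' @export
encode_class_map <- function(map) {
  enc <- matrix(0L, nrow(map), ncol(map))
  enc[map == "single"] <- 128L
  enc[map == "multiple"] <- 255L
  enc
}

#' Velocity gradients in local gauge coordinates
#'
#' From the primary read-out motion per MT cell, the vector field is
#' lightly smoothed (one-cell Gaussian over valid cells), its Jacobian
#' taken by central differences (one-sided at mask borders), and projected
#' onto the local gauge frame: with `e_t` the unit flow direction and
#' `e_n` its 90-degree counter-clockwise normal,
#' `g_t = e_t' J e_t` (along-flow speed change: positive for local
#' expansion, negative for contraction) and `g_n = e_n' J e_t` (flow
#' bending: positive for CCW, negative for CW rotation). The pattern angle
#' is `chi = atan2(g_n, g_t)`.
#'
#' @param readout a [read_out_field()] result.
#' @param smooth_sigma Gaussian width of the pre-smoothing in MT cells.
#' @return object of class `"gradient_field"`: list of matrices `gt`, `gn`,
#'   `chi` (degrees in `(-180, 180]`), `magnitude`, and the logical `mask`
#'   of cells with a defined gradient. Units: pixels/frame per MT cell.
#' @export
velocity_gradients <- function(readout, smooth_sigma = 1) {
  vx <- readout$vx1
  vy <- readout$vy1
  mask <- !is.na(vx)
  vxs <- masked_smooth(vx, mask, smooth_sigma)
  vys <- masked_smooth(vy, mask, smooth_sigma)
  # derivatives in math coords: x = column index, y-up = -row index
  dvx_dx <- masked_diff(vxs, mask, axis = "x")
  dvy_dx <- masked_diff(vys, mask, axis = "x")
  dvx_dy <- -masked_diff(vxs, mask, axis = "y")
  dvy_dy <- -masked_diff(vys, mask, axis = "y")
  spd <- sqrt(vxs^2 + vys^2)
  tx <- vxs / spd; ty <- vys / spd
  nx <- -ty; ny <- tx
  # J e_t then projections
  jx <- dvx_dx * tx + dvx_dy * ty
  jy <- dvy_dx * tx + dvy_dy * ty
  gt <- tx * jx + ty * jy
  gn <- nx * jx + ny * jy
  bad <- !mask | !is.finite(gt) | !is.finite(gn)
  gt[bad] <- NA; gn[bad] <- NA
  chi <- atan2(gn, gt) * 180 / pi
  structure(list(gt = gt, gn = gn, chi = chi,
                 magnitude = sqrt(gt^2 + gn^2), mask = !bad),
            class = "gradient_field")
}

# Gaussian smoothing restricted to valid cells (normalized convolution).
masked_smooth <- function(m, mask, sigma) {
  if (sigma <= 0) { m[!mask] <- NA; return(m) }
  ext <- max(1, ceiling(2 * sigma))
  k <- exp(-(-ext:ext)^2 / (2 * sigma^2))
  v <- m; v[!mask] <- 0
  wt <- matrix(as.numeric(mask), nrow(m), ncol(m))
  sep_conv <- function(x) {
    x <- apply(x, 2, function(col) pad_conv(col, k))
    t(apply(x, 1, function(row) pad_conv(row, k)))
  }
  num <- sep_conv(v)
  den <- sep_conv(wt)
  out <- num / pmax(den, 1e-12)
  out[!mask] <- NA
  out
}

# 1-D convolution with replicated (Neumann) ends.
pad_conv <- function(x, k) {
  ext <- (length(k) - 1) / 2
  n <- length(x)
  xp <- c(rep(x[1], ext), x, rep(x[n], ext))
  stats::filter(xp, k, sides = 2)[(ext + 1):(ext + n)]
}

# Central differences over valid cells, one-sided at mask borders,
# NA where no valid neighbor exists. axis "x" = along columns.
masked_diff <- function(m, mask, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "y") return(t(masked_diff(t(m), t(mask), "x")))
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      jm <- j - 1; jp <- j + 1
      okm <- jm >= 1 && mask[i, jm]
      okp <- jp <= w && mask[i, jp]
      if (okm && okp) out[i, j] <- (m[i, jp] - m[i, jm]) / 2
      else if (okp) out[i, j] <- m[i, jp] - m[i, j]
      else if (okm) out[i, j] <- m[i, j] - m[i, jm]
      else out[i, j] <- 0
    }
  }
  out
}

#' Danger-zone decision rule
#'
#' A pixel is flagged as a danger zone when it shows motion transparency
#' (class `"multiple"`) and the largest read-out speed there is below
#' `theta_slow`: slow transparent motion indicates reduced throughput and
#' building pressure, unlike fast transparency (e.g. lanes of opposite
#' flow).
#'
#' @param class_map a frame-resolution motion class map.
#' @param speed_max_up frame-resolution matrix of the largest read-out
#'   speed per pixel (nearest-neighbor upsampled from the MT grid).
#' @param theta_slow slow-speed cutoff in pixels/frame.
#' @return logical matrix; `TRUE` only where the class is `"multiple"`.
#' @export
danger_zones <- function(class_map, speed_max_up, theta_slow) {
  stopifnot(all(dim(class_map) == dim(speed_max_up)))
  unclass(class_map == "multiple") & !is.na(speed_max_up) &
    speed_max_up < theta_slow
}

#' Direction histogram over a region
#'
#' Accumulates all read-out motions (weighted by their read-out weight)
#' inside a region of the MT grid into a direction histogram, normalized to
#' sum one. A region with no read-out motions yields all-zero mass and is
#' flagged by the attribute `empty = TRUE`.
#'
#' @param readout a [read_out_field()] result.
#' @param region logical matrix over the MT grid (default: everywhere).
#' @param n_bins number of direction bins over `[0, 360)`.
#' @return numeric vector of bin masses with attributes `breaks` (degrees)
#'   and `empty`.
#' @export
direction_histogram <- function(readout, region = NULL, n_bins = 16) {
  n <- readout$n
  if (is.null(region)) region <- matrix(TRUE, nrow(n), ncol(n))
  if (!any(region)) stop("empty region")
  counts <- numeric(n_bins)
  width <- 360 / n_bins
  for (idx in which(region & n > 0)) {
    mo <- readout$motions[[idx]]
    b <- floor((mo$direction %% 360) / width) + 1
    for (r in seq_len(nrow(mo))) counts[b[r]] <- counts[b[r]] + mo$weight[r]
  }
  tot <- sum(counts)
  out <- if (tot > 0) counts / tot else counts
  attr(out, "breaks") <- seq(0, 360, by = width)
  attr(out, "empty") <- tot == 0
  out
}

#' Calibrate the read-out threshold
#'
#' Runs the full V1-MT pipeline on a reference coherent translating dot
#' stimulus and returns `theta_motion_frac` times the peak MT activation -
#' the "theoretical single-motion maximum" of the calibrated pipeline.
#' Deterministic given the parameters (fixed internal seed).
#'
#' @param params a [motion_model_params()].
#' @param size,n_frames reference stimulus geometry.
#' @return threshold value.
#' @export
calibrate_motion_threshold <- function(params = motion_model_params(),
                                       size = c(64, 64), n_frames = 6) {
  fs <- make_translating_dots(
    n_dots = round(0.05 * prod(size)), speed = params$speeds[1],
    direction = 0, size = size, n_frames = n_frames, seed = 20120
  )
  v1 <- run_v1(fs, params, feedback = TRUE)
  peak <- max(vapply(v1$z3_mt, max, numeric(1)))
  params$theta_motion_frac * peak
}
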