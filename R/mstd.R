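# Model area MSTd: template matching for global optic-flow patterns
# (expansion, contraction, rotations and their spiral mixtures) over a grid
# of candidate pattern centres, with leaky temporal integration and
# normalization across spatial anchors.

#' Build MSTd pattern templates
#'
#' A template for anchor `(u, v)` and pattern angle `delta` assigns each MT
#' location and motion direction the likelihood
#' `[cos(phi - (psi + delta))]^+ * exp(-d^2 / (2 sigma_pat^2))`, where `psi`
#' is the angle from the anchor to the location (measured like motion
#' directions: 0 = rightward, 90 = up on screen) and `d` the distance to
#' the anchor. `delta = 0` matches expansion, 90 CCW rotation, 180
#' contraction, 270 CW rotation; odd multiples of 45 match spirals.
#' Anchors sit at `{0, 25, 50, 75, 100}% x {0, 50, 100}%` of the MT field
#' (15 anchors x 8 angles = 120 template cells) and the envelope width is
#' `sigma_pat_frac` of the field extent.
#'
#' @param h_mt,w_mt MT field size (rows, cols).
#' @param directions motion directions of the velocity grid (degrees).
#' @param params a [motion_model_params()].
#' @return object of class `"mstd_templates"`: list with `fields`, an array
#'   `h_mt x w_mt x nd x n_anchor x n_delta`; `anchors` (data frame with
#'   `u`, `v` in MT pixels and `u_pct`, `v_pct`); `deltas` (degrees).
#' @export
build_templates <- function(h_mt, w_mt, directions = seq(0, 315, by = 45),
                            params = motion_model_params()) {
  u_pct <- rep(c(0, 25, 50, 75, 100), times = 3)
  v_pct <- rep(c(0, 50, 100), each = 5)
  # percent positions to 1-based MT pixel coordinates, rounding half up
  half_up <- function(x) floor(x + 0.5)
  us <- half_up(u_pct / 100 * (w_mt - 1)) + 1
  vs <- half_up(v_pct / 100 * (h_mt - 1)) + 1
  deltas <- seq(0, 315, by = 45)
  if (any(us < 1 | us > w_mt | vs < 1 | vs > h_mt)) {
    stop("anchor outside the MT field")
  }
  sigma_pat <- params$sigma_pat_frac * max(h_mt, w_mt)
  nd <- length(directions)
  na <- length(us)
  fields <- array(0, c(h_mt, w_mt, nd, na, length(deltas)))
  xs <- matrix(rep(seq_len(w_mt), each = h_mt), h_mt, w_mt)
  ys <- matrix(rep(seq_len(h_mt), w_mt), h_mt, w_mt)
  for (a in seq_len(na)) {
    dx <- xs - us[a]
    dy <- ys - vs[a]
    psi <- atan2(-dy, dx) * 180 / pi  # y up, like motion directions
    env <- exp(-(dx^2 + dy^2) / (2 * sigma_pat^2))
    for (di in seq_along(deltas)) {
      pref <- psi + deltas[di]
      for (j in seq_len(nd)) {
        tun <- pmax(cos((directions[j] - pref) * pi / 180), 0)
        fields[, , j, a, di] <- tun * env
      }
    }
  }
  structure(list(
    fields = fields,
    anchors = data.frame(u = us, v = vs, u_pct = u_pct, v_pct = v_pct),
    deltas = deltas, directions = directions, sigma_pat = sigma_pat
  ), class = "mstd_templates")
}

#' @export
print.mstd_templates <- function(x, ...) {
  cat(sprintf(
    "<mstd_templates> %d anchors x %d pattern angles on %d x %d MT cells\n",
    nrow(x$anchors), length(x$deltas), dim(x$fields)[1], dim(x$fields)[2]
  ))
  invisible(x)
}

#' MSTd first stage: pattern projection with leaky temporal integration
#'
#' The MT signal is marginalized over speed (unweighted mean over the speed
#' channels), enhanced by the power `alpha`, and projected onto every
#' template by the inner product over space and direction. The projection
#' is folded into a leaky integrator:
#' `r1 = (1 - lambda_temp) * r1_prev + lambda_temp * p`.
#'
#' @param z3_mt MT output array `h x w x ns x nd`.
#' @param templates a [build_templates()] result matching `h x w x nd`.
#' @param r1_prev previous integrated response (`n_anchor x n_delta`
#'   matrix) or `NULL` for a zero initial state.
#' @param params a [motion_model_params()].
#' @return `n_anchor x n_delta` matrix `r1`; the raw projection is attached
#'   as attribute `"projection"`.
#' @export
mstd_integrate <- function(z3_mt, templates, r1_prev = NULL,
                           params = motion_model_params()) {
  d <- dim(z3_mt)
  tf <- dim(templates$fields)
  if (!all(d[c(1, 2, 4)] == tf[1:3])) {
    stop("template fields do not match the MT field size")
  }
  m <- rowMeans(aperm(z3_mt, c(1, 2, 4, 3)), dims = 3)  # mean over speeds
  m <- m^params$alpha
  na <- tf[4]; ndl <- tf[5]
  tmat <- matrix(templates$fields, nrow = prod(tf[1:3]), ncol = na * ndl)
  p <- matrix(as.vector(m) %*% tmat, na, ndl)
  lam <- params$lambda_temp
  if (is.null(r1_prev)) r1_prev <- matrix(0, na, ndl)
  r1 <- (1 - lam) * r1_prev + lam * p
  attr(r1, "projection") <- p
  r1
}

#' MSTd third stage: normalization across anchors, and display scaling
#'
#' For each pattern angle, the surround is the mean of `r1` over all
#' spatial anchors; the normalized response is
#' `r3 = r1 / (A_MST + B_MST * surround)`. Display values are `r3` scaled
#' to a maximum of one (all zeros stay zero).
#'
#' @param r1 `n_anchor x n_delta` matrix from [mstd_integrate()].
#' @param params a [motion_model_params()].
#' @return list with matrices `r3` and `display`.
#' @export
mstd_normalize <- function(r1, params = motion_model_params()) {
  surround <- matrix(colMeans(r1), nrow(r1), ncol(r1), byrow = TRUE)
  r3 <- r1 / (params$A_MST + params$B_MST * surround)
  mx <- max(r3)
  display <- if (mx > 0) r3 / mx else r3
  list(r3 = r3, display = display)
}

#' Export MSTd responses as a tidy table
#'
#' One row per (frame, anchor, pattern angle) with the normalized and
#' display responses; pattern angles are also labelled (EXP, CON, CW, CCW,
#' and spiral mixtures) in bar-chart-ready order.
#'
#' @param responses list over frames; each element a list with `r3` and
#'   `display` (from [mstd_normalize()]).
#' @param templates the [build_templates()] used.
#' @param path optional CSV path; when given the table is written there.
#' @return data frame with columns `frame`, `u_pct`, `v_pct`, `delta_deg`,
#'   `pattern`, `r3`, `display`.
#' @export
mstd_to_csv <- function(responses, templates, path = NULL) {
  labs <- c("EXP", "EXP&CCW", "CCW", "CON&CCW", "CON", "CON&CW", "CW",
            "EXP&CW")
  an <- templates$anchors
  rows <- lapply(seq_along(responses), function(t) {
    r <- responses[[t]]
    data.frame(
      frame = t,
      u_pct = rep(an$u_pct, times = length(templates$deltas)),
      v_pct = rep(an$v_pct, times = length(templates$deltas)),
      delta_deg = rep(templates$deltas, each = nrow(an)),
      pattern = rep(labs[match(templates$deltas, seq(0, 315, 45))],
                    each = nrow(an)),
      r3 = as.vector(r$r3),
      display = as.vector(r$display)
    )
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
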