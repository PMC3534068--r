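# Social-force pedestrian simulation and its bird's-eye rendering. The
# simulator follows the circular-specification force model widely used for
# escape-panic studies: each agent i accelerates toward its desired velocity
# v0*e with relaxation time tau, and is repelled from other agents and walls
# by an exponential "social" force A*exp((r - d)/B) plus, on contact, a body
# force k*(r - d) and a sliding-friction force kappa*(r - d)*dv_t.

#' Default social-force parameters
#'
#' The circular-specification defaults: relaxation time `tau` (s), repulsion
#' amplitude `A`, repulsion range `B` (m), body radius `radius` (m), desired
#' speed `v0` (m/s), body-force constant `k`, sliding-friction constant
#' `kappa`, agent mass `mass` (kg) and integration step `dt` (s).
#'
#' @return named list of parameters.
#' @export
social_force_params <- function() {
  list(tau = 0.5, A = 2000, B = 0.08, radius = 0.3, v0 = 1.34,
       k = 1.2e5, kappa = 2.4e5, mass = 80, dt = 0.02)
}

#' Crowd scenario
#'
#' Bundles the geometry and force parameters of a social-force simulation:
#' wall segments, per-agent state, the domain, and the rendering scale.
#'
#' @param agents data frame with columns `x`, `y` (m), `vx`, `vy` (m/s),
#'   `v0` (desired speed, m/s, > 0) and `gx`, `gy` (unit goal direction).
#' @param walls list of wall segments, each `c(x1, y1, x2, y2)` in meters.
#' @param domain domain size `c(length_x, width_y)` in meters.
#' @param cyclic_x wrap the x coordinate at the domain length.
#' @param params force parameters, see [social_force_params()].
#' @param pixels_per_meter rendering scale (default 10, so a 0.3 m-radius
#'   body spans ~6 px).
#' @return object of class `"crowd_scenario"`.
#' @export
crowd_scenario <- function(agents, walls = list(), domain = c(50, 10),
                           cyclic_x = TRUE, params = social_force_params(),
                           pixels_per_meter = 10) {
  stopifnot(is.data.frame(agents) || nrow(agents) == 0)
  if (nrow(agents) > 0) {
    stopifnot(all(c("x", "y", "vx", "vy", "v0", "gx", "gy") %in%
                    names(agents)))
    if (any(agents$v0 <= 0)) stop("desired speeds must be positive")
    for (w in walls) {
      d <- point_segment_distance(agents$x, agents$y, w)
      if (any(d$dist < params$radius)) {
        stop("agents must not be initialized inside walls")
      }
    }
  }
  structure(list(agents = agents, walls = walls, domain = domain,
                 cyclic_x = cyclic_x, params = params,
                 pixels_per_meter = pixels_per_meter),
            class = "crowd_scenario")
}

#' Corridor scenarios
#'
#' Builds the two reference scenarios: an open corridor (bidirectional flow
#' on a cyclic walkway, which self-organizes into lanes of alternating
#' direction) and a closed corridor whose ends are walled off except for
#' narrow exits (which produces clogging and a slow-down). Half of the
#' agents target the +x direction, the other half -x.
#'
#' @param n_agents number of pedestrians.
#' @param length,width corridor size in meters.
#' @param closed close the corridor ends, leaving only `exit_width` gaps.
#' @param exit_width width of the exits in the closed configuration (m).
#' @param params force parameters.
#' @param seed integer seed for initial placement.
#' @return a [crowd_scenario()].
#' @export
corridor_scenario <- function(n_agents = 200, length = 50, width = 10,
                              closed = FALSE, exit_width = 1,
                              params = social_force_params(), seed = NULL) {
  walls <- list(c(0, 0, length, 0), c(0, width, length, width))
  if (closed) {
    gap <- c(width / 2 - exit_width / 2, width / 2 + exit_width / 2)
    walls <- c(walls, list(
      c(0, 0, 0, gap[1]), c(0, gap[2], 0, width),
      c(length, 0, length, gap[1]), c(length, gap[2], length, width)
    ))
  }
  margin <- params$radius * 1.5
  agents <- with_seed(seed, {
    xs <- stats::runif(n_agents, margin, length - margin)
    ys <- stats::runif(n_agents, margin, width - margin)
    data.frame(
      x = xs, y = ys, vx = 0, vy = 0,
      v0 = params$v0,
      gx = rep(c(1, -1), length.out = n_agents),
      gy = 0
    )
  })
  crowd_scenario(agents, walls, domain = c(length, width), cyclic_x = TRUE,
                 params = params)
}

# Distance from points to a wall segment, with the closest point on the
# segment returned for the normal direction.
point_segment_distance <- function(px, py, seg) {
  ax <- seg[1]; ay <- seg[2]; bx <- seg[3]; by <- seg[4]
  abx <- bx - ax; aby <- by - ay
  len2 <- abx^2 + aby^2
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(pmax(((px - ax) * abx + (py - ay) * aby) / len2, 0), 1)
  cx <- ax + t * abx
  cy <- ay + t * aby
  list(dist = sqrt((px - cx)^2 + (py - cy)^2), cx = cx, cy = cy)
}

#' Simulate a crowd scenario with the social-force model
#'
#' Explicit Euler integration of the force model. Speeds are capped at
#' `1.3 * v0`; the x coordinate wraps cyclically when the scenario says so;
#' agents are hard-projected out of walls if the body force alone did not
#' keep them clear within one step.
#'
#' @param scenario a [crowd_scenario()].
#' @param n_steps number of integration steps.
#' @param dt integration step in seconds (default from the scenario
#'   parameters); must keep per-step displacement below the body radius.
#' @param record_every keep every `record_every`-th step in the output.
#' @return object of class `"crowd_trajectories"`: list with `x`, `y`, `vx`,
#'   `vy` (matrices `n_recorded x n_agents`), `time` (s), and the scenario.
#' @export
simulate_social_force <- function(scenario, n_steps, dt = NULL,
                                  record_every = 1) {
  p <- scenario$params
  if (is.null(dt)) dt <- p$dt
  ag <- scenario$agents
  n <- nrow(ag)
  rec_idx <- seq(1, n_steps + 1, by = record_every)
  nt <- length(rec_idx)
  out <- list(x = matrix(NA_real_, nt, n), y = matrix(NA_real_, nt, n),
              vx = matrix(NA_real_, nt, n), vy = matrix(NA_real_, nt, n),
              time = (rec_idx - 1) * dt, scenario = scenario)
  class(out) <- "crowd_trajectories"
  if (n == 0) return(out)

  L <- scenario$domain[1]
  x <- ag$x; y <- ag$y; vx <- ag$vx; vy <- ag$vy
  v0 <- ag$v0; gx <- ag$gx; gy <- ag$gy
  two_r <- 2 * p$radius
  rec <- 1
  store <- function(i) {
    out$x[i, ] <<- x; out$y[i, ] <<- y
    out$vx[i, ] <<- vx; out$vy[i, ] <<- vy
  }
  store(1); rec <- 2

  for (step in seq_len(n_steps)) {
    # driving force toward desired velocity
    ax <- (v0 * gx - vx) / p$tau
    ay <- (v0 * gy - vy) / p$tau

    if (n > 1) {
      dx <- outer(x, x, "-")
      if (scenario$cyclic_x) dx <- dx - L * round(dx / L)
      dy <- outer(y, y, "-")
      d <- sqrt(dx^2 + dy^2)
      diag(d) <- Inf
      nx <- dx / d; ny <- dy / d
      overlap <- two_r - d
      f_soc <- p$A * exp(overlap / p$B)
      touching <- overlap > 0
      f_body <- ifelse(touching, p$k * overlap, 0)
      fx <- (f_soc + f_body) * nx
      fy <- (f_soc + f_body) * ny
      if (any(touching)) {
        # sliding friction along the tangential direction t = (-ny, nx);
        # dvt[i, j] = (v_j - v_i) . t
        dvt <- (-outer(vx, vx, "-")) * (-ny) + (-outer(vy, vy, "-")) * nx
        f_fric <- ifelse(touching, p$kappa * overlap * dvt, 0)
        fx <- fx + f_fric * (-ny)
        fy <- fy + f_fric * nx
      }
      ax <- ax + rowSums(fx) / p$mass
      ay <- ay + rowSums(fy) / p$mass
    }

    for (w in scenario$walls) {
      ps <- point_segment_distance(x, y, w)
      d <- pmax(ps$dist, 1e-6)
      nx <- (x - ps$cx) / d
      ny <- (y - ps$cy) / d
      overlap <- p$radius - d
      f_soc <- p$A * exp(overlap / p$B)
      f_body <- ifelse(overlap > 0, p$k * overlap, 0)
      ax <- ax + (f_soc + f_body) * nx / p$mass
      ay <- ay + (f_soc + f_body) * ny / p$mass
      if (any(overlap > 0)) {
        dvt <- vx * (-ny) + vy * nx
        f_fric <- ifelse(overlap > 0, -p$kappa * overlap * dvt, 0)
        ax <- ax + f_fric * (-ny) / p$mass
        ay <- ay + f_fric * nx / p$mass
      }
    }

    vx <- vx + ax * dt
    vy <- vy + ay * dt
    spd <- sqrt(vx^2 + vy^2)
    cap <- 1.3 * v0
    over <- spd > cap
    if (any(over)) {
      sc <- cap[over] / spd[over]
      vx[over] <- vx[over] * sc
      vy[over] <- vy[over] * sc
    }
    spd <- sqrt(vx^2 + vy^2)
    if (max(spd) * dt > p$radius) {
      stop(sprintf(
        "social-force integration unstable at step %d: displacement %.3f m exceeds body radius %.2f m; reduce dt",
        step, max(spd) * dt, p$radius
      ))
    }
    x <- x + vx * dt
    y <- y + vy * dt
    if (scenario$cyclic_x) x <- x %% L

    # hard constraint: keep agent centres clear of walls
    for (w in scenario$walls) {
      ps <- point_segment_distance(x, y, w)
      bad <- ps$dist < p$radius * 0.5
      if (any(bad)) {
        d <- pmax(ps$dist[bad], 1e-6)
        x[bad] <- ps$cx[bad] + (x[bad] - ps$cx[bad]) / d * p$radius * 0.5
        y[bad] <- ps$cy[bad] + (y[bad] - ps$cy[bad]) / d * p$radius * 0.5
      }
    }

    if (rec <= nt && (step + 1) == rec_idx[rec]) {
      store(rec); rec <- rec + 1
    }
  }
  out
}

#' @export
print.crowd_trajectories <- function(x, ...) {
  cat(sprintf("<crowd_trajectories> %d agents, %d recorded steps, %.1f s\n",
              ncol(x$x), nrow(x$x), max(x$time)))
  invisible(x)
}

#' Render agent trajectories into a bird's-eye video
#'
#' Agents become bright anti-aliased discs on a dark ground; walls are drawn
#' as static mid-gray lines. One output frame is produced per recorded
#' trajectory step.
#'
#' @param traj a `"crowd_trajectories"` object from
#'   [simulate_social_force()].
#' @param agent_radius_px disc radius in pixels (>= 2).
#' @param steps indices of recorded steps to render (default all).
#' @return a [frame_stack()] of size
#'   `round(width * ppm) x round(length * ppm) x length(steps)`.
#' @export
render_agents <- function(traj, agent_radius_px = 3, steps = NULL) {
  if (agent_radius_px < 2) stop("agent_radius_px must be >= 2")
  sc <- traj$scenario
  ppm <- sc$pixels_per_meter
  W <- round(sc$domain[1] * ppm)
  H <- round(sc$domain[2] * ppm)
  if (is.null(steps)) steps <- seq_len(nrow(traj$x))
  wall_img <- matrix(0, H, W)
  gx <- rep(0:(W - 1), each = H) + 0.5
  gy <- rep(0:(H - 1), W) + 0.5
  for (w in sc$walls) {
    ps <- point_segment_distance(gx / ppm, gy / ppm, w)
    wall_img[ps$dist * ppm < 1.5] <- 0.5
  }
  out <- array(0, c(H, W, length(steps)))
  for (i in seq_along(steps)) {
    t <- steps[i]
    img <- render_dots(traj$x[t, ] * ppm, traj$y[t, ] * ppm, H, W,
                       agent_radius_px, base = wall_img)
    out[, , i] <- img
  }
  frame_stack(out)
}

#' Write trajectories to CSV
#'
#' One row per (recorded step, agent): `step`, `agent_id`, `x_m`, `y_m`,
#' `vx`, `vy`.
#'
#' @param traj a `"crowd_trajectories"` object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trajectories_csv <- function(traj, path) {
  nt <- nrow(traj$x); n <- ncol(traj$x)
  df <- data.frame(
    step = rep(seq_len(nt), each = n),
    agent_id = rep(seq_len(n), nt),
    x_m = as.vector(t(traj$x)), y_m = as.vector(t(traj$y)),
    vx = as.vector(t(traj$vx)), vy = as.vector(t(traj$vy))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
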