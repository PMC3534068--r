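# Shared fixtures for the test suite: the default parameter set, the
# calibrated read-out threshold (computed once per run), and small
# constructors for synthetic read-out fields.

.cache <- new.env(parent = emptyenv())

test_theta <- function() {
  if (is.null(.cache$theta)) {
    .cache$theta <- calibrate_motion_threshold(motion_model_params())
  }
  .cache$theta
}

# Circular difference helper mirrored here so tests do not rely on
# internal functions.
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Build a minimal readout_field from primary-motion component matrices,
# for gradient tests on analytic vector fields.
synthetic_readout <- function(vx, vy) {
  speed <- sqrt(vx^2 + vy^2)
  structure(list(
    vx1 = vx, vy1 = vy, speed1 = speed,
    dir1 = (atan2(vy, vx) * 180 / pi) %% 360,
    speed_max = speed,
    n = matrix(as.integer(!is.na(vx)), nrow(vx), ncol(vx))
  ), class = "readout_field")
}

# MT-resolution labels after the 3-frame consistency rule, from the last
# three frame pairs of a pipeline's MT outputs.
stabilized_mt_labels <- function(z3_mt_list, grid, theta) {
  n <- length(z3_mt_list)
  stopifnot(n >= 3)
  ros <- lapply(z3_mt_list[(n - 2):n], read_out_field, grid = grid,
                theta_motion = theta)
  labs <- lapply(ros, classify_motions)
  stab <- labs[[3]]
  stab[!(labs[[1]] == labs[[2]] & labs[[2]] == labs[[3]])] <- "none"
  list(labels = stab, readout = ros[[3]])
}
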