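# Synthetic stimulus generators: dot fields, lanes, pattern flows.

test_that("frame stacks enforce their invariants", {
  expect_error(frame_stack(array(0, c(16, 16, 1))), "at least T = 2")
  expect_error(frame_stack(array(0, c(8, 16, 2))), "16 x 16")
  expect_error(frame_stack(array(2, c(16, 16, 2))), "\\[0, 1\\]")
  bad <- array(0, c(16, 16, 2)); bad[1] <- NA
  expect_error(frame_stack(bad), "finite")
})

test_that("translating dots: static case, roll oracle, determinism", {
  # speed 0: every frame identical
  fs0 <- make_translating_dots(20, 0, 0, c(32, 32), 3, seed = 1)
  expect_identical(fs0[, , 1], fs0[, , 3])

  # speed 1 rightward: frame 3 equals frame 1 cyclically rolled by 2 px in x
  fs <- make_translating_dots(20, 1, 0, c(32, 32), 3, seed = 1)
  rolled <- fs[, , 1][, ((seq_len(32) - 1 - 2) %% 32) + 1]
  expect_equal(fs[, , 3], rolled, tolerance = 1e-12)

  # upward motion decreases the row index
  fsu <- make_translating_dots(20, 1, 90, c(32, 32), 3, seed = 1)
  rolled_up <- fsu[, , 1][((seq_len(32) - 1 + 2) %% 32) + 1, ]
  expect_equal(fsu[, , 3], rolled_up, tolerance = 1e-12)

  # same seed, bit-identical stacks
  a <- make_translating_dots(50, 1.3, 37, c(32, 32), 4, seed = 9)
  b <- make_translating_dots(50, 1.3, 37, c(32, 32), 4, seed = 9)
  expect_identical(unclass(a), unclass(b))

  expect_error(make_translating_dots(5, 1, 0, c(32, 32), 3, dot_radius = 16),
               "dot_radius")
})

test_that("transparent dots compose as the pixelwise max of components", {
  comps <- list(list(n_dots = 20, speed = 1, direction = 0, seed = 4),
                list(n_dots = 20, speed = 1, direction = 180, seed = 5))
  both <- make_transparent_dots(comps, c(32, 32), 3)
  s1 <- make_translating_dots(20, 1, 0, c(32, 32), 3, seed = 4)
  s2 <- make_translating_dots(20, 1, 180, c(32, 32), 3, seed = 5)
  expect_equal(unclass(both), pmax(unclass(s1), unclass(s2)))

  # one component degenerates to the single-field generator
  one <- make_transparent_dots(comps[1], c(32, 32), 3)
  expect_equal(unclass(one), unclass(s1))

  # different seeds give different layouts
  other <- make_transparent_dots(list(
    list(n_dots = 20, speed = 1, direction = 0, seed = 6),
    list(n_dots = 20, speed = 1, direction = 180, seed = 7)
  ), c(32, 32), 3)
  expect_false(identical(unclass(both), unclass(other)))
})

test_that("lane stimulus: single lane, per-row displacement, empty case", {
  # lane width = H is a pure single-direction translation
  fs <- make_lane_stimulus(32, 1, c(32, 32), 3, dot_density = 0.05, seed = 2)
  rolled <- fs[, , 1][, ((seq_len(32) - 1 - 2) %% 32) + 1]
  expect_equal(fs[, , 3], rolled, tolerance = 1e-12)
  expect_true(all(attr(fs, "lane_direction") == 0))

  # two lanes: cross-correlation of each half peaks at the signed shift
  fs2 <- make_lane_stimulus(16, 2, c(32, 32), 3, dot_density = 0.08,
                            dot_radius = 1, seed = 3)
  best_shift <- function(a, b) {
    # shift s maximizing the overlap of frame b pulled back by s columns
    sc <- vapply(0:31, function(s) {
      sum(a * b[, ((seq_len(32) - 1 + s) %% 32) + 1])
    }, numeric(1))
    shifts <- 0:31
    shifts[which.max(sc)]
  }
  top_shift <- best_shift(fs2[1:12, , 1], fs2[1:12, , 2])
  bot_shift <- best_shift(fs2[21:32, , 1], fs2[21:32, , 2])
  expect_equal(top_shift, 2)        # rightward lane: +2 px
  expect_equal(bot_shift, 32 - 2)   # leftward lane: -2 px (mod 32)
  expect_equal(attr(fs2, "lane_direction")[c(1, 32)], c(0, 180))

  # zero density: an all-black stack
  dark <- make_lane_stimulus(8, 1, c(32, 32), 3, dot_density = 0, seed = 1)
  expect_true(all(dark == 0))

  expect_error(make_lane_stimulus(0, 1, c(32, 32), 3), "lane_width")
})

test_that("pattern movies: flow geometry, rotation identity, Euler oracle", {
  fs <- make_pattern_movie("EXP", c(16, 16), c(32, 32), 3, gain = 0.05,
                           seed = 8)
  fl <- attr(fs, "flow")
  # right of the centre the EXP flow points in +x only
  expect_gt(fl$vx[17, 25], 0)
  expect_equal(fl$vy[17, 25], 0, tolerance = 1e-12)
  # left of the centre it points in -x
  expect_lt(fl$vx[17, 9], 0)

  # CCW flow is the EXP flow rotated by 90 degrees at every pixel
  fc <- make_pattern_movie("CCW", c(16, 16), c(32, 32), 3, gain = 0.05,
                           seed = 8)
  flc <- attr(fc, "flow")
  # rotating (vx, vy_up) by +90 deg: (vx, vy) -> (-vy_up, vx) with y up;
  # in image coords vy_img = -vy_up
  expect_equal(flc$vx, -(-fl$vy), tolerance = 1e-12)
  expect_equal(-flc$vy, fl$vx, tolerance = 1e-12)

  # a single advected dot tracks an explicit Euler integration of the
  # expansion field (disc centroids recover sub-pixel position)
  gain <- 0.04; u <- 16; v <- 16
  fs2 <- make_pattern_movie("EXP", c(u, v), c(32, 32), 11, gain = gain,
                            n_dots = 1, seed = 3)
  centroid <- function(m) {
    xs <- matrix(rep(0:31, each = 32), 32, 32)
    ys <- matrix(rep(0:31, 32), 32, 32)
    c(sum(xs * m), sum(ys * m)) / sum(m)
  }
  p <- centroid(fs2[, , 1])
  for (t in 1:10) p <- p + gain * (p - c(u, v))  # EXP in image coords
  expect_lt(sqrt(sum((centroid(fs2[, , 11]) - p)^2)), 0.5)

  expect_error(make_pattern_movie("EXP", c(100, 16), c(32, 32), 3),
               "center")
  expect_error(make_pattern_movie("XYZ", c(16, 16), c(32, 32), 3),
               "unknown pattern")
})
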