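# Read-out, classification, temporal stabilization, gradients, danger
# zones and direction histograms.

test_that("read-out: flat, delta-peak and bimodal activations", {
  grid <- velocity_grid()

  # flat activation below threshold: no motion
  flat <- matrix(0.01, 3, 8)
  expect_equal(nrow(read_out(flat, grid, theta_motion = 0.1)), 0)

  # a single delta peak at (2 px/frame, 90 deg) reads out exactly
  a <- matrix(0, 3, 8); a[2, 3] <- 1
  mo <- read_out(a, grid, theta_motion = 0.1)
  expect_equal(nrow(mo), 1)
  expect_equal(mo$speed, 2, tolerance = 1e-9)
  expect_equal(mo$direction, 90, tolerance = 1e-9)

  # equal bimodal peaks at 0 and 180 deg, 1 px/frame: two motions, each
  # within half a grid bin of its mode
  b <- matrix(0, 3, 8)
  b[1, 1] <- 1; b[1, 5] <- 1
  b[1, 2] <- b[1, 8] <- 0.3; b[1, 4] <- b[1, 6] <- 0.3
  mo2 <- read_out(b, grid, theta_motion = 0.1)
  expect_equal(nrow(mo2), 2)
  expect_lt(min(ang_diff(mo2$direction, 0)), 22.5)
  expect_lt(min(ang_diff(mo2$direction, 180)), 22.5)
  expect_true(all(abs(mo2$speed - 1) < 0.25))
  expect_true(all(mo2$weight > 0))

  # candidates within 20 deg of an extracted motion are absorbed: a
  # same-direction peak on another speed ring adds no second motion
  d <- matrix(0, 3, 8); d[1, 1] <- 1; d[3, 1] <- 0.8
  expect_equal(nrow(read_out(d, grid, theta_motion = 0.1)), 1)

  expect_error(read_out(matrix(-1, 3, 8), grid, 0.1))
})

test_that("classification maps counts to the three labels", {
  n <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  lab <- classify_motions(n)
  expect_equal(as.vector(lab), c("none", "single", "multiple", "multiple"))
})

test_that("3-frame consistency rule and nearest-neighbor upsampling", {
  mk <- function(l) matrix(l, 2, 2)
  # [single, single, single] survives; [single, multiple, single] does not
  out <- stabilize_and_upsample(list(mk("single"), mk("single"),
                                     mk("single")), c(4, 4))
  expect_true(all(out[[3]] == "single"))
  out2 <- stabilize_and_upsample(list(mk("single"), mk("multiple"),
                                      mk("single")), c(4, 4))
  expect_true(all(out2[[3]] == "none"))
  # constant multiple stays white everywhere from frame 3 on
  out3 <- stabilize_and_upsample(rep(list(mk("multiple")), 5), c(6, 6))
  for (t in 3:5) expect_true(all(out3[[t]] == "multiple"))
  # the first two frames carry no stabilized labels
  expect_true(all(out3[[1]] == "none") && all(out3[[2]] == "none"))
  # fewer than three frames: warned, all none
  expect_warning(short <- stabilize_and_upsample(list(mk("single"),
                                                      mk("single")),
                                                 c(4, 4)),
                 "fewer than 3")
  expect_true(all(short[[2]] == "none"))
  # upsampling is nearest neighbor: blocks of the low-res map
  mixed <- matrix(c("single", "none", "multiple", "none"), 2, 2)
  up <- stabilize_and_upsample(rep(list(mixed), 3), c(4, 4))[[3]]
  expect_equal(up[1:2, 1:2], matrix("single", 2, 2))
  expect_equal(up[1:2, 3:4], matrix("multiple", 2, 2))
})

test_that("class maps encode to the published gray levels", {
  m <- matrix(c("none", "single", "multiple", "none"), 2, 2)
  enc <- encode_class_map(m)
  expect_equal(as.vector(enc), c(0L, 128L, 255L, 0L))
})

test_that("gauge-coordinate gradients have the canonical signs", {
  n <- 15
  xs <- matrix(rep(1:n, each = n), n, n)
  ys <- matrix(rep(1:n, n), n, n)
  u <- (n + 1) / 2
  interior <- matrix(FALSE, n, n); interior[4:(n - 3), 4:(n - 3)] <- TRUE

  # uniform translation: both gauge derivatives vanish
  g0 <- velocity_gradients(synthetic_readout(matrix(1.3, n, n),
                                             matrix(0.4, n, n)))
  expect_lt(max(abs(g0$gt[interior])), 1e-9)
  expect_lt(max(abs(g0$gn[interior])), 1e-9)

  # ideal expansion v = k (x - u, y - v): g_t = +k, g_n = 0
  k <- 0.2
  gexp <- velocity_gradients(synthetic_readout(k * (xs - u), -k * (ys - u)))
  expect_equal(median(gexp$gt[interior]), k, tolerance = 0.02)
  expect_lt(max(abs(gexp$gn[interior])), 0.02)

  # contraction flips the tangential sign
  gcon <- velocity_gradients(synthetic_readout(-k * (xs - u), k * (ys - u)))
  expect_equal(median(gcon$gt[interior]), -k, tolerance = 0.02)

  # rigid CCW rotation (y up): g_t = 0, g_n = +omega everywhere interior
  w <- 0.2
  vx <- -w * (-(ys - u)); vy <- w * (xs - u)  # math coords, y up
  gccw <- velocity_gradients(synthetic_readout(vx, vy))
  expect_lt(max(abs(gccw$gt[interior])), 0.02)
  expect_equal(median(gccw$gn[interior]), w, tolerance = 0.02)
  # chi near +90 degrees for CCW
  expect_lt(max(abs(gccw$chi[interior] - 90)), 15)
})

test_that("danger rule: transparency AND slow speed, never elsewhere", {
  cm <- matrix(c("multiple", "multiple", "single", "none"), 2, 2)
  sp <- matrix(c(0.3, 2, 0.3, 0.3), 2, 2)
  dz <- danger_zones(cm, sp, theta_slow = 0.5)
  expect_equal(as.vector(dz), c(TRUE, FALSE, FALSE, FALSE))
  # danger is a subset of the multiple-motion map by construction
  expect_true(all(!dz | (cm == "multiple")))
})

test_that("direction histograms separate single and transparent regions", {
  p <- motion_model_params()
  grid <- velocity_grid()
  th <- test_theta()

  fs <- make_translating_dots(200, 1, 90, c(64, 64), 6, seed = 21)
  ro <- read_out_field(run_v1(fs, p)$z3_mt[[5]], grid, th)
  h1 <- direction_histogram(ro, n_bins = 8)
  expect_equal(sum(h1), 1, tolerance = 1e-9)
  # unimodal: the two bins around 90 degrees hold the bulk of the mass
  expect_gt(h1[2] + h1[3], 0.5)

  ft <- make_transparent_dots(list(
    list(n_dots = 150, speed = 1, direction = 0),
    list(n_dots = 150, speed = 1, direction = 180)
  ), c(64, 64), 6, seed = 22)
  ro2 <- read_out_field(run_v1(ft, p)$z3_mt[[5]], grid, th)
  h2 <- direction_histogram(ro2, n_bins = 8)
  # bimodal, modes ~180 degrees apart
  expect_gt(h2[1] + h2[8], 0.25)
  expect_gt(h2[4] + h2[5], 0.25)

  # an empty region errors; a region with no motions is flagged
  expect_error(direction_histogram(ro, region = matrix(FALSE, 13, 13)),
               "empty region")
  static <- read_out_field(array(0, c(3, 3, 3, 8)), grid, th)
  h0 <- direction_histogram(static, n_bins = 8)
  expect_true(attr(h0, "empty"))
  expect_true(all(h0 == 0))
})
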