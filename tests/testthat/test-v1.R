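# V1: initial motion detection and the three-stage cascade.

test_that("initial motion peaks at the true velocity and rejects statics", {
  p <- motion_model_params()
  grid <- velocity_grid()
  bank <- build_gabor_bank(48, 48, p)
  fs <- make_translating_dots(120, 1, 0, c(48, 48), 3, seed = 6)
  cc <- initial_motion(gabor_responses(fs[, , 1], bank),
                       gabor_responses(fs[, , 2], bank), bank, grid)
  expect_true(all(cc >= 0))
  # at dot-covered pixels the argmax over (speed, direction) is (1, 0 deg)
  dotpix <- which(fs[, , 1] > 0.5)
  hits <- 0
  for (px in dotpix) {
    ij <- arrayInd(px, c(48, 48))
    cell <- matrix(cc[ij[1], ij[2], , ], 3, 8)
    if (max(cell) > 0 && which.max(cell) == 1) hits <- hits + 1
  }
  expect_gt(hits / length(dotpix), 0.8)

  # a static pattern cancels exactly (forward = backward)
  g1 <- gabor_responses(fs[, , 1], bank)
  cc0 <- initial_motion(g1, g1, bank, grid)
  expect_equal(max(cc0), 0, tolerance = 1e-12)

  # counterphase flicker stays far below the matched coherent response
  fl <- make_flicker_dots(120, c(48, 48), 3, seed = 6)
  ccf <- initial_motion(gabor_responses(fl[, , 1], bank),
                        gabor_responses(fl[, , 2], bank), bank, grid)
  expect_lt(mean(ccf), 0.05 * mean(cc))

  # a speed with no matching ring is rejected
  expect_error(
    initial_motion(g1, g1, bank, velocity_grid(speeds = c(1, 2, 8))),
    "match"
  )
})

test_that("stage 1 is the velocity-space impulse response", {
  p <- motion_model_params()
  cc <- array(0, c(4, 4, 3, 8))
  cc[2, 2, 2, 3] <- 2
  z1 <- v1_stage1(cc, p)
  # impulse^alpha spread by the separable speed/direction kernels, the
  # direction axis circular, the speed axis mass-conserving at its ends:
  # compare against a direct evaluation of those kernels
  sp <- c(1, 2, 4)
  S <- outer(sp, sp, function(a, b) exp(-(a - b)^2 / (2 * 0.5^2)))
  S <- S / rowSums(S)
  dirs <- seq(0, 315, by = 45)
  cd <- pmin(abs(dirs - dirs[3]), 360 - abs(dirs - dirs[3]))
  dk <- exp(-cd^2 / (2 * 30^2))
  dk <- dk / sum(exp(-pmin(dirs, 360 - dirs)^2 / (2 * 30^2)))
  for (i in 1:3) for (j in 1:8) {
    expect_equal(z1[2, 2, i, j], 4 * S[i, 2] * dk[j], tolerance = 1e-9)
  }
  # spatial structure untouched, zero elsewhere
  expect_equal(sum(z1[-2, , , ]), 0)
  expect_equal(sum(z1), sum(z1[2, 2, , ]))

  # zero in, zero out
  expect_equal(max(v1_stage1(array(0, c(4, 4, 3, 8)), p)), 0)

  # two equal impulses 180 degrees apart: two equal modes, none between
  cc2 <- array(0, c(2, 2, 3, 8))
  cc2[1, 1, 1, 1] <- 1; cc2[1, 1, 1, 5] <- 1
  z2 <- v1_stage1(cc2, p)
  prof <- z2[1, 1, 1, ]
  expect_equal(prof[1], prof[5], tolerance = 1e-12)
  expect_gt(prof[1], prof[3])  # no spurious mean-direction mode at 90 deg
})

test_that("stage 2 is modulatory: feedback cannot create activity", {
  p <- motion_model_params()  # gamma = 100
  z1 <- array(runif(4 * 4 * 3 * 8), c(4, 4, 3, 8))
  expect_equal(v1_stage2(z1, NULL, p), z1)
  expect_equal(v1_stage2(z1, array(0, dim(z1)), p), z1)
  # zero driving signal stays zero no matter the feedback
  expect_equal(max(v1_stage2(array(0, dim(z1)), array(1, dim(z1)), p)), 0)
  # gamma = 100, z1 = 0.01, fb = 1 -> 0.01 * 101 = 1.01
  z <- array(0.01, dim(z1))
  expect_equal(v1_stage2(z, array(1, dim(z1)), p)[1], 1.01)
  expect_error(v1_stage2(z1, array(-1, dim(z1)), p), "nonnegative")
})

test_that("stage 3 matches its closed form and favors single motions", {
  p <- motion_model_params(A_V1 = 0.01, B_V1 = 1)
  z <- array(0, c(2, 2, 3, 8))
  expect_equal(max(v1_stage3(z, p)), 0)

  # one active cell with value v: z3 = v / (A + B v) < 1/B, monotone in v
  vals <- c(0.1, 0.5, 2, 10)
  outs <- vapply(vals, function(v) {
    z <- array(0, c(2, 2, 3, 8)); z[1, 1, 2, 3] <- v
    v1_stage3(z, p)[1, 1, 2, 3]
  }, numeric(1))
  expect_equal(outs, vals / (0.01 + vals), tolerance = 1e-12)
  expect_true(all(diff(outs) > 0))
  expect_true(all(outs < 1))

  # two equal peaks share the pool: each roughly half the lone response
  z2 <- array(0, c(2, 2, 3, 8))
  z2[1, 1, 1, 1] <- 1; z2[1, 1, 1, 5] <- 1
  two <- v1_stage3(z2, p)[1, 1, 1, 1]
  expect_equal(two, 1 / (0.01 + 2), tolerance = 1e-12)
})

test_that("cascade preserves nonnegativity and the B >= 1 bound", {
  p <- motion_model_params(B_V1 = 1)
  set.seed(33)
  for (rep in 1:20) {
    cc <- array(rexp(2 * 2 * 3 * 8, rate = 0.2), c(2, 2, 3, 8))
    z1 <- v1_stage1(cc, p)
    z2 <- v1_stage2(z1, array(runif(length(z1)), dim(z1)), p)
    z3 <- v1_stage3(z2, p)
    expect_true(all(z1 >= 0) && all(z2 >= 0) && all(z3 >= 0))
    expect_true(all(z3 <= 1))
  }
})

test_that("run_v1 honors feedback semantics and direction equivariance", {
  p <- motion_model_params()
  fs <- make_translating_dots(60, 1, 0, c(32, 32), 3, seed = 12)
  out <- run_v1(fs, p, feedback = TRUE)
  expect_length(out$z3_v1, 2)

  # gamma = 0 equals no feedback entirely
  p0 <- motion_model_params(gamma = 0)
  a <- run_v1(fs, p0, feedback = TRUE)$z3_v1[[2]]
  b <- run_v1(fs, p0, feedback = FALSE)$z3_v1[[2]]
  expect_equal(a, b, tolerance = 1e-12)

  # with feedback the matched velocity's share of activation cannot drop
  withfb <- run_v1(fs, p, feedback = TRUE)$z3_v1[[2]]
  nofb <- run_v1(fs, p, feedback = FALSE)$z3_v1[[2]]
  share <- function(z) sum(z[, , 1, 1]) / sum(z)
  expect_gte(share(withfb) + 1e-9, share(nofb))

  # rotating the stimulus by 90 degrees permutes the direction axis: a
  # field moving up instead of right moves its mass two direction bins on
  sfu <- make_translating_dots(60, 1, 90, c(32, 32), 3, seed = 12)
  cu <- run_v1(sfu, p, feedback = FALSE)$z3_v1[[2]]
  cr <- nofb
  md_r <- which.max(apply(cr, 4, sum))
  md_u <- which.max(apply(cu, 4, sum))
  expect_equal(md_r, 1)  # 0 degrees
  expect_equal(md_u, 3)  # 90 degrees
})
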