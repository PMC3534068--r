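# MSTd: pattern templates, temporal integration, normalization.

test_that("templates encode the radial geometry and cosine identities", {
  tpl <- build_templates(13, 13)
  expect_equal(dim(tpl$fields), c(13, 13, 8, 15, 8))
  expect_equal(nrow(tpl$anchors), 15)

  # central anchor, location directly to its right: EXP tuning peaks at
  # phi = 0 degrees
  ctr <- which(tpl$anchors$u_pct == 50 & tpl$anchors$v_pct == 50)
  di0 <- which(tpl$deltas == 0)
  prof <- tpl$fields[7, 11, , ctr, di0]
  expect_equal(which.max(prof), 1)

  # T_{delta+180}(phi) = T_delta(phi + 180)
  di180 <- which(tpl$deltas == 180)
  for (j in 1:8) {
    jj <- ((j - 1 + 4) %% 8) + 1
    expect_equal(tpl$fields[, , j, ctr, di180],
                 tpl$fields[, , jj, ctr, di0], tolerance = 1e-12)
  }

  # envelope decays by exp(-1/2) at one sigma from the anchor
  sig <- tpl$sigma_pat
  on_anchor <- max(tpl$fields[7, 7, , ctr, di0])
  d <- 4  # px along +x from the anchor
  at_d <- max(tpl$fields[7, 7 + d, , ctr, di0])
  expect_equal(at_d / on_anchor, exp(-d^2 / (2 * sig^2)), tolerance = 1e-9)
})

test_that("integration projects, leaks, and finds the matching pattern", {
  p <- motion_model_params()
  tpl <- build_templates(9, 9)

  # zero input: geometric decay of the integrated state
  r1 <- matrix(1, 15, 8)
  z0 <- array(0, c(9, 9, 3, 8))
  for (k in 1:3) r1 <- mstd_integrate(z0, tpl, r1, p)
  expect_equal(max(r1), (1 - p$lambda_temp)^3, tolerance = 1e-12)

  # fixed point: a state equal to the projection stays put
  z <- array(0, c(9, 9, 3, 8)); z[5, 7, , 1] <- 1
  pr <- attr(mstd_integrate(z, tpl, NULL, p), "projection")
  r1fix <- mstd_integrate(z, tpl, pr, p)
  expect_equal(unclass(r1fix), unclass(pr), tolerance = 1e-12,
               ignore_attr = TRUE)

  # an ideal EXP flow about the central anchor projects strongest onto
  # (central anchor, delta = 0), by brute-force comparison over all 120
  ctr <- which(tpl$anchors$u_pct == 50 & tpl$anchors$v_pct == 50)
  zexp <- array(0, c(9, 9, 3, 8))
  u <- tpl$anchors$u[ctr]; v <- tpl$anchors$v[ctr]
  dirs <- seq(0, 315, by = 45)
  for (y in 1:9) for (x in 1:9) {
    if (x == u && y == v) next
    psi <- (atan2(-(y - v), x - u) * 180 / pi) %% 360
    j <- which.min(pmin(abs(dirs - psi), 360 - abs(dirs - psi)))
    zexp[y, x, 2, j] <- 1
  }
  pr <- attr(mstd_integrate(zexp, tpl, NULL, p), "projection")
  best <- arrayInd(which.max(pr), dim(pr))
  expect_equal(best[1], ctr)
  expect_equal(tpl$deltas[best[2]], 0)

  expect_error(mstd_integrate(array(0, c(5, 5, 3, 8)), tpl, NULL, p),
               "size")
})

test_that("normalization pools over anchors and scales for display", {
  p <- motion_model_params()  # A_MST = 0.01, B_MST = 10

  # uniform r1: all r3 equal, display all one
  r1 <- matrix(0.2, 15, 8)
  out <- mstd_normalize(r1, p)
  expect_equal(max(out$r3), min(out$r3), tolerance = 1e-12)
  expect_true(all(out$display == 1))

  # one active anchor among 15: its r3 dominates by at least 10x
  r1 <- matrix(0, 15, 8); r1[4, 3] <- 1; r1[, 3] <- r1[, 3] + 0.01
  out <- mstd_normalize(r1, p)
  expect_gt(out$r3[4, 3] / max(out$r3[-4, 3]), 10)

  # closed form: r3 = r1 / (A + B * mean_anchors(r1)) per delta
  expect_equal(out$r3[4, 3],
               r1[4, 3] / (0.01 + 10 * mean(r1[, 3])), tolerance = 1e-12)

  # doubling r1 leaves the display values unchanged when A is negligible
  pbig <- motion_model_params(A_MST = 1e-12)
  d1 <- mstd_normalize(r1, pbig)$display
  d2 <- mstd_normalize(2 * r1, pbig)$display
  expect_equal(d1, d2, tolerance = 1e-9)

  # all-zero state: display all zeros, no NaN
  z <- mstd_normalize(matrix(0, 15, 8), p)
  expect_true(all(z$display == 0))
})

test_that("the pattern CSV is tidy and labelled in panel order", {
  p <- motion_model_params()
  tpl <- build_templates(9, 9)
  z <- array(0, c(9, 9, 3, 8)); z[3, 3, 1, 2] <- 1
  r1 <- mstd_integrate(z, tpl, NULL, p)
  resp <- list(mstd_normalize(r1, p))
  path <- tempfile(fileext = ".csv")
  df <- mstd_to_csv(resp, tpl, path)
  expect_true(file.exists(path))
  expect_equal(nrow(df), 15 * 8)
  expect_equal(unique(df$pattern[df$delta_deg == 225]), "CON&CW")
  expect_equal(unique(df$pattern[df$delta_deg == 0]), "EXP")
  expect_equal(max(df$display), 1)
})
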