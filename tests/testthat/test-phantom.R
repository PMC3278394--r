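test_that("the first cardiac phase is the identity mapping", {
  m <- smallModel()
  pts <- randomAnnulusPoints(m, 20)
  expect_equal(unname(evaluateMotion(m, pts, phase = 1)), unname(pts),
               tolerance = 1e-12)

  p <- renderDenseSeries(smallModel(), smallAcq())
  d1 <- p$truth@displacement$dx[, , , 1]
  expect_true(all(abs(d1[p$truth@mask[, , , 1]]) < 1e-12))
  s1 <- p$truth@strainRCL$rr[, , , 1]
  expect_true(all(abs(s1[!is.na(s1)]) < 1e-12))
})

test_that("points outside the reference annulus are rejected", {
  m <- smallModel()
  expect_error(evaluateMotion(m, c(0.1, 0, 3), phase = 2),
               class = "outOfMyocardium")
  expect_error(evaluateMotion(m, c(m@epiRadius + 1, 0, 3), phase = 2),
               class = "outOfMyocardium")
})

test_that("pure twist rotates linearly in z and carries no normal strain", {
  tau <- 0.5  # deg/mm, gentle so the quadratic twist term is negligible
  m <- smallModel(peakContraction = 1, peakShortening = 0,
                  peakTwistPerLength = tau)
  zb <- m@lvLength
  set.seed(11)
  pts <- randomAnnulusPoints(m, 25)
  w <- denseMechanics:::phaseWeight(m, 3L)
  out <- evaluateMotion(m, pts, phase = 3)
  ## rotation angle about +z: alpha = -(pi/180) tau w (zBase - z)
  a0 <- atan2(pts[, 2], pts[, 1])
  a1 <- atan2(out[, 2], out[, 1])
  expect_equal(wrapPhase(a1 - a0),
               -(pi / 180) * tau * w * (zb - pts[, 3]), tolerance = 1e-9)
  expect_equal(sqrt(out[, 1]^2 + out[, 2]^2),
               sqrt(pts[, 1]^2 + pts[, 2]^2), tolerance = 1e-9)
  ## finite-difference oracle: in-plane normal strains vanish
  for (i in 1:5) {
    Ffd <- fdDeformationGradient(m, pts[i, ], 3L)
    E <- (t(Ffd) %*% Ffd - diag(3)) / 2
    rcl <- cylProject(E, pts[i, ])
    expect_lt(abs(rcl["rr"]), 1e-8)
    expect_lt(abs(rcl["cc"]), 1e-8)
    expect_lt(abs(rcl["ll"]), 1e-3)  # r^2 alpha'^2 / 2, second order in tau
  }
})

test_that("incompressible deformation has unit Jacobian everywhere", {
  m <- smallModel()
  set.seed(4)
  pts <- randomAnnulusPoints(m, 100)
  for (f in c(2L, 3L, 5L)) {
    dets <- vapply(seq_len(nrow(pts)), function(i)
      det(fdDeformationGradient(m, pts[i, ], f)), numeric(1))
    expect_true(all(abs(dets - 1) < 1e-6))
  }
})

test_that("analytic RCL strain matches the finite-difference oracle", {
  for (m in list(smallModel(),
                 smallModel(incompressible = FALSE, peakContraction = 0.9,
                            peakTwistPerLength = 0, peakShortening = 0))) {
    set.seed(2)
    pts <- randomAnnulusPoints(m, 15)
    for (f in c(2L, 3L)) {
      ana <- denseMechanics:::analyticStrainRCL(m, pts, f)
      for (i in seq_len(nrow(pts))) {
        Ffd <- fdDeformationGradient(m, pts[i, ], f)
        E <- (t(Ffd) %*% Ffd - diag(3)) / 2
        expect_equal(unname(cylProject(E, pts[i, ])), unname(ana[i, ]),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("encoded phase follows 2*pi*ke*d with wrapping into (-pi, pi]", {
  ## closed form: 0.5 mm at ke = 1.1 wraps from 3.4558 to -2.8274 rad
  expect_equal(wrapPhase(2 * pi * 1.1 * 0.5), 2 * pi * 1.1 * 0.5 - 2 * pi,
               tolerance = 1e-12)
  expect_equal(wrapPhase(2 * pi * 1.1 * 0.5), -2.827433, tolerance = 1e-6)

  ## rendered phase at masked voxels equals wrap(2 pi ke d) for exact d
  p <- renderDenseSeries(smallModel(), smallAcq())
  f <- 3L
  m <- p$truth@mask[, , , f]
  enc <- wrapPhase(2 * pi * 1.1 * p$truth@displacement$dx[, , , f][m])
  expect_equal(p$series@phaseX[, , , f][m], enc, tolerance = 1e-9)

  ## zero-motion phantom: all phase volumes are zero without background
  m0 <- smallModel(peakContraction = 1, peakShortening = 0,
                   peakTwistPerLength = 0)
  p0 <- renderDenseSeries(m0, smallAcq())
  msk <- p0$truth@mask
  expect_true(all(abs(p0$series@phaseX[msk]) < 1e-12))

  ## ... and with a background field they equal the wrapped background
  bg <- c(0.3, 0.2, -0.1, 0.4)
  pb <- renderDenseSeries(m0, smallAcq(background = bg))
  dims <- dim(msk)[1:3]
  ctr <- denseMechanics:::voxelCenters(seq_len(prod(dims)), dims,
                                       c(0.5, 0.5, 0.8))
  want <- wrapPhase(bg[1] + ctr %*% bg[2:4])
  got <- pb$series@phaseY[, , , 2]
  expect_equal(got[msk[, , , 2]], want[which(msk[, , , 2])],
               tolerance = 1e-9)
})

test_that("wrapped phase always lies in (-pi, pi]", {
  p <- renderDenseSeries(smallModel(), smallAcq(snr = 5, seed = 3L))
  for (ph in list(p$series@phaseX, p$series@phaseY, p$series@phaseZ)) {
    expect_gt(min(ph), -pi)
    expect_lte(max(ph), pi)
  }
})

test_that("identical seeds give byte-identical series", {
  a <- renderDenseSeries(smallModel(), smallAcq(snr = 10, seed = 42L))
  b <- renderDenseSeries(smallModel(), smallAcq(snr = 10, seed = 42L))
  expect_identical(a$series@phaseX, b$series@phaseX)
  expect_identical(a$series@magnitude, b$series@magnitude)
  c_ <- renderDenseSeries(smallModel(), smallAcq(snr = 10, seed = 43L))
  expect_false(identical(a$series@phaseX, c_$series@phaseX))

  r1 <- renderPhaseCycledRaw(smallModel(), smallAcq(snr = 10, seed = 5L))
  r2 <- renderPhaseCycledRaw(smallModel(), smallAcq(snr = 10, seed = 5L))
  expect_identical(r1$raw$x[[2]], r2$raw$x[[2]])
})

test_that("phase-cycled acquisitions differ only by the cycle factor when artifact-free", {
  r <- renderPhaseCycledRaw(smallModel(), smallAcq(), artifactAmplitude = 0)
  inc <- r$increments
  expect_equal(r$raw$x[[2]], r$raw$x[[1]] * exp(1i * (inc[2] - inc[1])),
               tolerance = 1e-12)
  expect_equal(r$raw$z[[3]], r$raw$z[[1]] * exp(1i * (inc[3] - inc[1])),
               tolerance = 1e-12)
})

test_that("non-integral grids are rejected", {
  expect_error(acquisitionParams(fov = c(8.1, 8, 8.8)), "integer grid")
})
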