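trackFixture <- function() {
  dims <- c(16L, 16L, 8L)
  vox <- c(0.5, 0.5, 0.8)
  mask <- annulusMask(dims, vox, 1.2, 3.2)
  list(dims = dims, vox = vox, mask = mask)
}

test_that("forward map is the identity for zero displacement", {
  fx <- trackFixture()
  disp <- analyticDisplacementField(fx$dims, fx$vox, fx$mask,
                                    function(x) 0 * x)
  q <- denseMechanics:::voxelCenters(which(fx$mask), fx$dims, fx$vox)
  out <- forwardMap(disp, 2L, q)
  expect_equal(unname(out[, 1:3]), unname(q), tolerance = 1e-8)
})

test_that("affine motions are reproduced exactly", {
  fx <- trackFixture()
  t_ <- c(0.7, -0.4, 0.9)
  dispT <- analyticDisplacementField(fx$dims, fx$vox, fx$mask,
                                     function(x) matrix(t_, nrow(x), 3,
                                                        byrow = TRUE))
  q <- denseMechanics:::voxelCenters(which(fx$mask), fx$dims, fx$vox)
  outT <- forwardMap(dispT, 2L, q)
  errT <- sqrt(rowSums((outT - sweep(q, 2, t_, "+"))^2))
  expect_lt(max(errT), 0.01 * min(fx$vox))

  ## rotation about the grid axis: deformed x = R X, so d(x) = x - R^T x
  ang <- 12 * pi / 180
  ctr <- c(fx$dims[1] * fx$vox[1] / 2, fx$dims[2] * fx$vox[2] / 2, 0)
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3)
  dfun <- function(x) {
    xc <- sweep(x, 2, ctr)
    xc - xc %*% Rz  # x - R^T x  (row convention: X^T = x^T R)
  }
  dispR <- analyticDisplacementField(fx$dims, fx$vox, fx$mask, dfun)
  outR <- forwardMap(dispR, 2L, q)
  want <- sweep(sweep(q, 2, ctr) %*% t(Rz), 2, ctr, "+")
  errR <- sqrt(rowSums((outR - want)^2))
  expect_lt(max(errR), 0.01 * min(fx$vox))
})

test_that("phantom rotation field maps points to the closed-form rotation", {
  m <- smallModel(peakContraction = 1, peakShortening = 0,
                  peakTwistPerLength = 1)
  a <- smallAcq()
  p <- renderDenseSeries(m, a)
  disp <- assembleVectorField(p$truth@displacement$dx,
                              p$truth@displacement$dy,
                              p$truth@displacement$dz,
                              mask = p$truth@mask, ke = a@ke,
                              voxelSize = a@voxelSize)
  geom <- denseMechanics:::phantomGeometry(m, a)
  set.seed(5)
  q <- randomAnnulusPoints(m, 200, geom$cx, geom$cy, geom$apexZ,
                           margin = 0.3)
  out <- forwardMap(disp, 3L, q)
  want <- denseMechanics:::motionForward(m, q, 3L, geom$cx, geom$cy,
                                         geom$apexZ)
  err <- sqrt(rowSums((out - want)^2))
  expect_lt(stats::quantile(err, 0.95), 0.1 * max(a@voxelSize))
})

test_that("degenerate sample geometry is rejected", {
  sites <- cbind(runif(10), runif(10), 1)  # coplanar
  expect_error(denseMechanics:::rbfInterpolant(sites, sites), "coplanar")
})

test_that("trajectories start at the material points and track the phantom", {
  m <- smallModel()
  a <- smallAcq()
  p <- renderDenseSeries(m, a)
  disp <- assembleVectorField(p$truth@displacement$dx,
                              p$truth@displacement$dy,
                              p$truth@displacement$dz,
                              mask = p$truth@mask, ke = a@ke,
                              voxelSize = a@voxelSize)
  traj <- buildTrajectories(disp)
  expect_equal(traj@trajectories[, , 1], materialPoints(traj))
  expect_equal(nrow(materialPoints(traj)), sum(p$truth@mask[, , , 1]))
  geom <- denseMechanics:::phantomGeometry(m, a)
  errs <- vapply(2:nPhases(disp), function(f) {
    want <- denseMechanics:::motionForward(m, traj@points, f, geom$cx,
                                           geom$cy, geom$apexZ)
    mean(sqrt(rowSums((traj@trajectories[, , f] - want)^2)))
  }, numeric(1))
  expect_lt(max(errs), 0.15 * max(a@voxelSize))
})

test_that("zero motion gives constant trajectories", {
  fx <- trackFixture()
  disp <- analyticDisplacementField(fx$dims, fx$vox, fx$mask,
                                    function(x) 0 * x, P = 3L)
  traj <- buildTrajectories(disp)
  for (f in 2:3)
    expect_equal(traj@trajectories[, , f], traj@trajectories[, , 1],
                 tolerance = 1e-8)
  expect_true(all(traj@valid))
  expect_equal(length(traj@valid), nrow(traj@points))
})

test_that("queries beyond the sample support are flagged as extrapolated", {
  fx <- trackFixture()
  disp <- analyticDisplacementField(fx$dims, fx$vox, fx$mask,
                                    function(x) 0 * x)
  far <- matrix(c(50, 50, 50), 1, 3)
  expect_warning(out <- forwardMap(disp, 2L, far), "extrapolated")
  expect_true(attr(out, "extrapolated"))
})

test_that("polynomial smoothing is an idempotent projection that preserves polynomials", {
  P <- 14L
  t01 <- seq(0, 1, length.out = P)
  n <- 20L
  set.seed(8)
  coef <- matrix(rnorm(n * 3 * 4), n * 3, 4)
  ## cubic trajectories: inside the degree-10 space, must pass through
  base <- cbind(1, t01, t01^2, t01^3)
  arr <- array(t(coef %*% t(base)), c(P, n, 3))
  traj <- new("TrajectorySet",
              points = matrix(aperm(arr, c(2, 3, 1))[, , 1], n, 3),
              trajectories = aperm(arr, c(2, 3, 1)),
              valid = rep(TRUE, n),
              voxelIndex = matrix(1L, n, 3),
              partition = rep(1L, n), voxelSize = c(1, 1, 1))
  sm <- smoothTrajectories(traj, order = 10L)
  expect_equal(sm@trajectories, traj@trajectories, tolerance = 1e-8)
  ## constant trajectories unchanged
  cst <- traj
  cst@trajectories <- array(rep(traj@trajectories[, , 1], P), c(n, 3, P))
  expect_equal(smoothTrajectories(cst)@trajectories, cst@trajectories,
               tolerance = 1e-10)
  ## idempotence on noisy data
  noisy <- traj
  noisy@trajectories <- traj@trajectories +
    array(rnorm(n * 3 * P, 0, 0.1), c(n, 3, P))
  s1 <- smoothTrajectories(noisy, order = 10L)
  s2 <- smoothTrajectories(s1, order = 10L)
  expect_equal(s2@trajectories, s1@trajectories, tolerance = 1e-8)
})

test_that("smoothing reduces the error of noisy phantom trajectories", {
  m <- motionModel()
  a <- acquisitionParams(snr = Inf)
  geom <- denseMechanics:::phantomGeometry(m, a)
  set.seed(21)
  pts <- randomAnnulusPoints(m, 300, geom$cx, geom$cy, geom$apexZ)
  P <- m@nPhases
  clean <- array(NA_real_, c(nrow(pts), 3, P))
  for (f in seq_len(P))
    clean[, , f] <- denseMechanics:::motionForward(m, pts, f, geom$cx,
                                                   geom$cy, geom$apexZ)
  sigma <- 0.05 * min(a@voxelSize)
  noisy <- clean + array(rnorm(length(clean), 0, sigma), dim(clean))
  traj <- new("TrajectorySet", points = pts, trajectories = noisy,
              valid = rep(TRUE, nrow(pts)),
              voxelIndex = matrix(1L, nrow(pts), 3),
              partition = rep(1L, nrow(pts)), voxelSize = a@voxelSize)
  sm <- smoothTrajectories(traj, order = 10L)
  rmseBefore <- sqrt(mean((noisy - clean)^2))
  rmseAfter <- sqrt(mean((sm@trajectories - clean)^2))
  expect_lt(rmseAfter, rmseBefore)
})
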