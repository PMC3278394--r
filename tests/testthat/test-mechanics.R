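test_that("neighbor stencils take the nearest twelve within adjacent partitions", {
  tr <- gridTraj()
  center <- which(tr@voxelIndex[, 1] == 3 & tr@voxelIndex[, 2] == 3 &
                    tr@voxelIndex[, 3] == 2)
  st <- selectNeighbors(tr, center)
  expect_equal(ncol(st$V0), 12L)
  expect_equal(dim(st$V0), c(3L, 12L))
  ## all from partitions 1..3 (own +/- 1) and none farther than sqrt(2)
  expect_true(all(abs(tr@partition[st$neighbors] - 2L) <= 1L))
  expect_true(all(sqrt(colSums(st$V0^2)) <= sqrt(2) + 1e-9))

  ## partitions restricted: point in partition 1 only uses partitions 1-2
  corner <- which(tr@voxelIndex[, 1] == 1 & tr@voxelIndex[, 2] == 1 &
                    tr@voxelIndex[, 3] == 1)
  st2 <- selectNeighbors(tr, corner)
  expect_true(all(tr@partition[st2$neighbors] <= 2L))

  ## few available neighbors: N shrinks but the stencil is still built
  small <- gridTraj(nx = 2L, ny = 3L, nz = 1L)
  st3 <- selectNeighbors(small, 1L)
  expect_equal(ncol(st3$V0), 5L)
  ## fewer than 3 valid neighbors -> NULL
  tiny <- gridTraj(nx = 3L, ny = 1L, nz = 1L)
  expect_null(selectNeighbors(tiny, 1L))
})

test_that("deformation gradient solves Vf = F V0 through the SVD", {
  set.seed(3)
  V0 <- matrix(rnorm(36), 3, 12)
  expect_equal(deformationGradient(V0, V0), diag(3), tolerance = 1e-10)
  ## exact rotation recovered
  ang <- 30 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  expect_equal(deformationGradient(V0, R %*% V0), R, tolerance = 1e-10)
  ## least-squares oracle: normal equations solved independently
  A <- matrix(rnorm(9), 3, 3)
  Vf <- A %*% V0 + matrix(rnorm(36, 0, 0.01), 3, 12)
  oracle <- t(solve(V0 %*% t(V0), V0 %*% t(Vf)))
  expect_equal(deformationGradient(V0, Vf), oracle, tolerance = 1e-8)
  ## all singular values under the cutoff -> NULL
  expect_null(deformationGradient(V0 * 0, V0 * 0))
})

test_that("rank-deficient stencils fall back to the pseudo-inverse", {
  set.seed(4)
  ## coplanar neighbors (all in z = 0 plane)
  V0 <- rbind(matrix(rnorm(20), 2, 10), 0)
  A <- diag(c(0.9, 1.1, 1))
  Fhat <- deformationGradient(V0, A %*% V0)
  ## in-plane behaviour is recovered; out-of-plane column stays benign
  expect_equal(Fhat[1:2, 1:2], A[1:2, 1:2], tolerance = 1e-8)
  expect_true(all(is.finite(Fhat)))
})

test_that("Lagrangian strain is symmetric, objective, and exact on closed forms", {
  expect_equal(strainTensor(diag(3)), matrix(0, 3, 3))
  ang <- 1.1
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  expect_equal(strainTensor(R), matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(strainTensor(0.9 * diag(3)), -0.095 * diag(3),
               tolerance = 1e-12)
  set.seed(5)
  F_ <- matrix(rnorm(9), 3, 3)
  E <- strainTensor(F_)
  expect_equal(E, t(E), tolerance = 1e-12)
  expect_equal(strainTensor(R %*% F_), E, tolerance = 1e-12)
})

test_that("the RCL basis is right-handed and orthonormal", {
  b <- rclBasis(c(2, 0, 1), c(0, 0))
  expect_equal(b[, "r"], c(1, 0, 0))
  expect_equal(b[, "c"], c(0, 1, 0))
  expect_equal(b[, "l"], c(0, 0, 1))
  expect_null(rclBasis(c(0, 0, 1), c(0, 0)))
  set.seed(6)
  for (i in 1:200) {
    p <- c(rnorm(2), runif(1))
    if (sqrt(sum(p[1:2]^2)) < 1e-3) next
    B <- rclBasis(p, c(0, 0))
    expect_equal(unname(t(B) %*% B), diag(3), tolerance = 1e-12)
    expect_equal(det(B), 1, tolerance = 1e-12)
  }
})

test_that("strain projects onto RCL components correctly", {
  B <- rclBasis(c(1, 1, 0), c(0, 0))
  expect_equal(unname(projectStrain(matrix(0, 3, 3), B)), rep(0, 6))
  ## diagonal in the RCL frame: shears exactly zero
  D <- B %*% diag(c(0.2, -0.1, -0.05)) %*% t(B)
  pr <- projectStrain(D, B)
  expect_equal(unname(pr[c("rc", "rl", "cl")]), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(pr[c("rr", "cc", "ll")]), c(0.2, -0.1, -0.05),
               tolerance = 1e-12)
  ## isotropic in-plane scaling about the centroid: Err = Ecc = (l^2-1)/2
  lam <- 0.9
  F_ <- diag(c(lam, lam, 1))
  pr2 <- projectStrain(strainTensor(F_), B)
  expect_equal(unname(pr2["rr"]), (lam^2 - 1) / 2, tolerance = 1e-12)
  expect_equal(unname(pr2["cc"]), (lam^2 - 1) / 2, tolerance = 1e-12)
  expect_equal(unname(pr2["cl"]), 0, tolerance = 1e-12)
})

test_that("twist measures signed rotation about the slice centroid", {
  ## static points: zero twist at every phase
  tr <- gridTraj(P = 3L)
  tw <- twistAngle(tr)
  expect_true(all(abs(tw) < 1e-10))

  ## 10 degrees clockwise viewed from the base = -10 about +z mathematically
  ang <- -10 * pi / 180
  rot <- function(x) {
    ctr <- colMeans(x)
    xc <- sweep(x, 2, ctr)
    cbind(xc[, 1] * cos(ang) - xc[, 2] * sin(ang),
          xc[, 1] * sin(ang) + xc[, 2] * cos(ang), xc[, 3]) +
      matrix(ctr, nrow(x), 3, byrow = TRUE)
  }
  tr2 <- gridTraj(P = 2L, map = rot)
  tw2 <- twistAngle(tr2)
  expect_equal(unname(tw2[, 2]), rep(10, nrow(tw2)), tolerance = 1e-8)
  ## bulk translation does not masquerade as twist
  shift <- function(x) sweep(x, 2, c(0.4, -0.3, 0), "+")
  tw3 <- twistAngle(gridTraj(P = 2L, map = shift))
  expect_true(all(abs(tw3[, 2]) < 1e-10))
})

test_that("torsion normalizes the apex-base twist gradient by RLV/LLV", {
  expect_equal(torsion(5, 5, 2, 6), 0)
  expect_equal(torsion(8, 0, RLV = 2, LLV = 6), 8 * 2 / 6, tolerance = 1e-12)
  expect_equal(torsion(8, 0, RLV = 2, LLV = 6), 2.667, tolerance = 1e-3)
  ## isotropic scaling of the ventricle leaves torsion unchanged
  expect_equal(torsion(8, 1, 2 * 3.5, 6 * 3.5), torsion(8, 1, 2, 6))
  expect_error(torsion(1, 0, -1, 6))
})

test_that("phantom twist and torsion are recovered from exact trajectories", {
  m <- smallModel()
  a <- smallAcq()
  p <- renderDenseSeries(m, a)
  disp <- assembleVectorField(p$truth@displacement$dx,
                              p$truth@displacement$dy,
                              p$truth@displacement$dz,
                              mask = p$truth@mask, ke = a@ke,
                              voxelSize = a@voxelSize)
  traj <- buildTrajectories(disp)
  tt <- computeTwistTorsion(traj, p$truth@contours)
  ## slice twist matches tau * w * (zBase - z) within half a degree
  rows <- match(tt@slices, p$truth@partitions)
  expect_lt(max(abs(tt@twist - p$truth@twist[rows, ]), na.rm = TRUE), 0.5)
  expect_lt(max(abs(tt@torsion - truthTorsion(p$truth, tt))), 0.5)
  ## twist is zero at the reference phase
  expect_true(all(abs(tt@twist[, 1]) < 1e-8))
})

test_that("strain summaries resolve levels, layers, and end systole", {
  m <- motionModel(nPhases = 6L, systoleIndex = 3L)
  a <- smallAcq()
  p <- renderDenseSeries(m, a)
  disp <- assembleVectorField(p$truth@displacement$dx,
                              p$truth@displacement$dy,
                              p$truth@displacement$dz,
                              mask = p$truth@mask, ke = a@ke,
                              voxelSize = a@voxelSize)
  traj <- buildTrajectories(disp)
  strain <- computeStrain(traj, p$truth@contours)
  sm <- summarizeStrain(strain, byLayer = TRUE)
  expect_equal(sm$endSystolePhase, 3L)
  ## transmural gradient: |Ecc| larger subendo than subepi at each level
  pk <- sm$peak
  for (lev in c("apical", "mid", "basal")) {
    en <- pk$Ecc[pk$level == lev & pk$layer == "subendo"]
    ep <- pk$Ecc[pk$level == lev & pk$layer == "subepi"]
    expect_gt(abs(en), abs(ep))
  }
  ## strain vanishes identically at the reference phase
  tab <- sm$table
  expect_true(all(abs(tab$Ecc[tab$phase == 1]) < 1e-8))

  ## uniform strain field: identical means at all levels, SE ~ 0
  su <- strain
  su@rcl[] <- 0.1
  smu <- summarizeStrain(su)
  expect_equal(diff(range(smu$table$Err)), 0)

  ## single-voxel group: SE reported as 0
  s1 <- strain
  keepOne <- rep(TRUE, length(s1@flagged))
  keepOne[-1] <- TRUE
  s1@flagged[-1] <- TRUE
  sm1 <- summarizeStrain(s1, levels = list(
    apical = s1@partition[1], mid = s1@partition[1],
    basal = s1@partition[1]))
  expect_true(all(sm1$table$se_rr == 0))
})

test_that("strain estimation is objective under superposed rigid motion", {
  ## deforming trajectories, then the same with a global rotation +
  ## translation applied to every deformed configuration: with the basis
  ## held fixed the full tensor E is unchanged (quick spot check; the
  ## field-wide invariance is exercised in the acceptance suite)
  m <- smallModel()
  a <- smallAcq()
  p <- renderDenseSeries(m, a)
  disp <- assembleVectorField(p$truth@displacement$dx,
                              p$truth@displacement$dy,
                              p$truth@displacement$dz,
                              mask = p$truth@mask, ke = a@ke,
                              voxelSize = a@voxelSize)
  traj <- buildTrajectories(disp)
  ang <- 25 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3)
  t_ <- c(1.5, -2, 0.7)
  rigid <- traj
  for (f in 2:nPhases(disp))
    rigid@trajectories[, , f] <-
      sweep(traj@trajectories[, , f] %*% t(R), 2, t_, "+")
  s0 <- computeStrain(traj, p$truth@contours)
  s1 <- computeStrain(rigid, p$truth@contours)
  ok <- !s0@flagged & !s1@flagged
  expect_lt(max(abs(s0@E[ok, , ] - s1@E[ok, , ])), 1e-8)
})
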