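## Shared fixtures and independent oracles, all built in code.

## Small, fast phantom: coarse grid, 6 phases.
smallModel <- function(...) {
  args <- list(nPhases = 6L, systoleIndex = 3L)
  args[names(list(...))] <- list(...)
  do.call(motionModel, args)
}

smallAcq <- function(...) {
  args <- list(voxelSize = c(0.5, 0.5, 0.8), fov = c(8, 8, 8.8),
               nPhases = 6L, snr = Inf, seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(acquisitionParams, args)
}

## Finite-difference deformation gradient of the analytic motion — the
## independent oracle for all strain ground truth.
fdDeformationGradient <- function(model, pt, phase, cx = 0, cy = 0,
                                  apexZ = 0, h = 1e-5) {
  J <- matrix(0, 3, 3)
  fwd <- function(p) denseMechanics:::motionForward(model,
                                                    matrix(p, ncol = 3),
                                                    phase, cx, cy, apexZ)
  for (j in 1:3) {
    e <- numeric(3)
    e[j] <- h
    J[, j] <- (fwd(pt + e) - fwd(pt - e)) / (2 * h)
  }
  J
}

## Project a strain tensor at a reference point onto the cylindrical RCL
## frame about the axis at (cx, cy) — independent of rclBasis().
cylProject <- function(E, pt, cx = 0, cy = 0) {
  v <- c(pt[1] - cx, pt[2] - cy)
  r <- c(v / sqrt(sum(v^2)), 0)
  l <- c(0, 0, 1)
  cc <- c(-r[2], r[1], 0) * l[3]  # l x r
  B <- cbind(r, cc, l)
  M <- t(B) %*% E %*% B
  c(rr = M[1, 1], cc = M[2, 2], ll = M[3, 3],
    rc = M[1, 2], rl = M[1, 3], cl = M[2, 3])
}

## Random reference points inside the annulus of a model placed at
## (cx, cy, apexZ).
randomAnnulusPoints <- function(model, n, cx = 0, cy = 0, apexZ = 0,
                                margin = 0.05) {
  R <- sqrt(runif(n, (model@endoRadius + margin)^2,
                  (model@epiRadius - margin)^2))
  th <- runif(n, 0, 2 * pi)
  z <- runif(n, apexZ + margin, apexZ + model@lvLength - margin)
  cbind(cx + R * cos(th), cy + R * sin(th), z)
}

## Build a DisplacementField from a closed-form Eulerian displacement
## function d(x) (N x 3 -> N x 3), on the masked voxels of a grid.
analyticDisplacementField <- function(dims, vox, mask3, dfun, P = 2L,
                                      ke = 1.1) {
  d4 <- c(dims, P)
  dx <- dy <- dz <- array(NA_real_, d4)
  m4 <- array(FALSE, d4)
  idx <- which(mask3)
  x <- denseMechanics:::voxelCenters(idx, dims, vox)
  for (f in seq_len(P)) {
    d <- if (f == 1L) matrix(0, length(idx), 3) else dfun(x)
    sl <- (f - 1L) * prod(dims)
    dx[sl + idx] <- d[, 1]
    dy[sl + idx] <- d[, 2]
    dz[sl + idx] <- d[, 3]
    m4[sl + idx] <- TRUE
  }
  assembleVectorField(dx, dy, dz, mask = m4, ke = ke, voxelSize = vox)
}

## Annulus mask centered in the grid.
annulusMask <- function(dims, vox, rIn, rOut, zRange = NULL) {
  idx <- seq_len(prod(dims))
  x <- denseMechanics:::voxelCenters(idx, dims, vox)
  cx <- dims[1] * vox[1] / 2
  cy <- dims[2] * vox[2] / 2
  r <- sqrt((x[, 1] - cx)^2 + (x[, 2] - cy)^2)
  ok <- r >= rIn & r <= rOut
  if (!is.null(zRange)) ok <- ok & x[, 3] >= zRange[1] & x[, 3] <= zRange[2]
  array(ok, dims)
}

## Regular-grid trajectory set whose deformed configuration is map(points).
gridTraj <- function(nx = 5L, ny = 5L, nz = 3L, vox = c(1, 1, 1), P = 2L,
                     map = identity) {
  idx <- seq_len(nx * ny * nz)
  pts <- denseMechanics:::voxelCenters(idx, c(nx, ny, nz), vox)
  subs <- denseMechanics:::voxelSubscripts(idx, c(nx, ny, nz))
  traj <- array(NA_real_, c(nrow(pts), 3, P))
  traj[, , 1] <- pts
  for (f in 2:P) traj[, , f] <- map(pts)
  new("TrajectorySet", points = pts, trajectories = traj,
      valid = rep(TRUE, nrow(pts)), voxelIndex = subs,
      partition = as.integer(subs[, 3]), voxelSize = vox)
}

## Ground-truth torsion via the same estimator ranges as a fitted curve.
truthTorsion <- function(truth, curve) {
  parts <- truth@partitions
  cm <- function(x) atan2(mean(sin(x * pi / 180)),
                          mean(cos(x * pi / 180))) * 180 / pi
  rowsA <- which(parts %in% curve@apicalRange)
  rowsB <- which(parts %in% curve@basalRange)
  P <- ncol(truth@twist)
  a <- vapply(seq_len(P), function(f) cm(truth@twist[rowsA, f]), numeric(1))
  b <- vapply(seq_len(P), function(f) cm(truth@twist[rowsB, f]), numeric(1))
  (a - b) * curve@RLV / curve@LLV
}

## Mean strain over selected material voxels taken from phantom truth at the
## voxels of a trajectory set.
truthStrainMean <- function(truth, traj, sel, component, phase) {
  d <- dim(truth@mask)[1:3]
  vi <- traj@voxelIndex
  lin <- vi[, 1] + (vi[, 2] - 1L) * d[1] + (vi[, 3] - 1L) * d[1] * d[2]
  vals <- truth@strainRCL[[component]][lin[sel] + (phase - 1L) * prod(d)]
  mean(vals, na.rm = TRUE)
}
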