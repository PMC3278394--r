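## Lagrangian tissue tracking: scattered-data interpolation of the
## reference -> deformed map with linear-spline radial basis functions
## (phi(r) = r) plus an affine polynomial term, then temporal smoothing of
## the trajectories by least-squares polynomial fits.

## Fit the RBF interpolant through samples (sites -> values). Returns a
## closure evaluating at query points. Affine fields are reproduced exactly
## (weights vanish, the polynomial term carries the map).
rbfInterpolant <- function(sites, values, regularization = 1e-8) {
  n <- nrow(sites)
  if (n < 4L) stop("need at least 4 scattered samples")
  K <- as.matrix(stats::dist(sites))
  P <- cbind(1, sites)
  if (qr(P)$rank < 4L)
    stop("degenerate sample geometry: scattered sites are coplanar")
  lam <- regularization * mean(K)
  A <- rbind(cbind(K + diag(lam, n), P),
             cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(values, matrix(0, 4L, ncol(values)))
  coef <- solve(A, rhs)
  w <- coef[seq_len(n), , drop = FALSE]
  cpoly <- coef[n + 1:4, , drop = FALSE]
  function(query) {
    D2 <- outer(rowSums(query^2), rep(1, n)) +
      outer(rep(1, nrow(query)), rowSums(sites^2)) -
      2 * query %*% t(sites)
    Kq <- sqrt(pmax(D2, 0))
    Kq %*% w + cbind(1, query) %*% cpoly
  }
}

## Deterministic spatial subsampling: order sites lexicographically by
## (z, y, x) and take a regular stride, so retained centers stay spread.
subsampleSites <- function(sites, maxCenters) {
  n <- nrow(sites)
  if (n <= maxCenters) return(seq_len(n))
  ord <- order(sites[, 3], sites[, 2], sites[, 1])
  ord[round(seq(1, n, length.out = maxCenters))]
}

#' Forward material map at one cardiac phase
#'
#' Builds the scattered samples `(x_i - d(x_i, f)) -> x_i` from the Eulerian
#' displacement at phase `f` (a voxel at x holds tissue that was at
#' `x - d(x, f)` at encoding) and evaluates a linear-spline RBF interpolant
#' with affine term at the query reference positions. Affine motions
#' (including uniform translations and rotations) are reproduced exactly.
#'
#' @param displacement a [DisplacementField-class].
#' @param phase 1-based cardiac phase.
#' @param queryPoints N x 3 matrix of reference positions (mm).
#' @param maxCenters cap on the number of RBF centers; larger sample sets
#'   are subsampled deterministically.
#' @param regularization diagonal regularization relative to the mean
#'   inter-point distance.
#' @return N x 3 matrix of deformed positions with attribute
#'   `"extrapolated"`: logical, `TRUE` for queries farther than two voxels
#'   from every scattered sample.
#' @export
forwardMap <- function(displacement, phase, queryPoints, maxCenters = 2000L,
                       regularization = 1e-8) {
  stopifnot(is(displacement, "DisplacementField"))
  d4 <- dim(displacement@dx)
  m <- which(displacement@mask[, , , phase] & displacement@reliable[, , , phase])
  if (length(m) < 4L) stop("fewer than 4 usable voxels at this phase")
  vox <- displacement@voxelSize
  x <- voxelCenters(m, d4[1:3], vox)
  sl <- (phase - 1L) * prod(d4[1:3])
  d <- cbind(displacement@dx[sl + m], displacement@dy[sl + m],
             displacement@dz[sl + m])
  sites <- x - d
  keep <- subsampleSites(sites, maxCenters)
  interp <- rbfInterpolant(sites[keep, , drop = FALSE],
                           x[keep, , drop = FALSE], regularization)
  q <- if (is.matrix(queryPoints)) queryPoints else matrix(queryPoints, ncol = 3)
  out <- interp(q)
  ## extrapolation flag: query beyond 2 voxels from nearest retained site
  thr2 <- (2 * max(vox))^2
  s <- sites[keep, , drop = FALSE]
  nn2 <- vapply(seq_len(nrow(q)), function(i) {
    min((s[, 1] - q[i, 1])^2 + (s[, 2] - q[i, 2])^2 + (s[, 3] - q[i, 3])^2)
  }, numeric(1))
  extrap <- nn2 > thr2
  if (any(extrap))
    warning(sprintf("%d query points beyond sample support; extrapolated",
                    sum(extrap)))
  attr(out, "extrapolated") <- extrap
  out
}

#' Build Lagrangian trajectories from Eulerian displacement
#'
#' Material points are the masked voxel centers at the first (encoding)
#' cardiac phase; the trajectory of point p at phase f is
#' `forwardMap(displacement, f, p)`, with the phase-1 entry being p itself.
#'
#' @param displacement a [DisplacementField-class].
#' @param maxCenters,regularization passed to [forwardMap()].
#' @return a [TrajectorySet-class]; points whose mapping extrapolated beyond
#'   the displacement support at any phase are flagged invalid.
#' @export
buildTrajectories <- function(displacement, maxCenters = 2000L,
                              regularization = 1e-8) {
  stopifnot(is(displacement, "DisplacementField"))
  d4 <- dim(displacement@dx)
  m1 <- which(displacement@mask[, , , 1])
  if (!length(m1)) stop("empty mask at the first phase")
  vox <- displacement@voxelSize
  pts <- voxelCenters(m1, d4[1:3], vox)
  subs <- voxelSubscripts(m1, d4[1:3])
  P <- d4[4]
  traj <- array(NA_real_, c(nrow(pts), 3L, P))
  traj[, , 1] <- pts
  valid <- rep(TRUE, nrow(pts))
  for (f in seq_len(P)[-1]) {
    mapped <- withCallingHandlers(
      forwardMap(displacement, f, pts, maxCenters, regularization),
      warning = function(w) invokeRestart("muffleWarning"))
    traj[, , f] <- mapped
    valid <- valid & !attr(mapped, "extrapolated")
  }
  new("TrajectorySet", points = pts, trajectories = traj, valid = valid,
      voxelIndex = subs, partition = as.integer(subs[, 3]),
      voxelSize = vox)
}

#' Smooth trajectories with least-squares polynomial fits
#'
#' Each coordinate of each trajectory is replaced by its least-squares
#' polynomial fit over normalized time in `[0, 1]`. The fit is an orthogonal
#' projection, hence idempotent, and is not constrained through the phase-1
#' position. The order is reduced to `nPhases - 2` when fewer phases are
#' available than the requested order allows.
#'
#' @param traj a [TrajectorySet-class].
#' @param order polynomial order (default 10).
#' @return a smoothed [TrajectorySet-class].
#' @export
smoothTrajectories <- function(traj, order = 10L) {
  stopifnot(is(traj, "TrajectorySet"))
  P <- dim(traj@trajectories)[3]
  ord <- min(order, P - 2L)
  if (ord < 1L) return(traj)
  t01 <- seq(0, 1, length.out = P)
  Q <- qr.Q(qr(stats::poly(t01, degree = ord, raw = FALSE, simple = TRUE)))
  Q <- cbind(1 / sqrt(P), Q)          # include intercept, orthonormal
  H <- Q %*% t(Q)                     # projection onto degree-<=ord polys
  n <- dim(traj@trajectories)[1]
  X <- matrix(aperm(traj@trajectories, c(3, 1, 2)), nrow = P)  # P x (n*3)
  Xs <- H %*% X
  sm <- aperm(array(Xs, c(P, n, 3L)), c(2, 3, 1))
  out <- traj
  out@trajectories <- sm
  out
}
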