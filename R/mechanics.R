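## Local Lagrangian strain estimation from neighbor trajectories, RCL
## decomposition, twist, and normalized torsion.
##
## For each material voxel (VOI) with reference position u0 and up to N = 12
## nearest neighbors p0_i drawn from the voxel's own partition and the two
## adjacent ones, the reference distance-vector matrix is
## V0 = [p0_1 - u0, ..., p0_N - u0] (3 x N) and Vf its deformed counterpart
## at phase f. Assuming locally uniform strain, Vf = F_f V0; F_f is solved
## robustly through the SVD of V0 V0^T = U S V^T as
## F_f = Vf V0^T V S0 U^T, where S0 carries the reciprocal singular values
## (entries below a relative cutoff are zeroed, pseudo-inverse convention;
## off-diagonal entries of the diagonal S are copied, i.e. zero). This
## equals the least-squares minimizer of ||Vf - F V0|| when V0 V0^T is full
## rank. The Lagrangian finite strain tensor is E_f = (F_f^T F_f - I) / 2.

#' Select the neighbor stencil of a material voxel
#'
#' The up-to-12 nearest valid material points by reference-position
#' Euclidean distance, restricted to the voxel's image partition and its two
#' adjacent partitions, with a deterministic tie-break by (partition, row,
#' column) index order.
#'
#' @param traj a [TrajectorySet-class].
#' @param voxel row index of the voxel of interest.
#' @param nMax maximum number of neighbors (default 12).
#' @return list with `center` (reference position), `neighbors` (indices),
#'   `V0` (3 x N reference distance-vector matrix), or `NULL` when fewer
#'   than 3 valid neighbors exist.
#' @export
selectNeighbors <- function(traj, voxel, nMax = 12L) {
  stopifnot(is(traj, "TrajectorySet"))
  part <- traj@partition
  cand <- which(abs(part - part[voxel]) <= 1L & traj@valid)
  cand <- cand[cand != voxel]
  if (length(cand) < 3L) return(NULL)
  p0 <- traj@points[voxel, ]
  d2 <- (traj@points[cand, 1] - p0[1])^2 +
    (traj@points[cand, 2] - p0[2])^2 +
    (traj@points[cand, 3] - p0[3])^2
  ## canonical key: (partition, row=j, column=i) index order
  key <- order(part[cand], traj@voxelIndex[cand, 2], traj@voxelIndex[cand, 1])
  rank_ <- integer(length(cand))
  rank_[key] <- seq_along(cand)
  sel <- cand[order(d2, rank_)][seq_len(min(nMax, length(cand)))]
  V0 <- t(traj@points[sel, , drop = FALSE]) - p0
  list(center = p0, neighbors = sel, V0 = V0)
}

#' Deformation gradient from a neighbor stencil
#'
#' SVD-based solve of `Vf = F V0` (see the module notes above): singular
#' values of `V0 V0^T` below `svCutoff` times the largest are treated as
#' zero, giving the pseudo-inverse in the rank-deficient case.
#'
#' @param V0 3 x N reference distance-vector matrix.
#' @param Vf 3 x N deformed distance-vector matrix.
#' @param svCutoff relative singular-value cutoff (default 1e-6).
#' @return 3 x 3 deformation gradient, or `NULL` when all singular values
#'   fall below the cutoff.
#' @export
deformationGradient <- function(V0, Vf, svCutoff = 1e-6) {
  stopifnot(identical(dim(V0), dim(Vf)))
  sv <- svd(V0 %*% t(V0))
  keep <- sv$d > svCutoff * sv$d[1]
  if (!any(keep)) return(NULL)
  s0 <- ifelse(keep, 1 / sv$d, 0)
  Vf %*% t(V0) %*% sv$v %*% diag(s0, 3L) %*% t(sv$u)
}

#' Lagrangian finite strain tensor
#'
#' `E = (F^T F - I) / 2`; symmetric by construction and objective (any
#' rotation F gives E = 0).
#'
#' @param F 3 x 3 deformation gradient.
#' @return symmetric 3 x 3 strain tensor.
#' @examples
#' strainTensor(diag(0.9, 3))  # -0.095 * I
#' @export
strainTensor <- function(F) {
  (t(F) %*% F - diag(3)) / 2
}

#' Local radial/circumferential/longitudinal basis
#'
#' The longitudinal unit vector is +z (apex to base); the radial unit vector
#' points in-plane from the slice midwall centroid to the voxel; the
#' circumferential vector completes the right-handed triad `c = l x r`. The
#' basis is defined from the contours at the first cardiac phase.
#'
#' @param position reference position (x, y, z) in mm.
#' @param centroid slice midwall centroid (x, y) in mm.
#' @return 3 x 3 matrix with columns `r`, `c`, `l`, or `NULL` when the voxel
#'   coincides with the centroid.
#' @export
rclBasis <- function(position, centroid) {
  v <- c(position[1] - centroid[1], position[2] - centroid[2])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(NULL)
  r <- c(v / nv, 0)
  l <- c(0, 0, 1)
  cvec <- cross3(l, r)
  cbind(r = r, c = cvec, l = l)
}

#' Project a strain tensor onto the RCL frame
#'
#' @param E symmetric 3 x 3 strain tensor (grid coordinates).
#' @param basis 3 x 3 orthonormal basis with columns `r`, `c`, `l`.
#' @return named numeric of the six components
#'   `rr, cc, ll, rc, rl, cl` (`E_ab = a^T E b`).
#' @export
projectStrain <- function(E, basis) {
  M <- t(basis) %*% E %*% basis
  c(rr = M[1, 1], cc = M[2, 2], ll = M[3, 3],
    rc = M[1, 2], rl = M[1, 3], cl = M[2, 3])
}

#' Estimate the per-voxel strain field from trajectories
#'
#' For every valid material voxel, selects the neighbor stencil, solves the
#' deformation gradient at each phase, forms the Lagrangian strain tensor,
#' and projects it onto the local RCL frame defined from the phase-1
#' contours.
#'
#' @param traj a [TrajectorySet-class].
#' @param contours a [ContourSet-class] with phase-1 contours (used for the
#'   RCL basis, transmural depth, and layer labels).
#' @param nMax maximum neighbors per stencil.
#' @param svCutoff relative singular-value cutoff for the SVD solve.
#' @return a [StrainField-class].
#' @export
computeStrain <- function(traj, contours, nMax = 12L, svCutoff = 1e-6) {
  stopifnot(is(traj, "TrajectorySet"), is(contours, "ContourSet"))
  P <- dim(traj@trajectories)[3]
  n <- nrow(traj@points)
  E <- array(NA_real_, c(n, 6L, P))
  rcl <- array(NA_real_, c(n, 6L, P))
  flagged <- rep(FALSE, n)
  centroids <- sliceCentroids(contours)
  pz <- contours@partitionZ
  depth <- transmuralDepth(traj@points, contours)
  ## centroid of the contoured partition nearest each point's z
  nearest <- vapply(traj@points[, 3], function(z) which.min(abs(pz - z)),
                    integer(1))
  for (v in seq_len(n)) {
    if (!traj@valid[v]) {
      flagged[v] <- TRUE
      next
    }
    st <- selectNeighbors(traj, v, nMax)
    if (is.null(st) || qr(st$V0)$rank < 2L) {
      flagged[v] <- TRUE
      next
    }
    basis <- rclBasis(traj@points[v, ], centroids[[nearest[v]]])
    if (is.null(basis)) {
      flagged[v] <- TRUE
      next
    }
    sv <- svd(st$V0 %*% t(st$V0))
    keep <- sv$d > svCutoff * sv$d[1]
    if (!any(keep)) {
      flagged[v] <- TRUE
      next
    }
    Pinv <- sv$v %*% diag(ifelse(keep, 1 / sv$d, 0), 3L) %*% t(sv$u)
    V0tP <- t(st$V0) %*% Pinv
    for (f in seq_len(P)) {
      Vf <- t(traj@trajectories[st$neighbors, , f]) -
        traj@trajectories[v, , f]
      Ff <- Vf %*% V0tP
      Ef <- (t(Ff) %*% Ff - diag(3)) / 2
      E[v, , f] <- c(Ef[1, 1], Ef[2, 2], Ef[3, 3],
                     Ef[1, 2], Ef[1, 3], Ef[2, 3])
      rcl[v, , f] <- projectStrain(Ef, basis)
    }
  }
  new("StrainField", E = E, rcl = rcl, refPositions = traj@points,
      partition = traj@partition, depth = depth,
      layer = ifelse(depth < 0.5, "subendo", "subepi"), flagged = flagged)
}

#' Twist angle per slice per phase
#'
#' Per voxel, the signed in-plane angle between the radial line from the
#' per-phase slice centroid to the voxel at the first phase and at phase f
#' (centroids are recomputed per phase, so bulk translation does not
#' masquerade as twist). The slice twist is the circular mean over its
#' voxels. Positive twist is clockwise when viewed from the base (base at
#' high z).
#'
#' @param traj a [TrajectorySet-class].
#' @param slices optional integer vector of image partitions to analyze
#'   (default: all partitions with at least one valid point).
#' @return matrix nSlices x nPhases of twist angles (degrees), with
#'   `rownames` the partition indices.
#' @export
twistAngle <- function(traj, slices = NULL) {
  stopifnot(is(traj, "TrajectorySet"))
  P <- dim(traj@trajectories)[3]
  part <- traj@partition
  if (is.null(slices)) slices <- sort(unique(part[traj@valid]))
  out <- matrix(NA_real_, length(slices), P,
                dimnames = list(as.character(slices), NULL))
  for (si in seq_along(slices)) {
    sel <- which(part == slices[si] & traj@valid)
    if (!length(sel)) next
    p1 <- traj@trajectories[sel, 1:2, 1, drop = FALSE]
    dim(p1) <- c(length(sel), 2L)
    c1 <- colMeans(p1)
    ## the angle is undefined at the slice centroid; drop such voxels
    r1 <- sqrt((p1[, 1] - c1[1])^2 + (p1[, 2] - c1[2])^2)
    keep <- r1 > 1e-6
    if (!any(keep)) next
    sel <- sel[keep]
    p1 <- p1[keep, , drop = FALSE]
    c1 <- colMeans(p1)
    a1 <- atan2(p1[, 2] - c1[2], p1[, 1] - c1[1])
    for (f in seq_len(P)) {
      pf <- traj@trajectories[sel, 1:2, f, drop = FALSE]
      dim(pf) <- c(length(sel), 2L)
      cf <- colMeans(pf)
      af <- atan2(pf[, 2] - cf[2], pf[, 1] - cf[1])
      ## math (counterclockwise about +z) rotation -> negate for the
      ## clockwise-from-base convention
      out[si, f] <- -circularMean(wrapPhase(af - a1)) * 180 / pi
    }
  }
  out
}

#' Normalized LV torsion
#'
#' `torsion = (thetaApex - thetaBase) * RLV / LLV` per phase; the
#' normalization by the radius-to-length ratio makes the measure independent
#' of ventricle size.
#'
#' @param thetaApex,thetaBase per-phase twist angles (degrees).
#' @param RLV average short-axis LV radius (mm), positive.
#' @param LLV long-axis LV length (mm), positive.
#' @return per-phase normalized torsion (degrees).
#' @examples
#' torsion(8, 0, RLV = 2, LLV = 6)  # 2.667 deg
#' @export
torsion <- function(thetaApex, thetaBase, RLV, LLV) {
  stopifnot(RLV > 0, LLV > 0)
  (thetaApex - thetaBase) * RLV / LLV
}

#' Twist and torsion curves from trajectories
#'
#' Computes per-slice twist, averages it (circular mean) over the apical and
#' basal slice ranges, and normalizes by the phase-1 midwall radius and the
#' axial distance between the range centers.
#'
#' @param traj a [TrajectorySet-class].
#' @param contours a [ContourSet-class] (phase-1 contours give the midwall
#'   radius).
#' @param apicalRange,basalRange integer partition indices; default: lowest
#'   and highest thirds of the contoured partitions.
#' @return a [TwistTorsionCurve-class].
#' @export
computeTwistTorsion <- function(traj, contours, apicalRange = NULL,
                                basalRange = NULL) {
  parts <- contours@partitions
  thirds <- levelRanges(parts)
  if (is.null(apicalRange)) apicalRange <- thirds$apical
  if (is.null(basalRange)) basalRange <- thirds$basal
  tw <- twistAngle(traj, slices = parts)
  P <- ncol(tw)
  rowsA <- which(parts %in% apicalRange)
  rowsB <- which(parts %in% basalRange)
  cmDeg <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    circularMean(x * pi / 180) * 180 / pi
  }
  thetaA <- vapply(seq_len(P), function(f) cmDeg(tw[rowsA, f]), numeric(1))
  thetaB <- vapply(seq_len(P), function(f) cmDeg(tw[rowsB, f]), numeric(1))
  ## midwall radius at phase 1 over analyzed slices
  ph1 <- contours@contours[[1]]
  radii <- vapply(ph1, function(cc) {
    ctr <- colMeans(rbind(cc$endo, cc$epi))
    re <- mean(sqrt((cc$endo[, 1] - ctr[1])^2 + (cc$endo[, 2] - ctr[2])^2))
    rp <- mean(sqrt((cc$epi[, 1] - ctr[1])^2 + (cc$epi[, 2] - ctr[2])^2))
    (re + rp) / 2
  }, numeric(1))
  RLV <- mean(radii)
  pz <- contours@partitionZ
  LLV <- abs(mean(pz[match(basalRange, parts)]) -
               mean(pz[match(apicalRange, parts)]))
  new("TwistTorsionCurve", twist = tw, slices = parts, thetaApex = thetaA,
      thetaBase = thetaB, torsion = torsion(thetaA, thetaB, RLV, LLV),
      RLV = RLV, LLV = LLV, apicalRange = as.integer(apicalRange),
      basalRange = as.integer(basalRange))
}

## Split contoured partitions into apical/mid/basal thirds (apex at low z).
levelRanges <- function(parts) {
  parts <- sort(parts)
  n <- length(parts)
  k <- floor(n / 3)
  if (k < 1L) k <- 1L
  list(apical = parts[seq_len(k)],
       mid = parts[seq(k + 1L, n - k)],
       basal = parts[seq(n - k + 1L, n)])
}

#' Summarize a strain field by level, layer, and phase
#'
#' Means and standard errors of the six RCL strain components across voxels,
#' per ventricular level (basal / mid / apical partition ranges) and phase,
#' with an overall peak end-systolic row per level. End systole is the phase
#' maximizing the mean absolute circumferential strain over all analyzed
#' voxels; the layer split is at 50% transmural depth.
#'
#' @param strain a [StrainField-class].
#' @param levels optional list with integer vectors `apical`, `mid`,
#'   `basal`; default: thirds of the represented partitions.
#' @param byLayer additionally split rows by subendo/subepi layer.
#' @return list with `table` (data.frame of per-level per-phase means and
#'   standard errors), `peak` (data.frame of peak end-systolic values per
#'   level), and `endSystolePhase`.
#' @export
summarizeStrain <- function(strain, levels = NULL, byLayer = FALSE) {
  stopifnot(is(strain, "StrainField"))
  comp <- c("rr", "cc", "ll", "rc", "rl", "cl")
  P <- dim(strain@rcl)[3]
  ok <- !strain@flagged
  if (is.null(levels)) levels <- levelRanges(sort(unique(strain@partition[ok])))
  ## end systole: phase of maximal mean |E_cc|
  meanAbsEcc <- vapply(seq_len(P), function(f)
    mean(abs(strain@rcl[ok, 2, f]), na.rm = TRUE), numeric(1))
  es <- which.max(meanAbsEcc)
  groups <- if (byLayer) {
    g <- expand.grid(level = c("apical", "mid", "basal"),
                     layer = c("subendo", "subepi"),
                     stringsAsFactors = FALSE)
    split(g, seq_len(nrow(g)))
  } else {
    lapply(c("apical", "mid", "basal"),
           function(l) data.frame(level = l, stringsAsFactors = FALSE))
  }
  rows <- list()
  for (g in groups) {
    sel <- ok & strain@partition %in% levels[[g$level]]
    if (byLayer) sel <- sel & strain@layer == g$layer
    if (!any(sel)) next
    for (f in seq_len(P)) {
      m <- colMeans(strain@rcl[sel, , f, drop = FALSE], na.rm = TRUE)
      nv <- sum(sel)
      se <- apply(strain@rcl[sel, , f, drop = FALSE], 2, sd, na.rm = TRUE) /
        sqrt(nv)
      if (nv == 1L) se <- rep(0, 6L)
      rows[[length(rows) + 1L]] <- data.frame(
        level = g$level, layer = if (byLayer) g$layer else "all",
        phase = f, n = nv,
        as.list(stats::setNames(m, paste0("E", comp))),
        as.list(stats::setNames(se, paste0("se_", comp))))
    }
  }
  tab <- do.call(rbind, rows)
  peak <- tab[tab$phase == es, , drop = FALSE]
  list(table = tab, peak = peak, endSystolePhase = es)
}
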