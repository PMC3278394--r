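## Segmentation: propagate endo/epicardial contours delineated at the first
## cardiac phase to all phases with the measured displacement, and rasterize
## them into per-phase myocardial masks. Conventions: point-in-polygon at
## voxel centers, half-open pixel convention, world mm with origin at the
## grid corner. Contours are anchored at the first (encoding) phase so that
## propagation and the RCL basis share one reference.

#' Propagate contours to all cardiac phases
#'
#' Each contour vertex at phase f is the material (forward-mapped) image of
#' its phase-1 position under the tracking interpolant built from the
#' Eulerian displacement at phase f. The propagated polygon keeps its vertex
#' ordering (topology preserved) and is stored with the mean mapped axial
#' position of its vertices. Vertices outside the displacement support are
#' extrapolated from the nearest support with a warning.
#'
#' @param contours a [ContourSet-class] holding phase-1 contours.
#' @param displacement a [DisplacementField-class].
#' @param maxCenters passed to [forwardMap()].
#' @return a [ContourSet-class] with contours at all phases.
#' @export
propagateContours <- function(contours, displacement, maxCenters = 2000L) {
  stopifnot(is(contours, "ContourSet"), is(displacement, "DisplacementField"))
  P <- dim(displacement@dx)[4]
  ph1 <- contours@contours[[1]]
  out <- vector("list", P)
  out[[1]] <- ph1
  ## stack all vertices of all partitions into one query block per phase
  names_ <- names(ph1)
  nv <- vapply(ph1, function(cc) nrow(cc$endo) + nrow(cc$epi), integer(1))
  refPts <- do.call(rbind, lapply(seq_along(ph1), function(ii) {
    cc <- ph1[[ii]]
    z0 <- contours@partitionZ[ii]
    rbind(cbind(cc$endo, z0), cbind(cc$epi, z0))
  }))
  extrapWarned <- FALSE
  for (f in seq_len(P)[-1]) {
    mapped <- withCallingHandlers(
      forwardMap(displacement, f, refPts, maxCenters = maxCenters),
      warning = function(w) {
        extrapWarned <<- TRUE
        invokeRestart("muffleWarning")
      })
    pl <- vector("list", length(ph1))
    names(pl) <- names_
    pos <- 0L
    for (ii in seq_along(ph1)) {
      cc <- ph1[[ii]]
      ne <- nrow(cc$endo)
      np <- nrow(cc$epi)
      en <- mapped[pos + seq_len(ne), , drop = FALSE]
      ep <- mapped[pos + ne + seq_len(np), , drop = FALSE]
      pos <- pos + ne + np
      pl[[ii]] <- list(endo = en[, 1:2, drop = FALSE],
                       epi = ep[, 1:2, drop = FALSE],
                       z = mean(c(en[, 3], ep[, 3])))
    }
    out[[f]] <- pl
  }
  if (extrapWarned)
    warning("some contour vertices lay outside the displacement support; ",
            "nearest-support extrapolation used")
  new("ContourSet", contours = out, partitionZ = contours@partitionZ,
      partitions = contours@partitions, landmarks = contours@landmarks)
}

## Points strictly inside a closed polygon (even-odd rule via mgcv).
pointsInPolygon <- function(poly, pts) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  as.logical(mgcv::in.out(bnd, pts))
}

#' Rasterize contours into per-phase myocardial masks
#'
#' Partition-by-partition 2D rasterization: voxel centers inside the
#' epicardial polygon and outside the endocardial polygon are `TRUE`. For
#' each image partition and phase, the contour whose axial position is
#' nearest that partition's plane (within half a partition thickness) is
#' used; partitions with no nearby contour are excluded.
#'
#' @param contours a [ContourSet-class] (any number of phases).
#' @param dims grid dimensions `c(nx, ny, nz)`.
#' @param voxelSize voxel size (mm), length 3.
#' @return 4D logical array `c(dims, nPhases)`.
#' @export
rasterizeMask <- function(contours, dims, voxelSize) {
  stopifnot(is(contours, "ContourSet"))
  P <- length(contours@contours)
  mask <- array(FALSE, c(dims, P))
  xc <- axisCenters(dims[1], voxelSize[1])
  yc <- axisCenters(dims[2], voxelSize[2])
  pts <- cbind(rep(xc, times = dims[2]), rep(yc, each = dims[1]))
  zc <- axisCenters(dims[3], voxelSize[3])
  for (f in seq_len(P)) {
    pl <- contours@contours[[f]]
    if (!length(pl)) next
    czs <- vapply(pl, function(cc) cc$z, numeric(1))
    for (k in seq_len(dims[3])) {
      jj <- which.min(abs(czs - zc[k]))
      if (abs(czs[jj] - zc[k]) > voxelSize[3] / 2 + 1e-9) next
      cc <- pl[[jj]]
      inEpi <- pointsInPolygon(cc$epi, pts)
      inEndo <- pointsInPolygon(cc$endo, pts)
      mask[, , k, f] <- matrix(inEpi & !inEndo, dims[1], dims[2])
    }
  }
  mask
}

## Radius of a closed polygon around a centroid, interpolated at query
## angles (linear in angle across vertices).
polygonRadius <- function(poly, centroid, angles) {
  va <- atan2(poly[, 2] - centroid[2], poly[, 1] - centroid[1])
  vr <- sqrt((poly[, 1] - centroid[1])^2 + (poly[, 2] - centroid[2])^2)
  ord <- order(va)
  va <- va[ord]; vr <- vr[ord]
  va <- c(va, va[1] + 2 * pi)
  vr <- c(vr, vr[1])
  a <- wrapPhase(angles)
  a[a < va[1]] <- a[a < va[1]] + 2 * pi
  stats::approx(va, vr, xout = a, rule = 2)$y
}

## Transmural depth (0 endo .. 1 epi) of reference points, from the phase-1
## contours; points are assigned the contoured partition nearest their z.
transmuralDepth <- function(points, contours) {
  ph1 <- contours@contours[[1]]
  pz <- contours@partitionZ
  depth <- numeric(nrow(points))
  slice <- vapply(points[, 3], function(z) which.min(abs(pz - z)), integer(1))
  for (ii in unique(slice)) {
    cc <- ph1[[ii]]
    ctr <- colMeans(rbind(cc$endo, cc$epi))
    sel <- which(slice == ii)
    ang <- atan2(points[sel, 2] - ctr[2], points[sel, 1] - ctr[1])
    rad <- sqrt((points[sel, 1] - ctr[1])^2 + (points[sel, 2] - ctr[2])^2)
    re <- polygonRadius(cc$endo, ctr, ang)
    rp <- polygonRadius(cc$epi, ctr, ang)
    depth[sel] <- pmin(pmax((rad - re) / pmax(rp - re, 1e-9), 0), 1)
  }
  depth
}

## Midwall centroid (x, y) of the phase-1 contour assigned to each contoured
## partition index; named list by partition.
sliceCentroids <- function(contours) {
  ph1 <- contours@contours[[1]]
  out <- lapply(ph1, function(cc) colMeans(rbind(cc$endo, cc$epi)))
  names(out) <- as.character(contours@partitions)
  out
}
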