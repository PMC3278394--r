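## S4 containers for the DENSE mechanics pipeline. World coordinates are in
## mm with the origin at the grid corner; voxel centers sit at (i - 0.5) * h.
## The grid z axis is the LV long axis, apex at low z, base at high z; cardiac
## phases are 1-based with phase 1 the displacement-encoding (reference) phase.

#' Analytic LV motion model
#'
#' Axisymmetric thick-walled annulus undergoing radial contraction (with an
#' analytically incompressible in-plane radial profile when
#' `incompressible = TRUE`), affine longitudinal shortening toward the apex,
#' and a twist about the long axis that is linear in the axial coordinate.
#' Temporal modulation is a raised cosine rising from zero at the first phase
#' to its peak at `systoleIndex` and falling back to zero at the last phase.
#'
#' @slot endoRadius,epiRadius reference endo/epicardial radii (mm).
#' @slot lvLength reference base-apex length (mm).
#' @slot peakContraction endocardial radial scale at peak systole
#'   (dimensionless, in (0, 1]).
#' @slot peakTwistPerLength peak twist per unit length (degrees/mm), in the
#'   convention that positive twist is clockwise when viewed from the base.
#' @slot peakShortening peak longitudinal shortening fraction (dimensionless).
#' @slot nPhases number of cardiac phases.
#' @slot systoleIndex 1-based phase index of peak deformation.
#' @slot incompressible if `TRUE` the in-plane radial map preserves
#'   cross-sectional area between the walls so that det(F) = 1 exactly.
#' @export
setClass("MotionModel", representation(
  endoRadius = "numeric", epiRadius = "numeric", lvLength = "numeric",
  peakContraction = "numeric", peakTwistPerLength = "numeric",
  peakShortening = "numeric", nPhases = "integer", systoleIndex = "integer",
  incompressible = "logical"
))

setValidity("MotionModel", function(object) {
  msg <- character()
  if (object@endoRadius <= 0 || object@epiRadius <= object@endoRadius)
    msg <- c(msg, "need 0 < endoRadius < epiRadius")
  if (object@lvLength <= 0) msg <- c(msg, "lvLength must be positive")
  if (object@peakContraction <= 0 || object@peakContraction > 1)
    msg <- c(msg, "peakContraction must be in (0, 1]")
  if (object@peakShortening < 0 || object@peakShortening >= 1)
    msg <- c(msg, "peakShortening must be in [0, 1)")
  if (object@nPhases < 2L) msg <- c(msg, "nPhases must be >= 2")
  if (object@systoleIndex < 2L || object@systoleIndex >= object@nPhases)
    msg <- c(msg, "systoleIndex must satisfy 2 <= systoleIndex < nPhases")
  if (length(msg)) msg else TRUE
})

#' Acquisition parameters for the DENSE phantom
#'
#' @slot voxelSize voxel dimensions (mm), length 3.
#' @slot fov field of view (mm), length 3; `fov / voxelSize` must be integral.
#' @slot nPhases number of cardiac phases.
#' @slot ke displacement-encoding frequency (cycles/mm).
#' @slot snr linear magnitude SNR on the myocardium (`Inf` for noiseless).
#' @slot seed integer RNG seed; identical seeds give byte-identical output.
#' @slot background coefficients of an optional smooth background phase field
#'   (length-0 numeric disables it; otherwise `c(a0, ax, ay, az)` defines
#'   a0 + ax*x + ay*y + az*z radians with x,y,z in mm).
#' @export
setClass("AcquisitionParams", representation(
  voxelSize = "numeric", fov = "numeric", nPhases = "integer",
  ke = "numeric", snr = "numeric", seed = "integer", background = "numeric"
))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values")
  if (length(object@fov) != 3L || any(object@fov <= 0))
    msg <- c(msg, "fov must be 3 positive values")
  n <- object@fov / object@voxelSize
  if (any(abs(n - round(n)) > 1e-6))
    msg <- c(msg, "fov/voxelSize must yield integer grid dimensions")
  if (object@ke <= 0) msg <- c(msg, "ke must be positive")
  if (object@snr <= 0) msg <- c(msg, "snr must be positive")
  if (!(length(object@background) %in% c(0L, 4L)))
    msg <- c(msg, "background must be numeric(0) or 4 coefficients")
  if (length(msg)) msg else TRUE
})

#' Multiphase 3D DENSE image series
#'
#' Combined (stimulated-echo) magnitude volume plus the three wrapped phase
#' volumes encoded for displacement in x, y, and z, with acquisition metadata.
#' All arrays are 4D: `c(nx, ny, nz, nPhases)`.
#'
#' @slot magnitude 4D magnitude array.
#' @slot phaseX,phaseY,phaseZ 4D wrapped-phase arrays (radians, in (-pi, pi]).
#' @slot ke displacement-encoding frequency (cycles/mm).
#' @slot voxelSize voxel size (mm), length 3.
#' @export
setClass("DenseSeries", representation(
  magnitude = "array", phaseX = "array", phaseY = "array", phaseZ = "array",
  ke = "numeric", voxelSize = "numeric"
))

setValidity("DenseSeries", function(object) {
  msg <- character()
  d <- dim(object@magnitude)
  if (length(d) != 4L) msg <- c(msg, "magnitude must be a 4D array")
  for (s in c("phaseX", "phaseY", "phaseZ")) {
    p <- slot(object, s)
    if (!identical(dim(p), d)) msg <- c(msg, paste0(s, " shape mismatch"))
    rng <- range(p, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] <= -pi - 1e-9 || rng[2] > pi + 1e-9))
      msg <- c(msg, paste0(s, " values must lie in (-pi, pi]"))
  }
  if (object@ke <= 0) msg <- c(msg, "ke must be positive")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' Endo/epicardial contour set
#'
#' Per-phase, per-partition closed polygons for the endo- and epicardium,
#' stored as `contours[[phase]][[partition-name]] = list(endo, epi, z)` where
#' `endo`/`epi` are n x 2 matrices of in-plane vertex coordinates (mm) and `z`
#' is the axial position (mm) of the contour at that phase. Landmarks hold the
#' RV insertion point and valve-plane/apex partition indices.
#'
#' @slot contours nested list as described above.
#' @slot partitionZ axial positions (mm) of the contoured partitions at the
#'   reference phase.
#' @slot partitions integer image partition indices of the contoured slices.
#' @slot landmarks list with elements `rvInsertion` (x, y in mm),
#'   `valvePartition`, `apexPartition`.
#' @export
setClass("ContourSet", representation(
  contours = "list", partitionZ = "numeric", partitions = "integer",
  landmarks = "list"
))

setValidity("ContourSet", function(object) {
  msg <- character()
  if (length(object@partitionZ) != length(object@partitions))
    msg <- c(msg, "partitionZ and partitions must have equal length")
  for (ph in object@contours) {
    for (cc in ph) {
      if (!all(c("endo", "epi", "z") %in% names(cc))) {
        msg <- c(msg, "each contour entry needs endo, epi, z")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Eulerian displacement field
#'
#' Per-phase 3D displacement vectors (mm) on the voxel grid within the
#' myocardial mask. The vector at voxel x and phase f is the displacement of
#' the tissue currently at x relative to its position at encoding, so its
#' reference position is `x - d(x, f)`.
#'
#' @slot dx,dy,dz 4D arrays (mm); `NA` outside the mask.
#' @slot mask 4D logical array.
#' @slot reliable 4D logical array; `FALSE` flags voxels whose displacement
#'   magnitude exceeded the physiologic cap.
#' @slot ke encoding frequency (cycles/mm).
#' @slot voxelSize voxel size (mm).
#' @export
setClass("DisplacementField", representation(
  dx = "array", dy = "array", dz = "array", mask = "array",
  reliable = "array", ke = "numeric", voxelSize = "numeric"
))

setValidity("DisplacementField", function(object) {
  msg <- character()
  d <- dim(object@dx)
  if (length(d) != 4L) msg <- c(msg, "dx must be 4D")
  if (!identical(dim(object@dy), d) || !identical(dim(object@dz), d) ||
      !identical(dim(object@mask), d))
    msg <- c(msg, "component/mask shape mismatch")
  if (any(!is.finite(object@dx[object@mask])))
    msg <- c(msg, "non-finite displacement inside mask")
  if (length(msg)) msg else TRUE
})

#' Lagrangian trajectory set
#'
#' Motion trajectories of material points identified at voxel centers of the
#' first (encoding) cardiac phase.
#'
#' @slot points N x 3 matrix of material-point positions at phase 1 (mm).
#' @slot trajectories N x 3 x nPhases array of positions (mm).
#' @slot valid logical N; `FALSE` where tracking extrapolated beyond support.
#' @slot voxelIndex N x 3 integer matrix of (i, j, k) grid subscripts.
#' @slot partition integer N, image partition (k subscript) of each point.
#' @slot voxelSize voxel size (mm).
#' @export
setClass("TrajectorySet", representation(
  points = "matrix", trajectories = "array", valid = "logical",
  voxelIndex = "matrix", partition = "integer", voxelSize = "numeric"
))

setValidity("TrajectorySet", function(object) {
  msg <- character()
  n <- nrow(object@points)
  d <- dim(object@trajectories)
  if (length(d) != 3L || d[1] != n || d[2] != 3L)
    msg <- c(msg, "trajectories must be N x 3 x nPhases")
  if (length(object@valid) != n) msg <- c(msg, "valid length mismatch")
  if (length(msg)) msg else TRUE
})

#' Per-voxel Lagrangian strain field
#'
#' Symmetric 3D Lagrangian strain tensors per material voxel per phase, with
#' their projection onto the local radial/circumferential/longitudinal (RCL)
#' frame defined from the contours at the first cardiac phase.
#'
#' @slot E N x 6 x nPhases array of tensor components in grid coordinates,
#'   ordered `xx, yy, zz, xy, xz, yz`.
#' @slot rcl N x 6 x nPhases array ordered `rr, cc, ll, rc, rl, cl`.
#' @slot refPositions N x 3 reference positions (mm).
#' @slot partition integer N image partition per voxel.
#' @slot depth numeric N transmural depth in `[0, 1]` (0 = endo, 1 = epi).
#' @slot layer character N, `"subendo"` or `"subepi"` (split at depth 0.5).
#' @slot flagged logical N; `TRUE` where no strain could be estimated.
#' @export
setClass("StrainField", representation(
  E = "array", rcl = "array", refPositions = "matrix",
  partition = "integer", depth = "numeric", layer = "character",
  flagged = "logical"
))

#' Twist and torsion curves
#'
#' Per-slice twist angle and globally normalized torsion versus cardiac phase.
#' Positive twist is clockwise when viewed from the base.
#'
#' @slot twist nSlices x nPhases matrix (degrees).
#' @slot slices integer image partition indices of the rows of `twist`.
#' @slot thetaApex,thetaBase per-phase twist (degrees) averaged over the
#'   apical/basal slice ranges.
#' @slot torsion per-phase normalized torsion
#'   `(thetaApex - thetaBase) * RLV / LLV` (degrees).
#' @slot RLV average midwall radius at phase 1 (mm).
#' @slot LLV axial distance between the basal and apical range centers (mm).
#' @slot apicalRange,basalRange integer partition indices of the two ranges.
#' @export
setClass("TwistTorsionCurve", representation(
  twist = "matrix", slices = "integer", thetaApex = "numeric",
  thetaBase = "numeric", torsion = "numeric", RLV = "numeric",
  LLV = "numeric", apicalRange = "integer", basalRange = "integer"
))

setValidity("TwistTorsionCurve", function(object) {
  msg <- character()
  tor <- (object@thetaApex - object@thetaBase) * object@RLV / object@LLV
  if (length(tor) && max(abs(tor - object@torsion)) > 1e-8)
    msg <- c(msg, "torsion must equal (thetaApex - thetaBase) * RLV / LLV")
  if (length(msg)) msg else TRUE
})

#' Phantom ground truth
#'
#' Exact quantities exported alongside a rendered phantom series: the Eulerian
#' displacement field, analytic RCL strain at the reference voxels, per-phase
#' Eulerian myocardial masks, contours, and analytic twist.
#'
#' @slot displacement list of 4D arrays `dx`, `dy`, `dz` (mm; NA outside the
#'   per-phase mask).
#' @slot strainRCL list of six 4D arrays `rr, cc, ll, rc, rl, cl`, defined on
#'   the reference (phase-1) mask for every phase.
#' @slot mask 4D logical Eulerian myocardium mask per phase.
#' @slot contours [ContourSet-class] at all phases.
#' @slot twist nSlices x nPhases analytic twist (degrees, paper sign
#'   convention).
#' @slot partitions integer partition indices of twist rows.
#' @slot model,acq the generating [MotionModel-class] and
#'   [AcquisitionParams-class].
#' @export
setClass("PhantomTruth", representation(
  displacement = "list", strainRCL = "list", mask = "array",
  contours = "ContourSet", twist = "matrix", partitions = "integer",
  model = "MotionModel", acq = "AcquisitionParams"
))
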