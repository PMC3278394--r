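## Generics and accessors. Slot access from user code goes through these.

#' Number of cardiac phases
#' @param x an object with a cardiac-phase dimension.
#' @return integer phase count.
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' Voxel size in mm
#' @param x an object carrying grid metadata.
#' @return numeric length-3 voxel size (mm).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Displacement-encoding frequency (cycles/mm)
#' @param x an object carrying acquisition metadata.
#' @return numeric scalar.
#' @export
setGeneric("encodingFrequency", function(x) standardGeneric("encodingFrequency"))

#' @describeIn nPhases phase count of a DENSE series.
#' @export
setMethod("nPhases", "DenseSeries", function(x) dim(x@magnitude)[4])
#' @describeIn nPhases phase count of a displacement field.
#' @export
setMethod("nPhases", "DisplacementField", function(x) dim(x@dx)[4])
#' @describeIn nPhases phase count of a trajectory set.
#' @export
setMethod("nPhases", "TrajectorySet", function(x) dim(x@trajectories)[3])
#' @describeIn nPhases phase count of a motion model.
#' @export
setMethod("nPhases", "MotionModel", function(x) x@nPhases)
#' @describeIn nPhases phase count of acquisition parameters.
#' @export
setMethod("nPhases", "AcquisitionParams", function(x) x@nPhases)

#' @describeIn voxelSize voxel size of a DENSE series.
#' @export
setMethod("voxelSize", "DenseSeries", function(x) x@voxelSize)
#' @describeIn voxelSize voxel size of a displacement field.
#' @export
setMethod("voxelSize", "DisplacementField", function(x) x@voxelSize)
#' @describeIn voxelSize voxel size of acquisition parameters.
#' @export
setMethod("voxelSize", "AcquisitionParams", function(x) x@voxelSize)

#' @describeIn encodingFrequency encoding frequency of a DENSE series.
#' @export
setMethod("encodingFrequency", "DenseSeries", function(x) x@ke)
#' @describeIn encodingFrequency encoding frequency of a displacement field.
#' @export
setMethod("encodingFrequency", "DisplacementField", function(x) x@ke)
#' @describeIn encodingFrequency encoding frequency of acquisition parameters.
#' @export
setMethod("encodingFrequency", "AcquisitionParams", function(x) x@ke)

#' Material points of a trajectory set
#' @param x a [TrajectorySet-class].
#' @return N x 3 matrix of phase-1 positions (mm).
#' @export
materialPoints <- function(x) {
  stopifnot(is(x, "TrajectorySet"))
  x@points
}

#' Trajectory array of a trajectory set
#' @param x a [TrajectorySet-class].
#' @return N x 3 x nPhases array of positions (mm).
#' @export
trajectories <- function(x) {
  stopifnot(is(x, "TrajectorySet"))
  x@trajectories
}

#' RCL strain components
#'
#' @param x a [StrainField-class].
#' @param component one of `"rr", "cc", "ll", "rc", "rl", "cl"`, or `NULL`
#'   for the full N x 6 x nPhases array.
#' @return matrix N x nPhases (single component) or the full array.
#' @export
strainRCL <- function(x, component = NULL) {
  stopifnot(is(x, "StrainField"))
  if (is.null(component)) return(x@rcl)
  comp <- match.arg(component, c("rr", "cc", "ll", "rc", "rl", "cl"))
  x@rcl[, match(comp, c("rr", "cc", "ll", "rc", "rl", "cl")), ]
}

#' Full 3x3 strain tensor of one voxel at one phase
#' @param x a [StrainField-class].
#' @param voxel row index of the material voxel.
#' @param phase 1-based cardiac phase.
#' @return symmetric 3x3 matrix in grid coordinates.
#' @export
strainTensorAt <- function(x, voxel, phase) {
  stopifnot(is(x, "StrainField"))
  e <- x@E[voxel, , phase]
  matrix(c(e[1], e[4], e[5],
           e[4], e[2], e[6],
           e[5], e[6], e[3]), 3, 3)
}

#' Torsion curve accessor
#' @param x a [TwistTorsionCurve-class].
#' @return numeric per-phase normalized torsion (degrees).
#' @export
torsionCurve <- function(x) {
  stopifnot(is(x, "TwistTorsionCurve"))
  x@torsion
}

#' Twist matrix accessor
#' @param x a [TwistTorsionCurve-class].
#' @return nSlices x nPhases matrix of twist angles (degrees).
#' @export
twistMatrix <- function(x) {
  stopifnot(is(x, "TwistTorsionCurve"))
  x@twist
}

setMethod("show", "MotionModel", function(object) {
  cat("MotionModel:",
      sprintf("annulus %.2f-%.2f mm, length %.1f mm", object@endoRadius,
              object@epiRadius, object@lvLength), "\n")
  cat(sprintf("  contraction %.2f, twist %.2f deg/mm, shortening %.2f\n",
              object@peakContraction, object@peakTwistPerLength,
              object@peakShortening))
  cat(sprintf("  %d phases, systole at phase %d, incompressible: %s\n",
              object@nPhases, object@systoleIndex, object@incompressible))
})

setMethod("show", "DenseSeries", function(object) {
  d <- dim(object@magnitude)
  cat(sprintf("DenseSeries: %d x %d x %d grid, %d phases\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  ke = %.3g cycles/mm, voxel %.3g x %.3g x %.3g mm\n",
              object@ke, object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@dx)
  cat(sprintf("DisplacementField: %d x %d x %d grid, %d phases, %d masked voxels\n",
              d[1], d[2], d[3], d[4], sum(object@mask)))
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet: %d material points, %d phases (%d valid)\n",
              nrow(object@points), dim(object@trajectories)[3],
              sum(object@valid)))
})

setMethod("show", "StrainField", function(object) {
  cat(sprintf("StrainField: %d material voxels, %d phases (%d flagged)\n",
              dim(object@E)[1], dim(object@E)[3], sum(object@flagged)))
})

setMethod("show", "TwistTorsionCurve", function(object) {
  cat(sprintf("TwistTorsionCurve: %d slices, %d phases\n",
              nrow(object@twist), ncol(object@twist)))
  cat(sprintf("  peak |torsion| %.2f deg (RLV %.2f mm, LLV %.2f mm)\n",
              max(abs(object@torsion)), object@RLV, object@LLV))
})

setMethod("show", "ContourSet", function(object) {
  cat(sprintf("ContourSet: %d phases, %d contoured partitions\n",
              length(object@contours), length(object@partitions)))
})
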