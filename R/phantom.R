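## Analytic deforming-LV phantom. The motion model is a thick-walled annulus
## in cylindrical coordinates (R, Theta, Z): the endocardial radius scales by
## s(f) = 1 - (1 - peakContraction) * w(f); with incompressible = TRUE the
## in-plane radial profile solves r^2 = r_endo^2 + (R^2 - R_endo^2) / lamL so
## that det(F) = 1 exactly (the twist is a rotation and does not change the
## determinant), otherwise r = s * R is a uniform in-plane scale. The axial
## map is affine about the apex, z' = zApex + lamL * (Z - zApex) with
## lamL = 1 - peakShortening * w(f). The twist rotates material at axial
## height Z by alpha(Z) = -(pi/180) * tau * w * (zBase - Z) about +z, i.e.
## apical tissue twists clockwise when viewed from the base (positive angle
## in the reporting convention), linearly in Z. w(f) is a raised cosine
## reaching 1 at systoleIndex and returning to 0 at the last phase.

#' Construct an analytic LV motion model
#'
#' Defaults describe a murine left ventricle (base-apex length 6 mm, average
#' radius 2 mm represented as a 1.5-2.5 mm annulus) contracting to
#' physiologic peak strain and twist over 14 cardiac phases.
#'
#' @param endoRadius,epiRadius,lvLength reference geometry (mm).
#' @param peakContraction endocardial radial scale at systole (0, 1].
#' @param peakTwistPerLength peak twist per length (degrees/mm), positive =
#'   clockwise apical rotation viewed from the base.
#' @param peakShortening peak longitudinal shortening fraction.
#' @param nPhases number of cardiac phases.
#' @param systoleIndex 1-based phase of peak deformation.
#' @param incompressible use the area-preserving radial profile (det F = 1).
#' @return a [MotionModel-class].
#' @examples
#' motionModel()
#' @export
motionModel <- function(endoRadius = 1.5, epiRadius = 2.5, lvLength = 6,
                        peakContraction = 0.72, peakTwistPerLength = 1.4,
                        peakShortening = 0.12, nPhases = 14L,
                        systoleIndex = 6L, incompressible = TRUE) {
  new("MotionModel", endoRadius = endoRadius, epiRadius = epiRadius,
      lvLength = lvLength, peakContraction = peakContraction,
      peakTwistPerLength = peakTwistPerLength,
      peakShortening = peakShortening, nPhases = as.integer(nPhases),
      systoleIndex = as.integer(systoleIndex),
      incompressible = incompressible)
}

#' Construct acquisition parameters
#'
#' Defaults follow the 3D cine DENSE small-animal protocol: encoding
#' frequency 1.1 cycles/mm, 14 cardiac phases, 0.25 x 0.25 x 0.4 mm voxels.
#' The default field of view (8 x 8 x 8.8 mm, a 32 x 32 x 22 grid) covers the
#' whole phantom ventricle.
#'
#' @param voxelSize voxel size (mm), length 3.
#' @param fov field of view (mm), length 3.
#' @param nPhases number of cardiac phases.
#' @param ke displacement-encoding frequency (cycles/mm).
#' @param snr linear magnitude SNR on the myocardium; `Inf` disables noise.
#' @param seed integer RNG seed.
#' @param background optional background-phase coefficients
#'   `c(a0, ax, ay, az)`; `numeric(0)` (default) disables the background
#'   field.
#' @return an [AcquisitionParams-class].
#' @examples
#' acquisitionParams(snr = Inf)
#' @export
acquisitionParams <- function(voxelSize = c(0.25, 0.25, 0.4),
                              fov = c(8, 8, 8.8), nPhases = 14L, ke = 1.1,
                              snr = 20, seed = 1L,
                              background = numeric(0)) {
  new("AcquisitionParams", voxelSize = voxelSize, fov = fov,
      nPhases = as.integer(nPhases), ke = ke, snr = snr,
      seed = as.integer(seed), background = background)
}

## Temporal raised-cosine weight, w(1) = 0, w(systole) = 1, w(nPhases) = 0.
phaseWeight <- function(model, phase) {
  ps <- model@systoleIndex
  P <- model@nPhases
  ifelse(phase <= ps,
         0.5 * (1 - cos(pi * (phase - 1) / (ps - 1))),
         0.5 * (1 + cos(pi * (phase - ps) / (P - ps))))
}

## Geometry of the phantom LV inside the imaging grid: long axis through the
## in-plane FOV center, apex/base centred axially.
phantomGeometry <- function(model, acq) {
  list(cx = acq@fov[1] / 2, cy = acq@fov[2] / 2,
       apexZ = (acq@fov[3] - model@lvLength) / 2,
       baseZ = (acq@fov[3] + model@lvLength) / 2)
}

## Deformation scales at temporal weight w.
motionScales <- function(model, w) {
  list(lamL = 1 - model@peakShortening * w,
       sEndo = 1 - (1 - model@peakContraction) * w,
       tau = model@peakTwistPerLength * w)   # degrees/mm
}

## Forward map, vectorized over an N x 3 matrix of reference points (world
## mm). Returns N x 3 deformed positions. No inside checks.
motionForward <- function(model, pts, phase, cx = 0, cy = 0, apexZ = 0) {
  w <- phaseWeight(model, phase)
  sc <- motionScales(model, w)
  baseZ <- apexZ + model@lvLength
  X <- pts[, 1] - cx; Y <- pts[, 2] - cy; Z <- pts[, 3]
  R <- sqrt(X^2 + Y^2)
  Th <- atan2(Y, X)
  if (model@incompressible) {
    re <- sc$sEndo * model@endoRadius
    r <- sqrt(pmax(re^2 + (R^2 - model@endoRadius^2) / sc$lamL, 0))
  } else {
    r <- sc$sEndo * R
  }
  alpha <- -(pi / 180) * sc$tau * (baseZ - Z)
  th <- Th + alpha
  cbind(cx + r * cos(th), cy + r * sin(th), apexZ + sc$lamL * (Z - apexZ))
}

## Inverse map: N x 3 deformed points -> list(ref = N x 3 reference points,
## inside = logical N, TRUE when the reference point lies in the annulus).
motionInverse <- function(model, pts, phase, cx = 0, cy = 0, apexZ = 0) {
  w <- phaseWeight(model, phase)
  sc <- motionScales(model, w)
  baseZ <- apexZ + model@lvLength
  x <- pts[, 1] - cx; y <- pts[, 2] - cy
  Z <- apexZ + (pts[, 3] - apexZ) / sc$lamL
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  if (model@incompressible) {
    re <- sc$sEndo * model@endoRadius
    R2 <- model@endoRadius^2 + sc$lamL * (r^2 - re^2)
    R <- sqrt(pmax(R2, 0))
  } else {
    R <- r / sc$sEndo
  }
  alpha <- -(pi / 180) * sc$tau * (baseZ - Z)
  Th <- th - alpha
  inside <- R >= model@endoRadius - 1e-9 & R <= model@epiRadius + 1e-9 &
    Z >= apexZ - 1e-9 & Z <= baseZ + 1e-9
  list(ref = cbind(cx + R * cos(Th), cy + R * sin(Th), Z), inside = inside)
}

#' Evaluate the analytic motion model at material points
#'
#' Maps reference-configuration material points to their deformed positions
#' at a cardiac phase. By default the LV long axis passes through the origin
#' with the apex at z = 0 and the base at z = `lvLength`.
#'
#' @param model a [MotionModel-class].
#' @param points numeric length-3 vector or N x 3 matrix of reference
#'   positions (mm).
#' @param phase 1-based cardiac phase (phase 1 is the reference: identity).
#' @param cx,cy in-plane position of the long axis (mm).
#' @param apexZ axial position of the apex (mm).
#' @return matrix of deformed positions (mm), same shape as `points`.
#' @examples
#' m <- motionModel()
#' evaluateMotion(m, c(2, 0, 3), phase = 1)  # identity at the first phase
#' @export
evaluateMotion <- function(model, points, phase, cx = 0, cy = 0, apexZ = 0) {
  stopifnot(is(model, "MotionModel"))
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  if (phase < 1 || phase > model@nPhases)
    stop("phase must be in 1..nPhases")
  R <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
  Z <- pts[, 3]
  if (any(R < model@endoRadius - 1e-9 | R > model@epiRadius + 1e-9 |
          Z < apexZ - 1e-9 | Z > apexZ + model@lvLength + 1e-9))
    stop(structure(class = c("outOfMyocardium", "error", "condition"),
                   list(message = "material point outside the reference annulus",
                        call = sys.call())))
  out <- motionForward(model, pts, phase, cx, cy, apexZ)
  if (!is.matrix(points)) out <- drop(out)
  out
}

## Analytic RCL Green strain at reference points (world mm). Returns an
## N x 6 matrix ordered rr, cc, ll, rc, rl, cl. Derivation: in the reference
## cylindrical orthonormal basis (e_R, e_Theta, e_Z) — which coincides with
## the measurement RCL basis (radial from axis, c = l x r, l = +z) — the
## deformation gradient of the map r(R), theta' = Theta + alpha(Z),
## z' = affine(Z) gives C = F^T F with
##   C_RR = (dr/dR)^2, C_TT = (r/R)^2, C_ZZ = r^2 alpha'^2 + lamL^2,
##   C_TZ = (r/R) r alpha', other off-diagonals 0; E = (C - I)/2.
analyticStrainRCL <- function(model, pts, phase, cx = 0, cy = 0, apexZ = 0) {
  w <- phaseWeight(model, phase)
  sc <- motionScales(model, w)
  R <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
  if (model@incompressible) {
    re <- sc$sEndo * model@endoRadius
    r <- sqrt(pmax(re^2 + (R^2 - model@endoRadius^2) / sc$lamL, 0))
    drdR <- R / (r * sc$lamL)
  } else {
    r <- sc$sEndo * R
    drdR <- rep(sc$sEndo, length(R))
  }
  ## alpha(Z) = -(pi/180) tau (baseZ - Z)  =>  d(alpha)/dZ = +(pi/180) tau
  aprime <- (pi / 180) * sc$tau
  lamC <- r / R
  Err <- (drdR^2 - 1) / 2
  Ecc <- (lamC^2 - 1) / 2
  Ell <- (r^2 * aprime^2 + sc$lamL^2 - 1) / 2
  Ecl <- lamC * r * aprime / 2
  cbind(rr = Err, cc = Ecc, ll = Ell, rc = 0, rl = 0, cl = Ecl)
}

## Ground-truth contours: reference circles at the contoured image partitions
## mapped materially through the motion (same vertex parameterization at all
## phases, matching what contour propagation produces).
modelContours <- function(model, acq, nVertices = 64L) {
  geom <- phantomGeometry(model, acq)
  dims <- round(acq@fov / acq@voxelSize)
  zc <- axisCenters(dims[3], acq@voxelSize[3])
  keep <- which(zc >= geom$apexZ - 1e-9 & zc <= geom$baseZ + 1e-9)
  ang <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  phases <- vector("list", acq@nPhases)
  for (f in seq_len(acq@nPhases)) {
    pl <- vector("list", length(keep))
    names(pl) <- as.character(keep)
    for (ii in seq_along(keep)) {
      z0 <- zc[keep[ii]]
      mk <- function(rad) {
        ref <- cbind(geom$cx + rad * cos(ang), geom$cy + rad * sin(ang), z0)
        motionForward(model, ref, f, geom$cx, geom$cy, geom$apexZ)
      }
      en <- mk(model@endoRadius)
      ep <- mk(model@epiRadius)
      pl[[ii]] <- list(endo = en[, 1:2, drop = FALSE],
                       epi = ep[, 1:2, drop = FALSE],
                       z = mean(c(en[, 3], ep[, 3])))
    }
    phases[[f]] <- pl
  }
  new("ContourSet", contours = phases, partitionZ = zc[keep],
      partitions = as.integer(keep),
      landmarks = list(rvInsertion = c(geom$cx - model@epiRadius, geom$cy),
                       valvePartition = as.integer(max(keep)),
                       apexPartition = as.integer(min(keep))))
}

## Background phase field evaluated at world coordinates (radians, unwrapped).
backgroundField <- function(background, pts) {
  if (length(background) == 0L) return(rep(0, nrow(pts)))
  background[1] + background[2] * pts[, 1] + background[3] * pts[, 2] +
    background[4] * pts[, 3]
}

#' Render a synthetic 3D cine DENSE series with ground truth
#'
#' Evaluates the motion model Eulerian-wise on the acquisition grid: each
#' voxel at a cardiac phase holds the tissue that was at its inverse-mapped
#' reference position at encoding, and its phase in encoding direction j is
#' `wrap(2*pi*ke*d_j + background)`. Complex Gaussian noise is added to the
#' complex signal (per encoding direction) before phase extraction; the
#' stored magnitude is the root-sum-of-squares over the three directions.
#'
#' @param model a [MotionModel-class].
#' @param acq an [AcquisitionParams-class].
#' @return list with elements `series` (a [DenseSeries-class]) and `truth`
#'   (a [PhantomTruth-class]).
#' @examples
#' p <- renderDenseSeries(motionModel(nPhases = 4L, systoleIndex = 3L),
#'                        acquisitionParams(voxelSize = c(0.5, 0.5, 0.8),
#'                                          nPhases = 4L, snr = Inf))
#' p$series
#' @export
renderDenseSeries <- function(model, acq) {
  stopifnot(is(model, "MotionModel"), is(acq, "AcquisitionParams"))
  if (model@nPhases != acq@nPhases)
    stop("model and acquisition must agree on nPhases")
  dims <- acq@fov / acq@voxelSize
  if (any(abs(dims - round(dims)) > 1e-6))
    stop("fov/voxelSize must yield integer grid dimensions")
  dims <- as.integer(round(dims))
  geom <- phantomGeometry(model, acq)
  P <- acq@nPhases
  nvox <- prod(dims)
  centers <- voxelCenters(seq_len(nvox), dims, acq@voxelSize)

  set.seed(acq@seed)
  d4 <- c(dims, P)
  mag <- array(0, d4)
  phs <- list(x = array(0, d4), y = array(0, d4), z = array(0, d4))
  disp <- list(dx = array(NA_real_, d4), dy = array(NA_real_, d4),
               dz = array(NA_real_, d4))
  mask <- array(FALSE, d4)
  bg <- backgroundField(acq@background, centers)
  sigma <- if (is.finite(acq@snr)) 1 / acq@snr else 0

  ## reference mask and analytic strain on it
  inv1 <- motionInverse(model, centers, 1L, geom$cx, geom$cy, geom$apexZ)
  refIdx <- which(inv1$inside)
  strain <- lapply(seq_len(6), function(i) array(NA_real_, d4))
  names(strain) <- c("rr", "cc", "ll", "rc", "rl", "cl")

  for (f in seq_len(P)) {
    inv <- motionInverse(model, centers, f, geom$cx, geom$cy, geom$apexZ)
    inside <- inv$inside
    dmm <- centers - inv$ref
    dmm[!inside, ] <- 0
    amp <- as.numeric(inside)
    sl <- (f - 1L) * nvox
    for (j in 1:3) {
      phi <- 2 * pi * acq@ke * dmm[, j] + bg
      z <- complex(modulus = amp, argument = phi)
      if (sigma > 0)
        z <- z + complex(real = rnorm(nvox, 0, sigma),
                         imaginary = rnorm(nvox, 0, sigma))
      phs[[j]][sl + seq_len(nvox)] <- Arg(z)
      mag[sl + seq_len(nvox)] <- mag[sl + seq_len(nvox)] + Mod(z)^2
      disp[[j]][sl + which(inside)] <- dmm[inside, j]
    }
    mask[sl + which(inside)] <- TRUE
    sRCL <- analyticStrainRCL(model, centers[refIdx, , drop = FALSE], f,
                              geom$cx, geom$cy, geom$apexZ)
    for (cn in seq_len(6)) strain[[cn]][sl + refIdx] <- sRCL[, cn]
  }
  mag <- sqrt(mag)
  ## Arg() returns values in [-pi, pi]; fold -pi onto +pi for (-pi, pi].
  for (j in 1:3) phs[[j]][phs[[j]] <= -pi] <- pi

  contours <- modelContours(model, acq)
  zc <- axisCenters(dims[3], acq@voxelSize[3])
  keep <- contours@partitions
  twist <- outer(geom$baseZ - zc[keep],
                 phaseWeight(model, seq_len(P)) * model@peakTwistPerLength)

  series <- new("DenseSeries", magnitude = mag, phaseX = phs$x,
                phaseY = phs$y, phaseZ = phs$z, ke = acq@ke,
                voxelSize = acq@voxelSize)
  truth <- new("PhantomTruth", displacement = disp, strainRCL = strain,
               mask = mask, contours = contours, twist = twist,
               partitions = keep, model = model, acq = acq)
  list(series = series, truth = truth)
}

#' Render raw phase-cycled stimulated-echo acquisitions
#'
#' Emits, for each encoding direction, the three acquisitions of a
#' three-point phase-cycling scheme: the stimulated echo carries the
#' phase-cycle increments while the artifact-generating echo is
#' phase-cycle-invariant, so a linear combination isolates the stimulated
#' echo.
#'
#' @param model a [MotionModel-class].
#' @param acq an [AcquisitionParams-class] (`snr = Inf` gives noiseless
#'   data).
#' @param artifactAmplitude amplitude of the phase-cycle-invariant artifact
#'   echo relative to the stimulated echo.
#' @param increments phase-cycle increments (radians), default
#'   `c(0, 2*pi/3, 4*pi/3)`.
#' @return list with `raw` (per direction, a list of three complex 4D
#'   arrays), `ste` (per direction, the true stimulated-echo complex array),
#'   and `increments`.
#' @export
renderPhaseCycledRaw <- function(model, acq, artifactAmplitude = 1,
                                 increments = c(0, 2 * pi / 3, 4 * pi / 3)) {
  stopifnot(artifactAmplitude >= 0, length(increments) == 3L)
  rendered <- renderDenseSeries(model,
                                new("AcquisitionParams",
                                    voxelSize = acq@voxelSize, fov = acq@fov,
                                    nPhases = acq@nPhases, ke = acq@ke,
                                    snr = Inf, seed = acq@seed,
                                    background = acq@background))
  series <- rendered$series
  d4 <- dim(series@magnitude)
  nvox <- prod(d4[1:3])
  centers <- voxelCenters(seq_len(nvox), d4[1:3], acq@voxelSize)
  ## smooth phase-cycle-invariant artifact: Gaussian envelope, fixed phase
  env <- exp(-rowSums(sweep(centers, 2, acq@fov / 2)^2) /
               (2 * (max(acq@fov) / 3)^2))
  artifact <- artifactAmplitude * complex(modulus = env, argument = 0.7)
  sigma <- if (is.finite(acq@snr)) 1 / acq@snr else 0
  set.seed(acq@seed)
  chan <- list(x = series@phaseX, y = series@phaseY, z = series@phaseZ)
  steMag <- series@magnitude / sqrt(3)  # per-direction magnitude
  raw <- ste <- vector("list", 3L)
  names(raw) <- names(ste) <- c("x", "y", "z")
  for (j in 1:3) {
    s <- complex(modulus = steMag, argument = chan[[j]])
    dim(s) <- d4
    ste[[j]] <- s
    raw[[j]] <- lapply(increments, function(inc) {
      r <- s * exp(1i * inc) + rep(artifact, d4[4])
      if (sigma > 0)
        r <- r + complex(real = rnorm(length(r), 0, sigma),
                         imaginary = rnorm(length(r), 0, sigma))
      dim(r) <- d4
      r
    })
  }
  list(raw = raw, ste = ste, increments = increments)
}
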