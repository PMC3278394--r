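## End-to-end pipeline orchestration and protocol arithmetic.

#' Reconstructed grid dimensions from protocol parameters
#'
#' In-plane dimensions are `fov / voxel` (must be integral). The partition
#' dimension follows the acquisition arithmetic: `nPartitionsAcquired`
#' partitions zero-padded by `zeroPadFactor` during reconstruction, with
#' `edgeDiscard` partitions discarded at each end of the volume after the
#' Fourier transform in the partition direction.
#'
#' @param fov field of view (mm), length 3.
#' @param voxel voxel size (mm), length 3.
#' @param nPartitionsAcquired number of acquired 3D partitions.
#' @param zeroPadFactor partition zero-padding factor.
#' @param edgeDiscard partitions discarded at each end.
#' @return integer grid dimensions `c(nx, ny, nz)`.
#' @examples
#' reconstructedGridDims(c(32, 32, 8.4), c(0.25, 0.25, 0.4), 14, 2, 3)
#' @export
reconstructedGridDims <- function(fov, voxel, nPartitionsAcquired,
                                  zeroPadFactor = 1L, edgeDiscard = 0L) {
  inplane <- fov[1:2] / voxel[1:2]
  if (any(abs(inplane - round(inplane)) > 1e-6))
    stop("fov/voxel must be integral in-plane")
  nz <- nPartitionsAcquired * zeroPadFactor - 2L * edgeDiscard
  if (nz <= 0L) stop("partition arithmetic yields a non-positive dimension")
  as.integer(c(round(inplane), nz))
}

#' Default pipeline configuration
#'
#' @param seed integer seed used for every stochastic stage.
#' @return a config list accepted by [runPipeline()], describing the default
#'   phantom study (14 phases, ke 1.1 cycles/mm, 0.25 x 0.25 x 0.4 mm
#'   voxels, SNR 20).
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    phantom = list(motion = list(), acquisition = list(seed = seed)),
    thresholds = list(svCutoff = 1e-6, displacementCap = 3,
                      smoothingOrder = 10L, maxCenters = 2000L,
                      dilation = c(2L, 2L, 1L)),
    seed = as.integer(seed)
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure, thresholds, and input-file existence before any
#' computation; called by [runPipeline()].
#'
#' @param config config list (see [defaultPipelineConfig()]), or the path of
#'   a JSON file holding one.
#' @return the normalized config list, invisibly on success; errors with a
#'   stage-named diagnostic otherwise.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config: file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$phantom) && is.null(config$input))
    stop("config: need either 'phantom' parameters or 'input' paths")
  if (!is.null(config$input)) {
    if (is.null(config$input$series) || !dir.exists(config$input$series))
      stop("config: input series directory missing")
    if (is.null(config$input$contours) || !file.exists(config$input$contours))
      stop("config: input contour file missing")
  }
  th <- config$thresholds
  if (is.null(th)) th <- defaultPipelineConfig()$thresholds
  defaults <- defaultPipelineConfig()$thresholds
  for (nm in names(defaults)) if (is.null(th[[nm]])) th[[nm]] <- defaults[[nm]]
  if (any(unlist(th[c("svCutoff", "displacementCap", "maxCenters")]) <= 0))
    stop("config: thresholds must be positive")
  config$thresholds <- th
  if (is.null(config$seed)) config$seed <- 1L
  invisible(config)
}

#' Run the full DENSE mechanics pipeline
#'
#' Stages, in the processing order of the method: input (phantom generation
#' or container reading), segmentation of the first phase, spatiotemporal
#' phase unwrapping within a motion-dilated mask, conversion to Eulerian
#' displacement, contour propagation and final per-phase masks, Lagrangian
#' tissue tracking with polynomial smoothing, strain tensor estimation with
#' RCL decomposition, and twist/torsion quantification. Deterministic given
#' the config seed.
#'
#' @param config config list or JSON path (see [validatePipelineConfig()]).
#' @param outDir optional output directory for tables, summaries, and
#'   provenance.
#' @param verbose log stage progress and voxel accounting.
#' @return result bundle: a list with elements `series`, `truth` (phantom
#'   runs only), `contours`, `mask`, `displacement`, `trajectories`,
#'   `strain`, `twistTorsion`, `summary`, `provenance`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL,
                        verbose = FALSE) {
  config <- validatePipelineConfig(config)
  th <- config$thresholds
  say <- function(...) if (verbose) message(sprintf(...))

  truth <- NULL
  if (!is.null(config$phantom)) {
    say("stage phantom: rendering synthetic series")
    model <- do.call(motionModel, as.list(config$phantom$motion))
    acqArgs <- as.list(config$phantom$acquisition)
    if (is.null(acqArgs$seed)) acqArgs$seed <- config$seed
    acq <- do.call(acquisitionParams, acqArgs)
    rendered <- renderDenseSeries(model, acq)
    series <- rendered$series
    truth <- rendered$truth
    contours1 <- truth@contours
    ## pipeline input: contours at the first phase only
    contours1@contours <- contours1@contours[1]
  } else {
    say("stage input: reading series and contours")
    series <- readDenseSeries(config$input$series)
    contours1 <- readContours(config$input$contours)
    contours1@contours <- contours1@contours[1]
  }
  dims <- dim(series@magnitude)[1:3]
  P <- nPhases(series)

  say("stage segmentation: rasterizing first-phase contours")
  mask1 <- rasterizeMask(contours1, dims, series@voxelSize)[, , , 1]
  if (!any(mask1)) stop("segmentation: empty first-phase mask")

  say("stage unwrap: preliminary mask + spatiotemporal unwrapping")
  ## candidate region per phase: the phase-1 mask dilated by the expected
  ## per-phase motion, intersected with a stimulated-echo signal mask (the
  ## dilation ring outside the myocardium carries no stimulated echo)
  magThr <- 0.5 * stats::median(series@magnitude[, , , 1][mask1])
  prelim <- expandMask(dilateMask(mask1, th$dilation),
                       dim(series@magnitude)) & series@magnitude > magThr
  disp0 <- displacementFromSeries(series, prelim, cap = th$displacementCap)
  say("  %d voxel-phases in preliminary mask", sum(prelim))

  say("stage segmentation: propagating contours to %d phases", P)
  contoursAll <- suppressWarnings(
    propagateContours(contours1, disp0, maxCenters = th$maxCenters))
  maskAll <- rasterizeMask(contoursAll, dims, series@voxelSize)

  ## restrict displacement to the final per-phase masks
  finalMask <- maskAll & disp0@mask
  displacement <- assembleVectorField(disp0@dx, disp0@dy, disp0@dz,
                                      mask = finalMask, ke = series@ke,
                                      voxelSize = series@voxelSize,
                                      cap = th$displacementCap)
  say("  %d masked voxel-phases, %d reliable", sum(displacement@mask),
      sum(displacement@reliable))

  say("stage tracking: trajectories + order-%d smoothing", th$smoothingOrder)
  traj <- buildTrajectories(displacement, maxCenters = th$maxCenters)
  traj <- smoothTrajectories(traj, order = th$smoothingOrder)

  say("stage mechanics: strain tensors and RCL decomposition")
  strain <- computeStrain(traj, contoursAll, svCutoff = th$svCutoff)
  say("  %d material voxels, %d flagged", length(strain@flagged),
      sum(strain@flagged))

  say("stage mechanics: twist and torsion")
  tt <- computeTwistTorsion(traj, contoursAll,
                            apicalRange = config$levels$apical,
                            basalRange = config$levels$basal)
  lv <- levelRanges(contoursAll@partitions)
  if (!is.null(config$levels)) lv[names(config$levels)] <- config$levels
  summary <- summarizeStrain(strain, levels = lv)

  provenance <- list(configHash = configHash(config),
                     package = "denseMechanics",
                     version = as.character(utils::packageVersion("denseMechanics")),
                     seed = config$seed)

  bundle <- list(series = series, truth = truth, contours = contoursAll,
                 mask = maskAll, displacement = displacement,
                 trajectories = traj, strain = strain, twistTorsion = tt,
                 summary = summary, provenance = provenance)
  if (!is.null(outDir)) writePipelineOutputs(bundle, outDir, config)
  bundle
}

## Stable hash of the config: md5 of its canonical JSON serialization.
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

writePipelineOutputs <- function(bundle, outDir, config) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- bundle$provenance$configHash
  wt <- function(df, name) {
    path <- file.path(outDir, name)
    con <- file(path, "w")
    writeLines(sprintf("# config %s", hash), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wt(bundle$summary$table, "strain_summary.tsv")
  wt(bundle$summary$peak, "strain_peak.tsv")
  tw <- bundle$twistTorsion
  wt(data.frame(phase = seq_along(tw@torsion), thetaApex = tw@thetaApex,
                thetaBase = tw@thetaBase, torsion = tw@torsion),
     "twist_torsion.tsv")
  wt(strainTable(bundle$strain), "voxel_strain.tsv")
  jsonlite::write_json(c(bundle$provenance, list(config = config)),
                       file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outDir)
}
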