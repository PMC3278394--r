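## Reading and writing the pipeline's containers. Volumes are exchanged as
## NIfTI files in a directory layout (one file per phase and channel) with a
## JSON metadata sidecar; contours and summaries are structured text.

#' Write a DENSE series to a directory
#'
#' Layout: `magnitude_<phase>.nii.gz`, `phase_x_<phase>.nii.gz` (and y, z)
#' per cardiac phase plus `series.json` with `ke`, `voxel_size`, and
#' `n_phases`.
#'
#' @param series a [DenseSeries-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeDenseSeries <- function(series, dir) {
  stopifnot(is(series, "DenseSeries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  P <- nPhases(series)
  chans <- list(magnitude = series@magnitude, phase_x = series@phaseX,
                phase_y = series@phaseY, phase_z = series@phaseZ)
  for (nm in names(chans)) {
    for (f in seq_len(P)) {
      img <- RNifti::asNifti(chans[[nm]][, , , f],
                             pixdim = series@voxelSize)
      RNifti::writeNifti(img, file.path(dir, sprintf("%s_%02d.nii.gz", nm, f)))
    }
  }
  jsonlite::write_json(list(ke = series@ke, voxel_size = series@voxelSize,
                            n_phases = P),
                       file.path(dir, "series.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a DENSE series from a directory written by [writeDenseSeries()]
#'
#' @param dir directory containing the series.
#' @return a [DenseSeries-class].
#' @export
readDenseSeries <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  P <- meta$n_phases
  rd <- function(nm) {
    vols <- lapply(seq_len(P), function(f)
      as.array(RNifti::readNifti(file.path(dir,
                                           sprintf("%s_%02d.nii.gz", nm, f)))))
    array(unlist(vols), c(dim(vols[[1]]), P))
  }
  new("DenseSeries", magnitude = rd("magnitude"), phaseX = rd("phase_x"),
      phaseY = rd("phase_y"), phaseZ = rd("phase_z"), ke = meta$ke,
      voxelSize = meta$voxel_size)
}

#' Write contours as structured JSON
#'
#' @param contours a [ContourSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeContours <- function(contours, path) {
  stopifnot(is(contours, "ContourSet"))
  obj <- list(
    partitions = contours@partitions,
    partition_z = contours@partitionZ,
    landmarks = contours@landmarks,
    phases = lapply(contours@contours, function(pl)
      lapply(pl, function(cc)
        list(endo = unname(cc$endo), epi = unname(cc$epi), z = cc$z))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read contours written by [writeContours()]
#'
#' @param path JSON file path.
#' @return a [ContourSet-class].
#' @export
readContours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  asPoly <- function(rows)
    do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  phases <- lapply(obj$phases, function(pl)
    lapply(pl, function(cc)
      list(endo = asPoly(cc$endo), epi = asPoly(cc$epi),
           z = as.numeric(cc$z))))
  lm <- obj$landmarks
  lm$rvInsertion <- unlist(lm$rvInsertion, use.names = FALSE)
  lm$valvePartition <- as.integer(lm$valvePartition)
  lm$apexPartition <- as.integer(lm$apexPartition)
  new("ContourSet", contours = phases,
      partitionZ = unlist(obj$partition_z, use.names = FALSE),
      partitions = as.integer(unlist(obj$partitions)), landmarks = lm)
}

#' Export trajectories as a table
#'
#' @param traj a [TrajectorySet-class].
#' @return data.frame with columns point, phase, x, y, z, valid.
#' @export
trajectoryTable <- function(traj) {
  stopifnot(is(traj, "TrajectorySet"))
  n <- nrow(traj@points)
  P <- dim(traj@trajectories)[3]
  data.frame(point = rep(seq_len(n), P),
             phase = rep(seq_len(P), each = n),
             x = as.vector(traj@trajectories[, 1, ]),
             y = as.vector(traj@trajectories[, 2, ]),
             z = as.vector(traj@trajectories[, 3, ]),
             valid = rep(traj@valid, P))
}

#' Export per-voxel RCL strain as a table
#'
#' @param strain a [StrainField-class].
#' @return data.frame with one row per material voxel per phase.
#' @export
strainTable <- function(strain) {
  stopifnot(is(strain, "StrainField"))
  n <- dim(strain@rcl)[1]
  P <- dim(strain@rcl)[3]
  comp <- c("Err", "Ecc", "Ell", "Erc", "Erl", "Ecl")
  out <- data.frame(voxel = rep(seq_len(n), P),
                    phase = rep(seq_len(P), each = n),
                    partition = rep(strain@partition, P),
                    depth = rep(strain@depth, P),
                    layer = rep(strain@layer, P))
  for (i in seq_len(6))
    out[[comp[i]]] <- as.vector(strain@rcl[, i, ])
  out[!rep(strain@flagged, P), , drop = FALSE]
}
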