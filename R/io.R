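#' Write a specimen volume as NIfTI-1
#'
#' @param volume a \code{\linkS4class{SpecimenVolume}}.
#' @param path output file (".nii" recommended; written uncompressed).
#' @return the path, invisibly.
#' @export
writeSpecimenVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@data, pixdim = volume@voxelSize)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a specimen volume from NIfTI
#'
#' @param path NIfTI file.
#' @param specimenID,diagnosis metadata not carried by the NIfTI header.
#' @return a \code{\linkS4class{SpecimenVolume}}.
#' @export
readSpecimenVolume <- function(path, specimenID = basename(path),
                               diagnosis = 0L) {
  img <- RNifti::readNifti(path)
  new("SpecimenVolume", data = array(as.numeric(img), dim = dim(img)),
      voxelSize = RNifti::pixdim(img)[seq_len(3)],
      specimenID = specimenID, diagnosis = as.integer(diagnosis))
}

#' Write a grid layout as JSON
#'
#' The JSON round-trips losslessly through \code{\link{readGridLayout}}.
#'
#' @param layout a \code{\linkS4class{GridLayout}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGridLayout <- function(layout, path) {
  obj <- list(origin = layout@origin, spacing_mm = layout@spacingMM,
              voxel_size_mm = layout@voxelSizeMM, rotation = layout@rotation,
              well_markers = layout@wellMarkers, grid_dim = layout@gridDim,
              sections = layout@sections)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a grid layout from JSON
#'
#' @param path JSON file written by \code{\link{writeGridLayout}}.
#' @return a \code{\linkS4class{GridLayout}}.
#' @export
readGridLayout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GridLayout", origin = obj$origin, spacingMM = obj$spacing_mm,
      voxelSizeMM = obj$voxel_size_mm, rotation = obj$rotation,
      wellMarkers = matrix(obj$well_markers, ncol = 2),
      gridDim = as.integer(obj$grid_dim),
      sections = as.data.frame(obj$sections))
}

#' Write a ground-truth or section table as CSV
#'
#' Ground-truth tables are written with the fixed leading column order
#' \code{specimen_id, diagnosis, grid_row, grid_col, region, nm_conc,
#' fe_conc, true_cnr, valid}; any further columns follow.
#'
#' @param truth ground-truth data.frame.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  lead <- c("specimen_id", "diagnosis", "grid_row", "grid_col", "region",
            "nm_conc", "fe_conc", "true_cnr")
  out <- truth
  out$valid <- truth$is_valid
  cols <- c(lead, "valid", setdiff(names(out), c(lead, "valid")))
  write.csv(out[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a phantom cohort to a directory
#'
#' Writes per-specimen NIfTI volumes, grid-layout JSON files, reference and
#' SN mask index lists (JSON), the ground-truth CSV and the configuration
#' summary.
#'
#' @param cohort output of \code{\link{generateCohort}} (rendered).
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writePhantom <- function(cohort, dir) {
  if (is.null(cohort$specimens))
    stop("cohort was generated with render = FALSE; nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTruthTable(cohort$truth, file.path(dir, "ground_truth.csv"))
  cfg <- cohort$config
  jsonlite::write_json(
    list(n_specimens_ad = cfg@nSpecimensAD, n_specimens_pd = cfg@nSpecimensPD,
         cnr_model = cfg@cnrModel, signal_coeffs = as.list(cfg@signalCoeffs),
         cond_slopes = as.list(cfg@condSlopes),
         subject_intercept_sd = cfg@subjectInterceptSD,
         residual_sd = cfg@residualSD, image_params = cfg@imageParams,
         seed = cfg@seed),
    file.path(dir, "phantom_config.json"), digits = NA, auto_unbox = TRUE)
  for (id in names(cohort$specimens)) {
    sp <- cohort$specimens[[id]]
    writeSpecimenVolume(sp$volume, file.path(dir, paste0(id, ".nii")))
    writeGridLayout(sp$layout, file.path(dir, paste0(id, "_grid.json")))
    jsonlite::write_json(
      list(reference = which(sp$masks$reference),
           sn = which(sp$masks$sn), dim = dim(sp$masks$reference)),
      file.path(dir, paste0(id, "_masks.json")), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Write a section table as CSV
#'
#' Column order is fixed: \code{specimen_id, diagnosis, grid_row, grid_col,
#' region, mean_cnr, sn_voxel_fraction, nm_conc, fe_conc, n_voxels},
#' followed by the \code{is_sn}/\code{is_posterior} flags.
#'
#' @param sections section table from \code{\link{aggregateSections}}.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
writeSectionTable <- function(sections, path) {
  cols <- c("specimen_id", "diagnosis", "grid_row", "grid_col", "region",
            "mean_cnr", "sn_voxel_fraction", "nm_conc", "fe_conc",
            "n_voxels", "is_sn", "is_posterior")
  write.csv(sections[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a section table from CSV
#' @param path CSV written by \code{\link{writeSectionTable}}.
#' @return data.frame.
#' @export
readSectionTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
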