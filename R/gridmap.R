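#' Map image voxels to grid sections
#'
#' Assigns every voxel of the flattened image to a dissection-grid section
#' by the rigid transform of the layout (origin, rotation) followed by
#' integer division by the section pitch. A voxel center falling exactly on
#' a section boundary is assigned to the lower-index section. Voxels
#' outside the grid, or at grid positions with no section, map to NA.
#'
#' @param flat a \code{\linkS4class{CleanFlatImage}} (or any object with a
#'   matrix in \code{@intensity}) defining the image dimensions.
#' @param layout a \code{\linkS4class{GridLayout}}.
#' @return integer matrix of section ids (NA where unassigned).
#' @section Errors:
#' A transform that places the whole grid outside the image raises an
#' error.
#' @export
registerGrid <- function(flat, layout) {
  dims <- dim(flat@intensity)
  sp <- layout@spacingMM / layout@voxelSizeMM
  theta <- layout@rotation * pi / 180
  ## voxel centers in 0-based coordinates
  rc <- expand.grid(r = seq_len(dims[1]) - 0.5, c = seq_len(dims[2]) - 0.5)
  dr <- rc$r - layout@origin[1]
  dc <- rc$c - layout@origin[2]
  ## rotate image coordinates back into the grid frame
  gr <- cos(theta) * dr + sin(theta) * dc
  gc <- -sin(theta) * dr + cos(theta) * dc
  ## boundary ties go to the lower-index section: ceiling(x) - 1 maps (0, sp]
  ## to 0; round first to absorb float fuzz from the rotation
  secRow <- as.integer(ceiling(round(gr / sp, 9)) - 1)
  secCol <- as.integer(ceiling(round(gc / sp, 9)) - 1)
  sec <- layout@sections
  key <- paste(sec$grid_row, sec$grid_col)
  id <- sec$section_id[match(paste(secRow, secCol), key)]
  inGrid <- secRow >= 0 & secRow < layout@gridDim[1] &
    secCol >= 0 & secCol < layout@gridDim[2]
  id[!inGrid] <- NA_integer_
  map <- matrix(as.integer(id), dims[1], dims[2])
  if (all(is.na(map)))
    stop("grid transform places all sections outside the image")
  map
}

#' Aggregate cleaned voxels into a per-section table
#'
#' Computes, for every usable grid section, the mean CNR of its valid
#' voxels and --- for sections flagged as containing substantia nigra ---
#' the fraction of valid voxels with CNR above \code{snCnrThreshold},
#' and joins the per-section NM and Fe concentrations. Sections flagged
#' invalid in the layout (lost to dissection or assay problems) are
#' dropped; sections with zero valid voxels are emitted with missing
#' \code{mean_cnr} and a warning.
#'
#' @param flat cleaned \code{\linkS4class{CleanFlatImage}}.
#' @param map voxel-to-section matrix from \code{\link{registerGrid}}.
#' @param layout the specimen's \code{\linkS4class{GridLayout}}.
#' @param concentrations data.frame with \code{section_id},
#'   \code{specimen_id}, \code{diagnosis}, \code{nm_conc}, \code{fe_conc}
#'   for this specimen (e.g. ground-truth rows, or assay results).
#' @param snCnrThreshold CNR above which a voxel counts as SN-containing
#'   (default 0.10).
#' @return data.frame (one row per usable section): \code{specimen_id},
#'   \code{diagnosis}, \code{grid_row}, \code{grid_col}, \code{region},
#'   \code{mean_cnr}, \code{sn_voxel_fraction} (NA outside SN sections),
#'   \code{nm_conc}, \code{fe_conc}, \code{n_voxels}, \code{is_sn},
#'   \code{is_posterior}.
#' @export
aggregateSections <- function(flat, map, layout, concentrations,
                              snCnrThreshold = 0.10) {
  sec <- layout@sections
  conc <- concentrations[match(sec$section_id, concentrations$section_id), ]
  valid <- flat@validity == .REASON[["valid"]]
  rows <- lapply(seq_len(nrow(sec)), function(i) {
    sid <- sec$section_id[i]
    idx <- which(!is.na(map) & map == sid & valid)
    v <- flat@cnr[idx]
    n <- length(idx)
    meanCnr <- if (n >= 1L) mean(v) else NA_real_
    frac <- if (sec$is_sn[i] && n >= 1L) mean(v > snCnrThreshold) else NA_real_
    data.frame(specimen_id = conc$specimen_id[i],
               diagnosis = conc$diagnosis[i],
               grid_row = sec$grid_row[i], grid_col = sec$grid_col[i],
               region = sec$region[i], mean_cnr = meanCnr,
               sn_voxel_fraction = frac,
               nm_conc = conc$nm_conc[i], fe_conc = conc$fe_conc[i],
               n_voxels = n, is_sn = sec$is_sn[i],
               is_posterior = sec$is_posterior[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[sec$is_valid, , drop = FALSE]
  if (any(is.na(out$mean_cnr)))
    warning(sum(is.na(out$mean_cnr)),
            " section(s) with zero valid voxels; mean_cnr missing")
  rownames(out) <- NULL
  out
}

#' Run cleaning and aggregation for every specimen of a cohort
#'
#' Convenience wrapper: cleans each rendered specimen volume and aggregates
#' it against the cohort ground truth, returning the combined section
#' table.
#'
#' @param cohort output of \code{\link{generateCohort}} (rendered).
#' @param ... passed to \code{\link{cleanVolume}}.
#' @return combined section table (see \code{\link{aggregateSections}}).
#' @export
cohortSectionTable <- function(cohort, ...) {
  stopifnot(!is.null(cohort$specimens))
  tabs <- lapply(names(cohort$specimens), function(id) {
    sp <- cohort$specimens[[id]]
    cl <- cleanVolume(sp$volume, sp$layout,
                      referenceMask = sp$masks$reference, ...)
    aggregateSections(cl$flat, cl$map, sp$layout,
                      cohort$truth[cohort$truth$specimen_id == id, ])
  })
  do.call(rbind, tabs)
}
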