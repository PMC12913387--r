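## kernel density estimate used for thresholding and mode finding:
## Gaussian kernel, Silverman rule-of-thumb bandwidth, 512-point grid.
.kde <- function(x, bandwidth = NULL, n = 512L) {
  bw <- bandwidth %||% bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0)
    stop("degenerate intensity distribution: zero bandwidth")
  density(x, bw = bw, n = n)
}

## indices of local maxima of y (endpoints included, plateaus collapse left)
.localMaxima <- function(y) {
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  which(y > left & y >= right)
}

#' Low-signal threshold from the bimodal intensity histogram
#'
#' Fits a kernel-smoothed density to all voxel intensities of a specimen
#' volume and returns the intensity at the density minimum lying between
#' its two largest modes: the left mode holds voxels outside the specimen
#' (and dropout voxels), the right mode holds tissue voxels. Voxels
#' strictly below the threshold are excluded downstream.
#'
#' @param volume a \code{\linkS4class{SpecimenVolume}} or numeric array.
#' @param bandwidth optional kernel bandwidth override (default: Silverman's
#'   rule of thumb).
#' @return the threshold intensity (scalar).
#' @section Errors:
#' If fewer than two density modes are found, an explicit "unimodal
#' histogram" error is raised rather than silently returning an extremum.
#' @export
lowSignalThreshold <- function(volume, bandwidth = NULL) {
  x <- if (is(volume, "SpecimenVolume")) as.vector(volume@data) else as.vector(volume)
  if (length(x) == 0L) stop("empty volume")
  if (length(unique(x)) < 2L)
    stop("unimodal histogram: cannot place a low-signal threshold")
  d <- .kde(x, bandwidth)
  peaks <- .localMaxima(d$y)
  if (length(peaks) < 2L)
    stop("unimodal histogram: cannot place a low-signal threshold")
  top2 <- peaks[order(d$y[peaks], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  between <- seq(lo, hi)
  ## global minimum strictly between the two modes; ties toward lower intensity
  d$x[between[which.min(d$y[between])]]
}

#' Flatten a volume to a 2D image by slice averaging
#'
#' Per in-plane position, the mean over slices of the voxels flagged valid
#' in 3D. Positions with no valid voxel in any slice are flagged invalid
#' (low-signal: outside the specimen or full-thickness dropout).
#'
#' @param volume a \code{\linkS4class{SpecimenVolume}}.
#' @param valid3d logical array of the same dimension flagging voxels that
#'   survived low-signal thresholding.
#' @return a \code{\linkS4class{CleanFlatImage}} with intensity and
#'   validity set (CNR not yet computed).
#' @export
flattenVolume <- function(volume, valid3d) {
  dat <- volume@data
  if (length(dat) == 0L) stop("empty volume")
  stopifnot(identical(dim(dat), dim(valid3d)))
  cnt <- rowSums(valid3d, dims = 2L)
  sums <- rowSums(dat * valid3d, dims = 2L)
  intensity <- ifelse(cnt > 0L, sums / pmax(cnt, 1L), NA_real_)
  validity <- matrix(.REASON[["valid"]], nrow(intensity), ncol(intensity))
  validity[cnt == 0L] <- .REASON[["low_signal"]]
  intensity[cnt == 0L] <- 0
  new("CleanFlatImage", intensity = intensity, validity = validity,
      cnr = matrix(NA_real_, nrow(intensity), ncol(intensity)),
      referenceMode = NA_real_)
}

## mode of a continuous sample = argmax of the kernel density estimate
intensityMode <- function(x, bandwidth = NULL) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- .kde(x, bandwidth)
  d$x[which.max(d$y)]
}

#' Compute per-voxel CNR against a reference region
#'
#' Sets the reference mode to the kernel-density mode of valid
#' reference-region intensities and computes
#' \code{CNR_v = (I_v - mode(I_RR)) / mode(I_RR)} for every valid voxel.
#'
#' @param flat a \code{\linkS4class{CleanFlatImage}}.
#' @param referenceMask logical matrix marking the reference region (crus
#'   cerebri white matter).
#' @param bandwidth optional kernel bandwidth override for the mode.
#' @return the image with \code{cnr} and \code{referenceMode} filled in.
#' @export
computeCNR <- function(flat, referenceMask, bandwidth = NULL) {
  stopifnot(identical(dim(referenceMask), dim(flat@intensity)))
  sel <- referenceMask & flat@validity == .REASON[["valid"]]
  if (!any(sel))
    stop("reference region is empty after cleaning")
  m <- intensityMode(flat@intensity[sel], bandwidth)
  if (m <= 0) stop("nonpositive reference mode")
  cnr <- matrix(NA_real_, nrow(flat@intensity), ncol(flat@intensity))
  ok <- flat@validity == .REASON[["valid"]]
  cnr[ok] <- (flat@intensity[ok] - m) / m
  initialize(flat, cnr = cnr, referenceMode = m)
}

#' Remove edge artifacts at the specimen boundary
#'
#' Two-step morphological edge cleaning on the flattened image:
#' \enumerate{
#'   \item boundary voxels (valid voxels 4-adjacent to an invalid voxel or
#'     the image edge) are dilated by \code{innerWidth} voxels (city-block
#'     structuring element) and removed unconditionally;
#'   \item in the band extending \code{bandWidth} further voxels beyond that
#'     border, voxels with CNR above \code{cnrCutoff} are removed --- except
#'     in grid sections flagged as containing substantia nigra, whose high
#'     CNR is signal, not artifact.
#' }
#' Both depths are measured from the original boundary. CNR for step 2 is
#' recomputed after step 1 when \code{referenceMask} is supplied (the
#' reference mode then excludes border voxels); otherwise the CNR already
#' present in \code{flat} is used.
#'
#' @param flat a \code{\linkS4class{CleanFlatImage}}.
#' @param snMask logical matrix marking voxels in SN-flagged grid sections.
#' @param referenceMask optional logical matrix; triggers provisional CNR
#'   computation after step 1.
#' @param innerWidth dilation of the boundary removed unconditionally
#'   (default 2 voxels).
#' @param bandWidth thickness of the conditional outer band (default 5).
#' @param cnrCutoff CNR above which band voxels are removed (default 0.40).
#' @param bandwidth optional kernel bandwidth override for the reference
#'   mode.
#' @return the cleaned image (validity reasons \code{border_inner} and
#'   \code{border_cnr} recorded; CNR present if computable).
#' @export
removeEdgeArtifacts <- function(flat, snMask, referenceMask = NULL,
                                innerWidth = 2L, bandWidth = 5L,
                                cnrCutoff = 0.40, bandwidth = NULL) {
  stopifnot(identical(dim(snMask), dim(flat@intensity)))
  valid <- flat@validity == .REASON[["valid"]]
  depth <- cityblockDepth(valid)
  validity <- flat@validity
  inner <- valid & depth <= (1L + innerWidth)
  validity[inner] <- .REASON[["border_inner"]]
  flat@validity <- validity
  if (!is.null(referenceMask))
    flat <- computeCNR(flat, referenceMask, bandwidth)
  band <- flat@validity == .REASON[["valid"]] &
    depth <= (1L + innerWidth + bandWidth) & !snMask
  kill <- band & !is.na(flat@cnr) & flat@cnr > cnrCutoff
  validity <- flat@validity
  validity[kill] <- .REASON[["border_cnr"]]
  cnr <- flat@cnr
  cnr[validity != .REASON[["valid"]]] <- NA_real_
  initialize(flat, validity = validity, cnr = cnr)
}

#' Cook's distance of each observation in an intercept-only regression
#'
#' For the constant-only model y = mu + e, leverage is 1/n for every
#' observation and Cook's distance reduces to
#' \code{D_i = r_i^2 / (n s^2 (1 - 1/n)^2)} with \code{s^2} the residual
#' mean square. Equivalent to the leave-one-out definition
#' \code{D_i = sum_j (yhat_j - yhat_j(i))^2 / (p s^2)}.
#'
#' @param x numeric vector.
#' @return numeric vector of Cook's distances (zeros when the sample is
#'   constant).
#' @export
cooksDistanceConstant <- function(x) {
  n <- length(x)
  ## numerically constant samples (spread at floating-point noise level)
  ## have no outliers; without this guard the distances are ratios of
  ## rounding errors
  if (diff(range(x)) <= 1e-8 * max(abs(x), 1))
    return(numeric(n))
  r <- x - mean(x)
  s2 <- sum(r^2) / (n - 1L)
  r^2 * (1 / n) / (s2 * (1 - 1 / n)^2)
}

#' Flag outlier voxels within a grid section by Cook's distance
#'
#' Voxels whose Cook's distance in a constant-only regression of CNR
#' exceeds \code{multiplier / n} are flagged, where n is the number of
#' voxels in the grid section. Sections with fewer than 3 voxels pass
#' unfiltered with a warning.
#'
#' @param values numeric vector of CNR values of one grid section.
#' @param multiplier threshold numerator (default 4, i.e. D > 4/n).
#' @return list with \code{kept} (surviving values), \code{flagged}
#'   (indices removed) and \code{cooks} (distances).
#' @export
cooksOutlierFilter <- function(values, multiplier = 4) {
  n <- length(values)
  if (n < 3L) {
    warning("fewer than 3 voxels in section; Cook's filter skipped")
    return(list(kept = values, flagged = integer(0),
                cooks = rep(NA_real_, n)))
  }
  d <- cooksDistanceConstant(values)
  flagged <- which(d > multiplier / n)
  list(kept = if (length(flagged)) values[-flagged] else values,
       flagged = flagged, cooks = d)
}

#' Run the full voxel-cleaning chain on a specimen volume
#'
#' Fixed order of operations: 3D low-signal threshold, slice flattening,
#' unconditional border removal, provisional CNR (reference mode from the
#' post-border image), conditional border-band removal, per-section Cook's
#' outlier filter, and a final CNR recomputation with the final reference
#' mode.
#'
#' @param volume a \code{\linkS4class{SpecimenVolume}}.
#' @param layout the specimen's \code{\linkS4class{GridLayout}}.
#' @param referenceMask logical matrix of reference-region voxels; defaults
#'   to the voxels of CC-labeled grid sections.
#' @param innerWidth,bandWidth,cnrCutoff edge-removal parameters (see
#'   \code{\link{removeEdgeArtifacts}}).
#' @param cooksMultiplier Cook's threshold numerator (default 4).
#' @param bandwidth optional kernel bandwidth override used by the
#'   threshold and mode estimates.
#' @return list with \code{flat} (final \code{CleanFlatImage}), \code{map}
#'   (voxel-to-section matrix), \code{threshold}, and \code{removed}
#'   (named voxel counts by removal reason).
#' @export
cleanVolume <- function(volume, layout, referenceMask = NULL,
                        innerWidth = 2L, bandWidth = 5L, cnrCutoff = 0.40,
                        cooksMultiplier = 4, bandwidth = NULL) {
  thr <- lowSignalThreshold(volume, bandwidth)
  valid3d <- volume@data >= thr
  flat <- flattenVolume(volume, valid3d)
  map <- registerGrid(flat, layout)
  sec <- layout@sections
  snIDs <- sec$section_id[sec$is_sn]
  snMask <- !is.na(map) & matrix(map %in% snIDs, nrow(map), ncol(map))
  if (is.null(referenceMask)) {
    ccIDs <- sec$section_id[sec$region == "CC"]
    referenceMask <- !is.na(map) & matrix(map %in% ccIDs, nrow(map), ncol(map))
  } else {
    ## an explicitly traced reference ROI serves normalization only:
    ## its voxels do not contribute to grid-section statistics
    map[referenceMask] <- NA_integer_
  }
  flat <- removeEdgeArtifacts(flat, snMask, referenceMask,
                              innerWidth, bandWidth, cnrCutoff, bandwidth)
  ## Cook's filter within each grid section, on provisional CNR
  validity <- flat@validity
  for (sid in sec$section_id) {
    idx <- which(!is.na(map) & map == sid &
                   validity == .REASON[["valid"]])
    if (length(idx) < 3L) next
    d <- cooksDistanceConstant(flat@cnr[idx])
    out <- idx[d > cooksMultiplier / length(idx)]
    validity[out] <- .REASON[["cooks_outlier"]]
  }
  cnr <- flat@cnr
  cnr[validity != .REASON[["valid"]]] <- NA_real_
  flat <- initialize(flat, validity = validity, cnr = cnr)
  ## final CNR with the final reference mode
  flat <- computeCNR(flat, referenceMask, bandwidth)
  counts <- table(factor(flat@validity, levels = .REASON,
                         labels = names(.REASON)))
  list(flat = flat, map = map, threshold = thr,
       removed = setNames(as.integer(counts), names(counts)))
}
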