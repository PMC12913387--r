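#' @describeIn SpecimenVolume-class intensity array accessor
#' @param object,x an object of the documented class
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @export
setMethod("volumeData", "SpecimenVolume", function(x) x@data)

#' Voxel size accessor
#' @param x a \code{SpecimenVolume}
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setMethod("voxelSize", "SpecimenVolume", function(x) x@voxelSize)

#' Section metadata accessor
#' @param x a \code{GridLayout}
#' @export
setGeneric("gridSections", function(x) standardGeneric("gridSections"))

#' @export
setMethod("gridSections", "GridLayout", function(x) x@sections)

#' Validity (removal-reason) mask accessor
#' @param x a \code{CleanFlatImage}
#' @export
setGeneric("validityMask", function(x) standardGeneric("validityMask"))

#' @export
setMethod("validityMask", "CleanFlatImage", function(x) x@validity)

#' Per-voxel CNR map accessor
#' @param x a \code{CleanFlatImage}
#' @export
setGeneric("cnrMap", function(x) standardGeneric("cnrMap"))

#' @export
setMethod("cnrMap", "CleanFlatImage", function(x) x@cnr)

#' Reference-region intensity mode accessor
#' @param x a \code{CleanFlatImage}
#' @export
setGeneric("referenceMode", function(x) standardGeneric("referenceMode"))

#' @export
setMethod("referenceMode", "CleanFlatImage", function(x) x@referenceMode)

#' Posterior draws accessor
#' @param x a \code{GroupDiffPosterior}
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @export
setMethod("posteriorDraws", "GroupDiffPosterior", function(x) x@draws)

#' Split-R-hat diagnostics accessor
#' @param x a \code{GroupDiffPosterior}
#' @export
setGeneric("rhat", function(x) standardGeneric("rhat"))

#' @export
setMethod("rhat", "GroupDiffPosterior", function(x) x@rhat)

#' @export
setMethod("coef", "MixedModelFit", function(object, ...) object@beta)

setMethod("show", "SpecimenVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpecimenVolume '%s' (%s): %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@specimenID, if (object@diagnosis == 1L) "PD" else "AD",
              d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "GridLayout", function(object) {
  s <- object@sections
  cat(sprintf("GridLayout: %d x %d grid, %.2f mm pitch (%.3g mm voxels), rotation %.1f deg\n",
              object@gridDim[1], object@gridDim[2], object@spacingMM,
              object@voxelSizeMM, object@rotation))
  cat(sprintf("  %d sections (%d valid); regions: %s\n", nrow(s), sum(s$is_valid),
              paste(sprintf("%s=%d", names(table(s$region)), table(s$region)),
                    collapse = " ")))
})

setMethod("show", "CleanFlatImage", function(object) {
  d <- dim(object@intensity)
  tab <- table(factor(object@validity, levels = .REASON,
                      labels = names(.REASON)))
  cat(sprintf("CleanFlatImage: %d x %d voxels, reference mode %s\n", d[1], d[2],
              if (is.na(object@referenceMode)) "not set"
              else format(object@referenceMode, digits = 6)))
  cat("  voxels by status:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %d AD + %d PD specimens, %d grid sections, cnrModel='%s', seed=%d\n",
              object@nSpecimensAD, object@nSpecimensPD,
              sum(object@allocation), object@cnrModel, object@seed))
})

setMethod("show", "MixedModelFit", function(object) {
  cat(sprintf("Random-intercept mixed model (%s sections, profiled ML)\n",
              object@subset))
  cat(sprintf("  n = %d sections, %d specimens; df = %d\n",
              object@nSections, object@nSpecimens, object@df))
  tab <- data.frame(estimate = object@beta, se = object@se,
                    ci_lo = object@ci95[, 1], ci_hi = object@ci95[, 2],
                    t = object@tstat, p = object@p)
  print(signif(tab, 4))
  cat(sprintf("  sigma_e = %.4g, sigma_b = %.4g (percent CNR); R2 = %.3f (corr), %.3f (1-RSS/TSS)\n",
              sqrt(object@sigma2e), sqrt(object@sigma2b),
              object@r2["corr"], object@r2["rss"]))
})

setMethod("show", "GroupDiffPosterior", function(object) {
  cat(sprintf("Bayesian group difference (PD - AD), %s / %s: %.4g [%.4g, %.4g]\n",
              object@region, object@metric, object@estimate,
              object@ci95[1], object@ci95[2]))
  cat(sprintf("  %d draws, max split-R-hat %.4f%s\n",
              length(object@draws), max(object@rhat),
              if (object@converged) "" else " (NOT converged)"))
})
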