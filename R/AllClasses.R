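#' Specimen image volume
#'
#' A 3D grayscale NM-MRI volume of one ex vivo midbrain specimen slice,
#' with voxel size and specimen metadata.
#'
#' @slot data 3D numeric array (row, column, slice) of signal intensities.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot specimenID character scalar.
#' @slot diagnosis integer, 0 = AD, 1 = PD.
#' @exportClass SpecimenVolume
setClass("SpecimenVolume",
  representation(data = "array", voxelSize = "numeric",
                 specimenID = "character", diagnosis = "integer"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive lengths (mm)")
    if (!object@diagnosis %in% c(0L, 1L)) return("diagnosis must be 0 (AD) or 1 (PD)")
    TRUE
  })

#' Grid layout of dissection sections
#'
#' Geometry mapping image voxels to 3.5 mm dissection-grid sections, plus
#' per-section region labels and flags.
#'
#' @slot origin numeric(2), grid origin in voxel units (0-based row, col).
#' @slot spacingMM section pitch in mm (3.5 for the dissection grid insert).
#' @slot voxelSizeMM in-plane voxel size in mm.
#' @slot rotation grid rotation about the origin, degrees counter-clockwise.
#' @slot wellMarkers 4 x 2 matrix of water-well marker coordinates (voxels).
#' @slot gridDim integer(2), number of section rows and columns.
#' @slot sections data.frame with one row per section: \code{section_id},
#'   \code{grid_row}, \code{grid_col} (0-based), \code{region},
#'   \code{is_sn}, \code{is_posterior}, \code{is_valid}.
#' @exportClass GridLayout
setClass("GridLayout",
  representation(origin = "numeric", spacingMM = "numeric",
                 voxelSizeMM = "numeric", rotation = "numeric",
                 wellMarkers = "matrix", gridDim = "integer",
                 sections = "data.frame"),
  validity = function(object) {
    if (object@spacingMM <= 0) return("spacingMM must be > 0")
    if (object@voxelSizeMM <= 0) return("voxelSizeMM must be > 0")
    s <- object@sections
    need <- c("section_id", "grid_row", "grid_col", "region",
              "is_sn", "is_posterior", "is_valid")
    if (!all(need %in% names(s)))
      return(paste("sections must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(s[, c("grid_row", "grid_col")]))
      return("sections must tile the grid without overlap")
    if (!all(s$region %in% .REGIONS))
      return(paste("unknown region label; expected one of:",
                   paste(.REGIONS, collapse = ", ")))
    TRUE
  })

#' Cleaned, flattened specimen image
#'
#' 2D image obtained by averaging a specimen volume over slices, with a
#' per-voxel validity mask (removal reason) and CNR values where valid.
#'
#' CNR for voxel v is defined against the mode of the reference-region (RR)
#' intensity distribution: CNR_v = (I_v - mode(I_RR)) / mode(I_RR).
#'
#' @slot intensity numeric matrix of mean in-specimen signal.
#' @slot validity integer matrix of removal reasons; 0 = valid,
#'   1 = low_signal (outside specimen or signal dropout), 2 = border_inner
#'   (perimeter + 2-voxel dilation), 3 = border_cnr (5-voxel outer band with
#'   CNR > cutoff), 4 = cooks_outlier.
#' @slot cnr numeric matrix, CNR values (fractional); NA where invalid.
#' @slot referenceMode scalar mode of valid reference-region intensities.
#' @exportClass CleanFlatImage
setClass("CleanFlatImage",
  representation(intensity = "matrix", validity = "matrix",
                 cnr = "matrix", referenceMode = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@intensity), dim(object@validity)))
      return("intensity and validity must have identical dimensions")
    if (!identical(dim(object@intensity), dim(object@cnr)))
      return("intensity and cnr must have identical dimensions")
    if (!all(object@validity %in% .REASON))
      return("validity codes must be in 0:4")
    if (!is.na(object@referenceMode) && object@referenceMode <= 0)
      return("referenceMode must be positive")
    if (any(!is.na(object@cnr) & object@validity != 0L))
      return("cnr must be NA where voxels are invalid")
    TRUE
  })

#' Phantom cohort configuration
#'
#' Parameters of the synthetic-specimen generator: cohort composition,
#' per-specimen section allocation, region x group distributions of NM-MRI
#' signal and NM/Fe concentrations, the section-CNR signal model, and image
#' rendering parameters.
#'
#' @slot nSpecimensAD,nSpecimensPD integer cohort sizes (defaults 7 and 4).
#' @slot allocation integer matrix, specimens x section classes
#'   (SN, RN, CC, SC, PAG, unassigned, posterior, invalid); row sums are the
#'   per-specimen section counts, constrained to 13--36.
#' @slot regionParams data.frame with columns \code{region}, \code{group},
#'   \code{cnr_mean}, \code{cnr_sd} (fractional NM-MRI CNR), \code{nm_mean},
#'   \code{nm_sd} (ug NM per mg wet tissue), \code{fe_mean}, \code{fe_sd}
#'   (ng Fe per mg wet tissue).
#' @slot signalCoeffs named numeric (beta0, beta1, beta2, beta3): the
#'   model-scale coefficients (percent CNR response) that phantom cohorts
#'   encode; used directly as generating coefficients when
#'   \code{cnrModel = "linear"}.
#' @slot condSlopes named numeric (gamma1, gamma2): conditional within-region
#'   slopes used when \code{cnrModel = "anchored"}; calibrated once by
#'   simulation so the marginal mixed-model slopes equal \code{beta1},
#'   \code{beta2} (see the methods vignette).
#' @slot subjectInterceptSD,residualSD noise SDs on the percent-CNR scale.
#' @slot cnrModel \code{"anchored"} (default: section CNR anchored at the
#'   region x group mean NM-MRI signal) or \code{"linear"} (pure linear
#'   model in NM, Fe and diagnosis).
#' @slot imageParams list: \code{voxel_size_mm}, \code{n_slices},
#'   \code{background}, \code{tissue}, \code{edge_amplitude},
#'   \code{dropout_prob}.
#' @slot seed integer master seed.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(nSpecimensAD = "integer", nSpecimensPD = "integer",
                 allocation = "matrix", regionParams = "data.frame",
                 signalCoeffs = "numeric", condSlopes = "numeric",
                 subjectInterceptSD = "numeric", residualSD = "numeric",
                 cnrModel = "character", imageParams = "list",
                 seed = "integer"),
  validity = function(object) {
    rp <- object@regionParams
    if (any(rp[, c("cnr_sd", "nm_sd", "fe_sd")] < 0))
      return("all SDs must be >= 0")
    ns <- rowSums(object@allocation)
    if (any(ns < 13L | ns > 36L))
      return("per-specimen section counts must lie in [13, 36]")
    if (nrow(object@allocation) != object@nSpecimensAD + object@nSpecimensPD)
      return("allocation must have one row per specimen")
    if (!all(c("beta0", "beta1", "beta2", "beta3") %in% names(object@signalCoeffs)))
      return("signalCoeffs must name beta0..beta3")
    if (!all(c("gamma1", "gamma2") %in% names(object@condSlopes)))
      return("condSlopes must name gamma1, gamma2")
    if (object@subjectInterceptSD < 0 || object@residualSD < 0)
      return("noise SDs must be >= 0")
    if (!object@cnrModel %in% c("anchored", "linear"))
      return("cnrModel must be 'anchored' or 'linear'")
    ip <- object@imageParams
    need <- c("voxel_size_mm", "n_slices", "background", "tissue",
              "edge_amplitude", "dropout_prob")
    if (!all(need %in% names(ip)))
      return(paste("imageParams must name:", paste(need, collapse = ", ")))
    if (ip$background >= ip$tissue)
      return("background level must be below tissue level")
    if (ip$dropout_prob < 0 || ip$dropout_prob > 1)
      return("dropout_prob must be in [0, 1]")
    TRUE
  })

#' Random-intercept mixed-model fit
#'
#' Fit of CNR_gs = beta0 + beta1 [NM]_gs + beta2 [Fe]_gs +
#' beta3 diagnosis_s + b0_s + eps_gs by profiled maximum likelihood, with
#' the CNR response expressed in percent.
#'
#' @slot beta named numeric(4) fixed-effect estimates.
#' @slot se,tstat,p named numeric(4) Wald statistics (two-sided p, df = n - 4).
#' @slot ci95 4 x 2 matrix of 95\% confidence limits.
#' @slot df residual degrees of freedom (n - 4).
#' @slot sigma2e,sigma2b residual and subject-intercept variance (ML).
#' @slot r2 named numeric: \code{corr} (squared correlation between
#'   fixed-effect predictions and observed CNR) and \code{rss}
#'   (1 - RSS/TSS of the fixed-effect predictions).
#' @slot nSections,nSpecimens integer sample sizes.
#' @slot subset which sections were fitted ("central_anterior"/"posterior").
#' @exportClass MixedModelFit
setClass("MixedModelFit",
  representation(beta = "numeric", se = "numeric", ci95 = "matrix",
                 tstat = "numeric", df = "integer", p = "numeric",
                 sigma2e = "numeric", sigma2b = "numeric", r2 = "numeric",
                 nSections = "integer", nSpecimens = "integer",
                 subset = "character"),
  validity = function(object) {
    if (object@df != object@nSections - 4L)
      return("df must equal nSections - 4")
    if (object@sigma2e < 0 || object@sigma2b < 0)
      return("variance components must be >= 0")
    TRUE
  })

#' Posterior of a Bayesian group difference
#'
#' Posterior draws and summaries of the AD-to-PD difference delta in
#' metric_gs = alpha + delta diagnosis_s + b0_s + eps_gs for one midbrain
#' subregion and metric.
#'
#' @slot region,metric character scalars.
#' @slot draws iterations x chains matrix of post-warmup delta draws.
#' @slot estimate posterior mean of delta.
#' @slot ci95 numeric(2), 2.5 and 97.5 posterior percentiles.
#' @slot rhat named numeric of split-R-hat per monitored parameter.
#' @slot converged TRUE when all split-R-hat < 1.01.
#' @exportClass GroupDiffPosterior
setClass("GroupDiffPosterior",
  representation(region = "character", metric = "character",
                 draws = "matrix", estimate = "numeric", ci95 = "numeric",
                 rhat = "numeric", converged = "logical"),
  validity = function(object) {
    if (length(object@ci95) != 2L) return("ci95 must have length 2")
    if (object@estimate < object@ci95[1] || object@estimate > object@ci95[2])
      return("credible interval must contain the posterior mean")
    TRUE
  })
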