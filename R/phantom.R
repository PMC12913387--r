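## truncated-at-zero normal draws (concentrations cannot be negative)
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  f0 <- pnorm(0, mean, sd)
  qnorm(f0 + runif(n) * (1 - f0), mean, sd)
}

## fixed per-specimen section layout: 4 grid rows, column-major fill from the
## posterior (left) side toward the anterior (right) side, mirroring the
## standard orientation (medial at top, anterior at right).
.FILL_ORDER <- c("posterior", "SC", "PAG", "RN", "SN", "CC", "unassigned", "invalid")

sectionLayoutTable <- function(counts) {
  regions <- rep(.FILL_ORDER, times = counts[.FILL_ORDER])
  n <- length(regions)
  nrowg <- 4L
  ncolg <- as.integer(ceiling(n / nrowg))
  idx <- seq_len(n) - 1L
  data.frame(
    section_id = seq_len(n),
    grid_row = idx %% nrowg,
    grid_col = idx %/% nrowg,
    region = ifelse(regions == "invalid", "unassigned", regions),
    is_sn = regions == "SN",
    is_posterior = regions == "posterior",
    is_valid = regions != "invalid",
    stringsAsFactors = FALSE)
}

#' Generate ground-truth NM and Fe concentrations
#'
#' Draws per-section NM and Fe concentrations from truncated-at-zero normal
#' distributions with the configured region x group means and SDs, and lays
#' each specimen out on its dissection grid.
#'
#' @param cfg a \code{\linkS4class{PhantomConfig}}.
#' @return data.frame with one row per grid section: \code{specimen_id},
#'   \code{diagnosis} (0 = AD, 1 = PD), \code{section_id}, \code{grid_row},
#'   \code{grid_col}, \code{region}, \code{is_sn}, \code{is_posterior},
#'   \code{is_valid}, \code{nm_conc} (ug/mg), \code{fe_conc} (ng/mg).
#'   Reproducible given \code{cfg@seed}.
#' @export
generateConcentrations <- function(cfg) {
  stopifnot(is(cfg, "PhantomConfig"))
  validObject(cfg)
  set.seed(stageSeed(cfg@seed, 1L))
  rp <- cfg@regionParams
  specs <- rownames(cfg@allocation)
  groups <- c(rep("AD", cfg@nSpecimensAD), rep("PD", cfg@nSpecimensPD))
  out <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    lay <- sectionLayoutTable(cfg@allocation[s, ])
    p <- rp[match(paste(lay$region, groups[s]), paste(rp$region, rp$group)), ]
    lay$nm_conc <- mapply(function(m, sdv) rtnorm0(1L, m, sdv),
                          p$nm_mean, p$nm_sd)
    lay$fe_conc <- mapply(function(m, sdv) rtnorm0(1L, m, sdv),
                          p$fe_mean, p$fe_sd)
    lay <- cbind(specimen_id = specs[s],
                 diagnosis = as.integer(groups[s] == "PD"), lay)
    out[[s]] <- lay
  }
  do.call(rbind, out)
}

#' Generate true section CNR from the signal model
#'
#' Adds the true NM-MRI contrast-to-noise ratio of every grid section to a
#' ground-truth concentration table. Under the default anchored model,
#' percent CNR is the region x group mean plus conditional NM/Fe slopes on
#' the concentration deviations, a subject intercept and residual noise;
#' under the linear model it is
#' \code{beta0 + beta1 NM + beta2 Fe + beta3 diagnosis + b0 + eps}.
#' Posterior-midbrain sections receive CNR with no NM or Fe dependence in
#' either model, reflecting the absence of a signal-concentration
#' relationship in that territory.
#'
#' @param truth output of \code{\link{generateConcentrations}}.
#' @param cfg the same \code{\linkS4class{PhantomConfig}}.
#' @return \code{truth} with added columns \code{true_cnr} (fractional CNR)
#'   and \code{subject_intercept} (percent-CNR scale).
#' @export
generateSectionCNR <- function(truth, cfg) {
  stopifnot(is(cfg, "PhantomConfig"))
  set.seed(stageSeed(cfg@seed, 2L))
  specs <- unique(truth$specimen_id)
  b0 <- setNames(rnorm(length(specs), 0, cfg@subjectInterceptSD), specs)
  eps <- rnorm(nrow(truth), 0, cfg@residualSD)
  grp <- ifelse(truth$diagnosis == 1L, "PD", "AD")
  rp <- cfg@regionParams
  p <- rp[match(paste(truth$region, grp), paste(rp$region, rp$group)), ]
  bb <- cfg@signalCoeffs
  gg <- cfg@condSlopes
  base <- if (cfg@cnrModel == "anchored") {
    ifelse(truth$is_posterior,
           100 * p$cnr_mean,
           100 * p$cnr_mean +
             gg["gamma1"] * (truth$nm_conc - p$nm_mean) +
             gg["gamma2"] * (truth$fe_conc - p$fe_mean))
  } else {
    ifelse(truth$is_posterior,
           bb["beta0"] + bb["beta3"] * truth$diagnosis,
           bb["beta0"] + bb["beta1"] * truth$nm_conc +
             bb["beta2"] * truth$fe_conc + bb["beta3"] * truth$diagnosis)
  }
  pct <- base + b0[truth$specimen_id] + eps
  truth$true_cnr <- as.numeric(pct) / 100
  truth$subject_intercept <- as.numeric(b0[truth$specimen_id])
  truth
}

## two-pass city-block (chamfer) distance to the nearest FALSE cell;
## cells beyond the matrix edge count as FALSE.
cityblockDepth <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inf <- nr + nc + 2
  d <- matrix(ifelse(mask, inf, 0), nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (d[i, j] > 0) {
      up <- if (i > 1) d[i - 1, j] else 0
      lf <- if (j > 1) d[i, j - 1] else 0
      d[i, j] <- min(d[i, j], up + 1, lf + 1)
    }
  }
  for (j in rev(seq_len(nc))) for (i in rev(seq_len(nr))) {
    if (d[i, j] > 0) {
      dn <- if (i < nr) d[i + 1, j] else 0
      rt <- if (j < nc) d[i, j + 1] else 0
      d[i, j] <- min(d[i, j], dn + 1, rt + 1)
    }
  }
  d
}

#' Render a synthetic specimen volume
#'
#' Converts the ground truth of one specimen into a 3D NM-MRI-like volume:
#' voxel intensity is \code{tissue * (1 + CNR)} inside the specimen and
#' \code{background} outside, yielding a bimodal intensity histogram.
#' Edge artifacts (a bright rim two voxels deep plus sparse bright voxels
#' at depths 3--7), random signal-dropout voxels, and four water well
#' markers at the dish rim are injected, and the exact voxel-to-section
#' mapping is returned as ground truth.
#'
#' @param truthSpec ground-truth rows of a single specimen (ordered by
#'   \code{section_id}), as produced by \code{\link{generateSectionCNR}}.
#' @param cfg a \code{\linkS4class{PhantomConfig}}.
#' @param seed integer seed for the artifact/dropout draws.
#' @return list with elements \code{volume} (\code{SpecimenVolume}),
#'   \code{layout} (\code{GridLayout}) and \code{masks} (list of ground
#'   truth masks: \code{sectionMap} voxel-to-section matrix,
#'   \code{specimen}, \code{dropout} (3D), \code{artifact}, \code{rim},
#'   \code{reference} (CC sections), \code{sn}).
#' @export
renderVolume <- function(truthSpec, cfg, seed = cfg@seed) {
  stopifnot(is(cfg, "PhantomConfig"), nrow(truthSpec) >= 1L)
  if (length(unique(truthSpec$specimen_id)) != 1L)
    stop("truthSpec must contain exactly one specimen")
  set.seed(seed)
  ip <- cfg@imageParams
  sp <- as.integer(round(3.5 / ip$voxel_size_mm))
  if (sp < 3L) stop("configuration error: grid pitch below 3 voxels")
  ns <- as.integer(ip$n_slices)
  if (ns < 1L) stop("configuration error: need at least one slice")
  margin <- 8L
  nrowg <- max(truthSpec$grid_row) + 1L
  ncolg <- max(truthSpec$grid_col) + 1L
  nrv <- nrowg * sp + 2L * margin
  ncv <- ncolg * sp + 2L * margin

  sectionMap <- matrix(NA_integer_, nrv, ncv)
  cnrImg <- matrix(NA_real_, nrv, ncv)
  refMask <- matrix(FALSE, nrv, ncv)
  mid <- (sp + 1L) %/% 2L
  patch <- if (sp >= 5L) mid + (-1L:1L) else mid
  for (k in seq_len(nrow(truthSpec))) {
    rr <- margin + truthSpec$grid_row[k] * sp + seq_len(sp)
    cc <- margin + truthSpec$grid_col[k] * sp + seq_len(sp)
    sectionMap[rr, cc] <- truthSpec$section_id[k]
    cnrImg[rr, cc] <- truthSpec$true_cnr[k]
    if (truthSpec$region[k] == "CC") {
      ## reference ROI: a traced patch of CC white matter rendered at the
      ## zero-CNR intensity (ground-truth CNR is defined relative to it);
      ## ROI voxels serve normalization only, not section statistics
      pr <- rr[patch]; pc <- cc[patch]
      refMask[pr, pc] <- TRUE
      cnrImg[pr, pc] <- 0
      sectionMap[pr, pc] <- NA_integer_
    }
  }
  specimen <- !is.na(sectionMap) | refMask
  base2d <- matrix(ip$background, nrv, ncv)
  base2d[specimen] <- ip$tissue * (1 + cnrImg[specimen])

  depth <- cityblockDepth(specimen)
  rim <- specimen & depth <= 2L
  deepCand <- specimen & depth >= 3L & depth <= 7L
  artifact <- deepCand & matrix(runif(nrv * ncv) < 0.02, nrv, ncv)
  art2d <- rim | artifact
  base2d[art2d] <- base2d[art2d] * (1 + ip$edge_amplitude)

  ## water wells at the four cardinal points of the dish rim
  wellAt <- function(r, c) cbind(r + c(0L, 1L, 0L, 1L), c + c(0L, 0L, 1L, 1L))
  wells <- rbind(wellAt(3L, ncv %/% 2L), wellAt(nrv - 4L, ncv %/% 2L),
                 wellAt(nrv %/% 2L, 3L), wellAt(nrv %/% 2L, ncv - 4L))
  base2d[wells] <- ip$tissue * 1.3

  vol <- array(rep(base2d, ns), dim = c(nrv, ncv, ns))
  dropout <- array(runif(nrv * ncv * ns) < ip$dropout_prob &
                     rep(specimen, ns), dim = dim(vol))
  nd <- sum(dropout)
  if (nd > 0) vol[dropout] <- ip$background * runif(nd, 0.5, 1.0)

  volume <- new("SpecimenVolume", data = vol,
                voxelSize = c(ip$voxel_size_mm, ip$voxel_size_mm, 0.6),
                specimenID = truthSpec$specimen_id[1],
                diagnosis = as.integer(truthSpec$diagnosis[1]))
  layout <- new("GridLayout",
                origin = c(margin, margin), spacingMM = 3.5,
                voxelSizeMM = ip$voxel_size_mm, rotation = 0,
                wellMarkers = rbind(c(3, ncv / 2), c(nrv - 4, ncv / 2),
                                    c(nrv / 2, 3), c(nrv / 2, ncv - 4)),
                gridDim = c(nrowg, ncolg),
                sections = truthSpec[, c("section_id", "grid_row", "grid_col",
                                         "region", "is_sn", "is_posterior",
                                         "is_valid")])
  snMask <- matrix(FALSE, nrv, ncv)
  snIDs <- truthSpec$section_id[truthSpec$is_sn]
  snMask[!is.na(sectionMap) & sectionMap %in% snIDs] <- TRUE
  list(volume = volume, layout = layout,
       masks = list(sectionMap = sectionMap, specimen = specimen,
                    dropout = dropout, artifact = artifact, rim = rim,
                    reference = refMask, sn = snMask))
}

#' Generate a full synthetic cohort
#'
#' Runs \code{\link{generateConcentrations}},
#' \code{\link{generateSectionCNR}} and \code{\link{renderVolume}} for every
#' specimen under per-stage seeds derived from the master seed, so each
#' stage is reproducible in isolation.
#'
#' @param cfg a \code{\linkS4class{PhantomConfig}}.
#' @param render if FALSE, skip image rendering and return only the
#'   ground-truth table (fast path for statistical simulations).
#' @return list with \code{truth} (ground-truth table), \code{specimens}
#'   (per-specimen render output, or NULL) and \code{config}.
#' @export
generateCohort <- function(cfg = phantomConfig(), render = TRUE) {
  truth <- generateConcentrations(cfg)
  truth <- generateSectionCNR(truth, cfg)
  specimens <- NULL
  if (render) {
    ids <- unique(truth$specimen_id)
    specimens <- lapply(seq_along(ids), function(s) {
      renderVolume(truth[truth$specimen_id == ids[s], ], cfg,
                   seed = stageSeed(cfg@seed, 10L + s))
    })
    names(specimens) <- ids
  }
  list(truth = truth, specimens = specimens, config = cfg)
}
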