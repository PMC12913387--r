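#' Build a pipeline run configuration
#'
#' Assembles and validates the configuration for a full phantom-to-fit run.
#' Cleaning defaults match the published processing chain exactly: border
#' widths 2 and 5 voxels, border CNR cutoff 0.40, SN-voxel CNR threshold
#' 0.10, Cook's multiplier 4. Any override of those values is echoed to the
#' log.
#'
#' @param phantom a \code{\linkS4class{PhantomConfig}} (or NULL for
#'   defaults).
#' @param cleaning named list of overrides: \code{innerWidth},
#'   \code{bandWidth}, \code{cnrCutoff}, \code{snCnrThreshold},
#'   \code{cooksMultiplier}, \code{bandwidth}.
#' @param model named list: \code{chains}, \code{iter}, \code{warmup},
#'   \code{regions}, \code{metrics}.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param file optional YAML or JSON file to read the configuration from
#'   (fields as above; explicit arguments win).
#' @return a validated configuration list of class \code{"nmgridRunConfig"}.
#' @export
runConfig <- function(phantom = NULL, cleaning = list(), model = list(),
                      seed = 1L, file = NULL) {
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    obj <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(file)
    } else jsonlite::read_json(file, simplifyVector = TRUE)
    cleaning <- utils::modifyList(obj$cleaning %||% list(), cleaning)
    model <- utils::modifyList(obj$model %||% list(), model)
    if (is.null(phantom) && !is.null(obj$phantom))
      phantom <- do.call(phantomConfig, obj$phantom)
    if (!is.null(obj$seed) && missing(seed)) seed <- obj$seed
  }
  cl <- list(innerWidth = 2L, bandWidth = 5L, cnrCutoff = 0.40,
             snCnrThreshold = 0.10, cooksMultiplier = 4, bandwidth = NULL)
  overridden <- intersect(names(cleaning), names(cl))
  cl[names(cleaning)] <- cleaning
  for (nm in overridden)
    message("cleaning override: ", nm, " = ", format(cl[[nm]]))
  md <- list(chains = 4L, iter = 3000L, warmup = 1000L,
             regions = c("SN", "RN", "CC", "SC", "PAG"),
             metrics = c("nm_mri", "nm_conc", "fe_conc"))
  md[names(model)] <- model
  if (is.null(phantom)) phantom <- phantomConfig(seed = stageSeed(seed, 0L))
  stopifnot(cl$cnrCutoff > 0, cl$snCnrThreshold > 0, cl$cooksMultiplier > 0,
            cl$innerWidth >= 0, cl$bandWidth >= 0)
  structure(list(phantom = phantom, cleaning = cl, model = md,
                 seed = as.integer(seed)), class = "nmgridRunConfig")
}

.stageRun <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full phantom-to-fit pipeline
#'
#' Orchestrates phantom generation, voxel cleaning, grid aggregation and
#' both statistical models as one reproducible run. When \code{outDir} is
#' given, all artifacts (section table, fit summaries, removal-count log,
#' manifest with MD5 checksums) are written there; identical configuration
#' and seed give byte-identical CSV/JSON outputs. A failing stage aborts
#' with the stage named; artifacts of completed stages are preserved.
#'
#' @param cfg a configuration from \code{\link{runConfig}}.
#' @param outDir optional output directory.
#' @param groupDiff fit the Bayesian group-difference models (slowest
#'   stage; default TRUE).
#' @return list with \code{sections} (combined section table),
#'   \code{mixedCentral} and \code{mixedPosterior}
#'   (\code{\linkS4class{MixedModelFit}}), \code{groupDiffs} (summary
#'   data.frame or NULL), \code{removalLog} (per-specimen voxel-removal
#'   counts by reason) and \code{manifest} (when written).
#' @examples
#' \donttest{
#' res <- runPipeline(runConfig(seed = 1), groupDiff = FALSE)
#' res$mixedCentral
#' }
#' @export
runPipeline <- function(cfg = runConfig(), outDir = NULL, groupDiff = TRUE) {
  stopifnot(inherits(cfg, "nmgridRunConfig"))
  cl <- cfg$cleaning
  cohort <- .stageRun("phantom", generateCohort(cfg$phantom))
  removalLog <- list()
  tabs <- list()
  for (id in names(cohort$specimens)) {
    sp <- cohort$specimens[[id]]
    res <- .stageRun(paste0("clean:", id), cleanVolume(
      sp$volume, sp$layout, referenceMask = sp$masks$reference,
      innerWidth = cl$innerWidth, bandWidth = cl$bandWidth,
      cnrCutoff = cl$cnrCutoff, cooksMultiplier = cl$cooksMultiplier,
      bandwidth = cl$bandwidth))
    removalLog[[id]] <- res$removed
    tabs[[id]] <- .stageRun(paste0("aggregate:", id), aggregateSections(
      res$flat, res$map, sp$layout,
      cohort$truth[cohort$truth$specimen_id == id, ],
      snCnrThreshold = cl$snCnrThreshold))
  }
  sections <- do.call(rbind, tabs)
  rownames(sections) <- NULL
  mixedCentral <- .stageRun("fit:mixed-central",
                            fitMixedModel(sections, "central_anterior"))
  mixedPosterior <- .stageRun("fit:mixed-posterior",
                              fitMixedModel(sections, "posterior"))
  groupDiffs <- NULL
  if (groupDiff) {
    md <- cfg$model
    groupDiffs <- .stageRun("fit:group-differences", groupDifferenceTable(
      sections, regions = md$regions, metrics = md$metrics,
      seed = stageSeed(cfg$seed, 3L), chains = md$chains, iter = md$iter,
      warmup = md$warmup))
  }
  out <- list(sections = sections, mixedCentral = mixedCentral,
              mixedPosterior = mixedPosterior, groupDiffs = groupDiffs,
              removalLog = removalLog, manifest = NULL)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSectionTable(sections, file.path(outDir, "sections.csv"))
    mixedJSON <- function(f) list(
      subset = f@subset, beta = as.list(f@beta), se = as.list(f@se),
      ci95 = f@ci95, t = as.list(f@tstat), df = f@df, p = as.list(f@p),
      sigma2e = f@sigma2e, sigma2b = f@sigma2b, r2 = as.list(f@r2),
      n_sections = f@nSections, n_specimens = f@nSpecimens)
    jsonlite::write_json(list(central_anterior = mixedJSON(mixedCentral),
                              posterior = mixedJSON(mixedPosterior)),
                         file.path(outDir, "mixed_model.json"),
                         digits = NA, auto_unbox = TRUE)
    if (!is.null(groupDiffs))
      write.csv(groupDiffs, file.path(outDir, "group_differences.csv"),
                row.names = FALSE)
    jsonlite::write_json(removalLog, file.path(outDir, "removal_log.json"),
                         auto_unbox = TRUE)
    files <- setdiff(list.files(outDir, full.names = TRUE),
                     file.path(outDir, "manifest.json"))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         digits = NA)
    out$manifest <- manifest
  }
  out
}

#' Plain-text report of the group-difference table
#'
#' Formats the output of \code{\link{groupDifferenceTable}} as a
#' human-readable region x metric table with group means, the posterior
#' difference and credible interval, and a significance marker when the
#' 95\% interval excludes zero.
#'
#' @param tab data.frame from \code{\link{groupDifferenceTable}}.
#' @return character vector of report lines.
#' @export
formatGroupDifferenceReport <- function(tab) {
  lines <- c(sprintf("%-6s %-8s %4s %10s %10s %12s %22s",
                     "region", "metric", "n", "AD mean", "PD mean",
                     "difference", "95% CrI"))
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf(
      "%-6s %-8s %4d %10.4g %10.4g %11.4g%s %22s",
      tab$region[i], tab$metric[i], tab$n[i], tab$mean_ad[i],
      tab$mean_pd[i], tab$difference[i],
      if (tab$significant[i]) "*" else " ",
      sprintf("(%.4g to %.4g)", tab$ci_lo[i], tab$ci_hi[i])))
  }
  lines
}
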