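## Pipeline orchestration: validated config -> simulate -> mask ->
## preprocess -> sub-band analysis -> classification -> report.

.configDefaults <- function() list(
  tissues = c("kidney", "liver"),
  preparations = c("FF", "FFPE"),
  n_rois = 8L,
  roi_shape = c(96L, 96L),
  seed = 42L,
  noise_sd = 0.0015,
  amplitude_jitter = 0.10,
  mask_band = 1608,
  window = 13L,
  polyorder = 2L,
  trim_per_side = 13L,
  sigma_multiplier = 3,
  tolerance = 2,
  window_halfwidth = 8,
  band_table = NULL,          # path to CSV (label, center); default Table
  n_classification = 2000L,   # sampled pixels per ROI
  n_occurrence = 100L,        # occurrence subset per ROI
  n_umap = 5000L,             # UMAP sample per sample type
  pca_components = 20L,
  umap_neighbors = 15L,
  umap_min_dist = 0.1,
  umap_epochs = 200L,
  top_n = 40L,
  write_cubes = FALSE,
  out_dir = NULL
)

.configChecks <- list(
  n_rois = function(v) v >= 1,
  roi_shape = function(v) length(v) == 2 && all(v >= 8),
  noise_sd = function(v) v >= 0,
  amplitude_jitter = function(v) v >= 0,
  window = function(v) v %% 2 == 1 && v >= 5,
  polyorder = function(v) v >= 2,
  trim_per_side = function(v) v >= 0,
  sigma_multiplier = function(v) v > 0,
  tolerance = function(v) v > 0,
  window_halfwidth = function(v) v > 0,
  n_classification = function(v) v >= 1,
  n_occurrence = function(v) v >= 1,
  n_umap = function(v) v >= 10,
  pca_components = function(v) v >= 2,
  umap_neighbors = function(v) v >= 2,
  umap_min_dist = function(v) v > 0,
  umap_epochs = function(v) v >= 10,
  top_n = function(v) v >= 1
)

#' Default pipeline configuration
#'
#' All defaults are the workflow's standard parameter values
#' (window 13, polynomial order 2, 26 trimmed points, 3-sigma rule,
#' +/-2 cm^-1 tolerance, 2000 classification / 100 occurrence pixels per
#' ROI, 5000 UMAP spectra per sample type, top 40 wavenumbers, 8 ROIs).
#'
#' @return named list of parameters accepted by [runPipeline()]
#' @export
defaultConfig <- function() .configDefaults()

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) config file, or takes a named list, merges it
#' over the defaults and validates it. Unknown keys are rejected and all
#' schema violations are reported together, not first-only.
#'
#' @param config path to a YAML/JSON file, a named list, or `NULL`/empty
#'   for all defaults
#' @return the fully-defaulted, validated config list
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a file path or a named list")
  defaults <- .configDefaults()
  errs <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown config key(s): ",
                           paste(unknown, collapse = ", ")))
  merged <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  for (key in names(.configChecks)) {
    v <- merged[[key]]
    ok <- tryCatch(isTRUE(.configChecks[[key]](v)), error = function(e) FALSE)
    if (!ok) errs <- c(errs, sprintf("invalid value for '%s': %s", key,
                                     paste(format(v), collapse = " ")))
  }
  if (!is.null(merged$band_table) && !file.exists(merged$band_table))
    errs <- c(errs, paste0("band table file not found: ", merged$band_table))
  if (length(errs))
    stop("config validation failed:\n  - ", paste(errs, collapse = "\n  - "))
  intKeys <- c("n_rois", "window", "polyorder", "trim_per_side",
               "n_classification", "n_occurrence", "n_umap",
               "pca_components", "umap_neighbors", "umap_epochs", "top_n",
               "seed")
  for (k in intKeys) merged[[k]] <- as.integer(merged[[k]])
  merged$roi_shape <- as.integer(merged$roi_shape)
  merged
}

# deterministic per-stage/ROI seed fan-out from the master seed
stageSeed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + index) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> mask -> preprocess -> sub-band analysis ->
#' classification on synthetic phantoms and writes tidy CSV outputs plus a
#' JSON run report. Identical config and seed give identical outputs.
#'
#' Stages: phantom study generation; per-ROI Otsu masking at the configured
#' wavenumber and background sigma; per-ROI pixel sampling, rubberband
#' correction, Savitzky-Golay second derivatives; 3-sigma dip detection,
#' occurrence counts on the per-ROI occurrence subset, composite-Simpson
#' band integrals of the per-ROI mean second derivative and FF-vs-FFPE
#' percent reductions; ROI correlation matrix, Z-score/PCA/UMAP embedding,
#' silhouette separation and per-tissue logistic wavenumber rankings.
#'
#' @param config a validated config from [validateConfig()] (a list or path
#'   is accepted and validated first)
#' @param outDir output directory (overrides `config$out_dir`)
#' @return invisibly, the run report list: output paths, parameter echo,
#'   package version, wall time and collected warnings
#' @export
runPipeline <- function(config = NULL, outDir = NULL) {
  cfg <- if (is.list(config) && !is.null(config$..validated))
    config else validateConfig(config)
  cfg$..validated <- TRUE
  outDir <- outDir %||% cfg$out_dir %||% stop("no output directory given")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  t0 <- Sys.time()
  warnings <- character(0)
  noteWarning <- function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- "simulate"
  report <- withCallingHandlers(tryCatch({
    ## simulate ---------------------------------------------------------
    study <- generateStudy(tissues = cfg$tissues,
                           preparations = cfg$preparations,
                           nRois = cfg$n_rois, roiShape = cfg$roi_shape,
                           noiseSd = cfg$noise_sd,
                           amplitudeJitter = cfg$amplitude_jitter,
                           seed = stageSeed(cfg$seed, "simulate"),
                           outDir = if (cfg$write_cubes)
                             file.path(outDir, "cubes") else NULL)
    bands <- if (is.null(cfg$band_table)) referenceBands()
             else utils::read.csv(cfg$band_table, stringsAsFactors = FALSE)

    ## mask + preprocess ------------------------------------------------
    stage <- "mask/preprocess"
    rois <- list()
    for (roiId in names(study$cubes)) {
      cube <- study$cubes[[roiId]]
      mask <- makeTissueMask(cube, bandWn = cfg$mask_band)
      bg <- computeBackground(cube, mask, window = cfg$window,
                              polyorder = cfg$polyorder,
                              trimPerSide = cfg$trim_per_side)
      idx <- match(roiId, names(study$cubes))
      pset <- samplePixels(cube, mask, n = cfg$n_classification,
                           seed = stageSeed(cfg$seed, "sample", idx))
      corr <- rubberbandBaseline(pset)
      d2 <- savgolSecondDerivative(corr, window = cfg$window,
                                   polyorder = cfg$polyorder,
                                   trimPerSide = cfg$trim_per_side)
      rois[[roiId]] <- list(meta = cubeMeta(cube), mask = mask, bg = bg,
                            pset = corr, d2 = d2)
    }
    axisT <- spectralAxis(rois[[1L]]$d2)

    ## sub-band analysis -------------------------------------------------
    stage <- "subband"
    wins <- withCallingHandlers(
      bandWindows(bands, axisT, halfWidth = cfg$window_halfwidth),
      warning = noteWarning)
    occRows <- list(); intRows <- list()
    for (roiId in names(rois)) {
      r <- rois[[roiId]]
      sType <- paste(r$meta$tissue, r$meta$preparation, sep = "_")
      d2v <- derivValues(r$d2)
      nOcc <- min(cfg$n_occurrence, nrow(d2v))
      idx <- match(roiId, names(rois))
      occSel <- withSeed(stageSeed(cfg$seed, "occurrence", idx),
                         sample(nrow(d2v), nOcc))
      calls <- lapply(occSel, function(i)
        detectSignificantDips(d2v[i, ], axisT, sigma = backgroundSigma(r$bg),
                              nsigma = cfg$sigma_multiplier))
      occ <- withCallingHandlers(
        occurrenceCounts(calls, bands, tolerance = cfg$tolerance,
                         step = axisStep(axisT)),
        warning = noteWarning)
      occ$sample_type <- sType; occ$roi_id <- roiId
      occRows[[roiId]] <- occ
      meanD2 <- colMeans(d2v)
      ints <- vapply(seq_len(nrow(wins)), function(b)
        integrateBand(meanD2, wins[b, ], axisT), numeric(1))
      intRows[[roiId]] <- data.frame(sample_type = sType, roi_id = roiId,
                                     band_label = wins$label,
                                     integral = ints,
                                     stringsAsFactors = FALSE)
    }
    occurrence <- do.call(rbind, occRows)
    integrals <- do.call(rbind, intRows)
    summaries <- summarizeBands(occurrence, integrals)

    ## percent reductions -------------------------------------------------
    redRows <- list()
    if (all(c("FF", "FFPE") %in% cfg$preparations)) {
      for (ti in cfg$tissues) for (bl in wins$label) {
        iff <- integrals$integral[integrals$sample_type == paste0(ti, "_FF") &
                                  integrals$band_label == bl]
        ipe <- integrals$integral[integrals$sample_type == paste0(ti, "_FFPE") &
                                  integrals$band_label == bl]
        if (!length(iff) || !length(ipe) || mean(iff) <= 0) next
        redRows[[paste(ti, bl)]] <- data.frame(
          tissue = ti, band_label = bl,
          reduction_pct = percentReduction(mean(iff), mean(ipe)),
          stringsAsFactors = FALSE)
      }
    }
    reductions <- if (length(redRows)) do.call(rbind, redRows) else
      data.frame(tissue = character(0), band_label = character(0),
                 reduction_pct = numeric(0))

    ## classification -----------------------------------------------------
    stage <- "classify"
    roiMeans <- t(vapply(rois, function(r) colMeans(pixelSpectra(r$pset)),
                         numeric(ncol(pixelSpectra(rois[[1L]]$pset)))))
    corrMat <- roiCorrelationMatrix(roiMeans)

    sampleTypes <- vapply(rois, function(r)
      paste(r$meta$tissue, r$meta$preparation, sep = "_"), character(1))
    byType <- split(names(rois), sampleTypes)
    pick <- list()
    for (st in names(byType)) {
      specs <- do.call(rbind, lapply(byType[[st]], function(id)
        pixelSpectra(rois[[id]]$pset)))
      nU <- min(cfg$n_umap, nrow(specs))
      sel <- withSeed(stageSeed(cfg$seed, "umap", match(st, names(byType))),
                      sample(nrow(specs), nU))
      meta0 <- rois[[byType[[st]][1L]]]$meta
      pick[[st]] <- list(spectra = specs[sel, , drop = FALSE],
                         tissue = meta0$tissue,
                         preparation = meta0$preparation)
    }
    xAll <- do.call(rbind, lapply(pick, `[[`, "spectra"))
    labAll <- data.frame(
      tissue = rep(vapply(pick, `[[`, character(1), "tissue"),
                   vapply(pick, function(p) nrow(p$spectra), integer(1))),
      preparation = rep(vapply(pick, `[[`, character(1), "preparation"),
                        vapply(pick, function(p) nrow(p$spectra), integer(1))),
      stringsAsFactors = FALSE)
    z <- zscoreNormalize(xAll)
    colnames(z) <- wavenumbers(spectralAxis(rois[[1L]]$pset))
    pca <- withCallingHandlers(pcaReduce(z, cfg$pca_components),
                               warning = noteWarning)
    emb <- umapEmbed(pca$scores, nNeighbors = cfg$umap_neighbors,
                     minDist = cfg$umap_min_dist,
                     seed = stageSeed(cfg$seed, "umap_layout"),
                     nEpochs = cfg$umap_epochs, labels = labAll)
    sepLab <- paste(labAll$tissue, labAll$preparation, sep = "_")
    separation <- if (length(unique(sepLab)) >= 2L)
      clusterSeparationMetrics(emb, sepLab) else NULL

    rankings <- list()
    if (all(c("FF", "FFPE") %in% cfg$preparations)) {
      for (ti in cfg$tissues) {
        sel <- labAll$tissue == ti
        if (length(unique(labAll$preparation[sel])) < 2L) next
        rankings[[ti]] <- withCallingHandlers(
          logisticFeatureImportance(z[sel, , drop = FALSE],
                                    labAll$preparation[sel],
                                    topN = cfg$top_n),
          warning = noteWarning)
      }
    }

    ## report --------------------------------------------------------------
    stage <- "report"
    paths <- c(
      occurrence = file.path(outDir, "occurrence.csv"),
      integrals = file.path(outDir, "integrals.csv"),
      integral_summary = file.path(outDir, "integral_summary.csv"),
      occurrence_summary = file.path(outDir, "occurrence_summary.csv"),
      reductions = file.path(outDir, "reductions.csv"),
      correlation = file.path(outDir, "correlation.csv"),
      embedding = file.path(outDir, "embedding.csv"))
    utils::write.csv(occurrence, paths["occurrence"], row.names = FALSE)
    utils::write.csv(integrals, paths["integrals"], row.names = FALSE)
    utils::write.csv(summaries$integralSummary, paths["integral_summary"],
                     row.names = FALSE)
    utils::write.csv(summaries$occurrenceSummary, paths["occurrence_summary"],
                     row.names = FALSE)
    utils::write.csv(reductions, paths["reductions"], row.names = FALSE)
    utils::write.csv(as.data.frame(corrMat), paths["correlation"],
                     row.names = TRUE)
    utils::write.csv(emb, paths["embedding"], row.names = FALSE)
    if (!is.null(separation)) {
      paths["separation"] <- file.path(outDir, "separation.csv")
      utils::write.csv(separation, paths["separation"], row.names = FALSE)
    }
    for (ti in names(rankings)) {
      p <- file.path(outDir, sprintf("ranking_%s.csv", ti))
      paths[paste0("ranking_", ti)] <- p
      utils::write.csv(rankings[[ti]], p, row.names = FALSE)
    }
    cfgEcho <- cfg; cfgEcho$..validated <- NULL
    rep <- list(paths = as.list(paths), parameters = cfgEcho,
                package_version = as.character(utils::packageVersion("mirsiprep")),
                wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                warnings = warnings)
    jsonlite::write_json(rep, file.path(outDir, "run.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep$tables <- list(occurrence = occurrence, integrals = integrals,
                       reductions = reductions, correlation = corrMat,
                       embedding = emb, separation = separation,
                       rankings = rankings, summaries = summaries)
    rep
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }), warning = noteWarning)
  invisible(report)
}
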