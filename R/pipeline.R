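#' @include synthetic.R
#' @include evaluate.R
#' @include texture.R
#' @include maps.R
NULL

#' Read and validate a run configuration
#'
#' Run configurations are YAML or JSON files; every field has a default,
#' so an empty file is a valid (if minimal) configuration. Unknown fields
#' are rejected to catch typos. The fully resolved configuration is
#' serialized into the output directory by every stage for
#' reproducibility.
#'
#' @param path YAML/JSON file path, or `NULL` for the defaults.
#' @return Named list with elements `out` (output directory), `seed`,
#'   `scene` (generator parameters), `segmentation`, `preprocess`,
#'   `spa`, `texture`, `fusion`, `model`, `cv`, `split`, `map`.
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(
    out = "hsifuse_out",
    seed = 1L,
    scene = list(nClasses = 3L, slicesPerClass = 4L, nScenes = 5L,
                 signalSplit = "both", vnirShape = c(160L, 120L)),
    segmentation = list(minAreaPx = 60L, connectivity = 8L,
                        method = "otsu"),
    preprocess = list(method = "d2", sgWindow = 17L, sgPolyorder = 3L),
    spa = list(nMin = 2L, nMax = 10L, folds = 5L),
    texture = list(L = 16L, distance = 1L),
    fusion = list(dimension = "all"),
    model = list(type = "plsda", nLatent = 5L),
    cv = list(times = 10L, folds = 5L),
    split = list(trainFrac = 2 / 3),
    map = list(block = c(4L, 4L))
  )
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                             simplifyVector = TRUE)
            else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  if (!cfg$model$type %in% c("plsda", "svm"))
    stop("model type must be plsda or svm")
  if (!cfg$scene$signalSplit %in% c("both", "spectral_only", "texture_only"))
    stop("invalid signalSplit")
  cfg
}

.stateFile <- function(cfg) file.path(cfg$out, "state.rds")

.loadState <- function(cfg, need, neededBy) {
  f <- .stateFile(cfg)
  state <- if (file.exists(f)) readRDS(f) else list()
  miss <- setdiff(need, names(state))
  if (length(miss))
    stop("missing upstream artifact(s) ", paste(miss, collapse = ", "),
         "; run stage '", neededBy, "' first")
  state
}

.saveState <- function(cfg, state) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  saveRDS(state, .stateFile(cfg), compress = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out, "run_config.yaml"))
}

.log <- function(cfg, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(cfg$out, "run.log"),
      append = TRUE)
}

#' Run one pipeline stage
#'
#' Stages (in workflow order): `simulate`, `calibrate`, `segment`,
#' `spectra`, `select-bands`, `textures`, `fuse`, `train`, `evaluate`,
#' `map`, and the consolidated experiment `grid`. Each stage reads its
#' upstream artifacts from the configuration's output directory, writes
#' its own artifacts there (plus the resolved configuration and a
#' timestamped log), and is deterministic given the configuration and
#' seed. A missing upstream artifact raises an error naming the stage to
#' run first.
#'
#' @param stage stage name, see Details.
#' @param config a configuration list from [readRunConfig()].
#' @return The stage's main artifact, invisibly.
#' @export
runStage <- function(stage, config = readRunConfig()) {
  cfg <- config
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
    simulate = .stageSimulate(cfg),
    calibrate = .stageCalibrate(cfg),
    segment = .stageSegment(cfg),
    spectra = .stageSpectra(cfg),
    "select-bands" = .stageSelectBands(cfg),
    textures = .stageTextures(cfg),
    fuse = .stageFuse(cfg),
    train = .stageTrain(cfg),
    evaluate = .stageEvaluate(cfg),
    map = .stageMap(cfg),
    grid = .stageGrid(cfg),
    stop("unknown stage '", stage, "'"))
}

.sceneConfigFromRun <- function(cfg) {
  sceneConfig(nClasses = cfg$scene$nClasses,
              slicesPerClass = cfg$scene$slicesPerClass,
              vnirShape = cfg$scene$vnirShape,
              signalSplit = cfg$scene$signalSplit,
              seed = cfg$seed)
}

.stageSimulate <- function(cfg) {
  state <- list()
  scenes <- lapply(seq_len(cfg$scene$nScenes), function(i) {
    sc <- .sceneConfigFromRun(cfg)
    sc@seed <- as.integer(cfg$seed + i - 1L)
    generateScene(sc)
  })
  state$scenes <- scenes
  manifest <- do.call(rbind, lapply(seq_along(scenes), function(i)
    data.frame(scene = i,
               slice = seq_along(scenes[[i]]$truth@sliceLabels),
               class = scenes[[i]]$truth@sliceLabels)))
  utils::write.csv(manifest, file.path(cfg$out, "labels.csv"),
                   row.names = FALSE)
  .saveState(cfg, state)
  .log(cfg, "simulate: ", length(scenes), " scenes, ",
       nrow(manifest), " slices")
  invisible(state$scenes)
}

.stageCalibrate <- function(cfg) {
  state <- .loadState(cfg, "scenes", "simulate")
  state$calibrated <- lapply(state$scenes, function(s)
    list(vnir = calibrateReflectance(s$vnir, s$vnirRefs),
         swir = calibrateReflectance(s$swir, s$swirRefs)))
  .saveState(cfg, state)
  .log(cfg, "calibrate: ", length(state$calibrated), " scenes")
  invisible(state$calibrated)
}

.stageSegment <- function(cfg) {
  state <- .loadState(cfg, c("scenes", "calibrated"), "calibrate")
  state$rois <- lapply(seq_along(state$calibrated), function(i) {
    cal <- state$calibrated[[i]]
    sc <- state$scenes[[i]]
    v <- segmentSlices(cal$vnir, minAreaPx = cfg$segmentation$minAreaPx,
                       connectivity = cfg$segmentation$connectivity)
    s <- segmentSlices(cal$swir, minAreaPx = cfg$segmentation$minAreaPx,
                       connectivity = cfg$segmentation$connectivity)
    list(vnir = .alignToTruth(v, sc$sliceIndexVNIR),
         swir = .alignToTruth(s, sc$sliceIndexSWIR))
  })
  rtab <- do.call(rbind, lapply(seq_along(state$rois), function(i)
    cbind(scene = i, range = rep(c("VNIR", "SWIR"),
                                 times = c(length(state$rois[[i]]$vnir),
                                           length(state$rois[[i]]$swir))),
          rbind(roiTable(state$rois[[i]]$vnir),
                roiTable(state$rois[[i]]$swir)))))
  utils::write.csv(rtab, file.path(cfg$out, "rois.csv"), row.names = FALSE)
  .saveState(cfg, state)
  .log(cfg, "segment: ", nrow(rtab), " ROIs")
  invisible(state$rois)
}

.stageSpectra <- function(cfg) {
  state <- .loadState(cfg, c("scenes", "calibrated", "rois"), "segment")
  pp <- preprocessSpec(cfg$preprocess$method,
                       sgWindow = cfg$preprocess$sgWindow,
                       sgPolyorder = cfg$preprocess$sgPolyorder)
  collect <- function(range) {
    vals <- do.call(rbind, lapply(seq_along(state$calibrated), function(i)
      featureValues(extractSpectra(state$calibrated[[i]][[range]],
                                   state$rois[[i]][[range]]))))
    wl <- wavelengths(state$calibrated[[1L]][[range]])
    spectrumTable(vals, wl,
                  sampleIds = paste0("s", seq_len(nrow(vals))),
                  labels = factor(unlist(lapply(state$scenes, function(s)
                    s$truth@sliceLabels))))
  }
  state$spectraRaw <- list(vnir = collect("vnir"), swir = collect("swir"))
  state$spectra <- lapply(state$spectraRaw, preprocessSpectra, spec = pp)
  for (r in names(state$spectra)) {
    tab <- state$spectra[[r]]
    utils::write.csv(
      data.frame(sample = tab@sampleIds, class = tab@labels,
                 tab@values, check.names = FALSE),
      file.path(cfg$out, paste0("spectra_", r, ".csv")),
      row.names = FALSE)
  }
  .saveState(cfg, state)
  .log(cfg, "spectra: ", nrow(state$spectra$vnir@values), " samples, ",
       "preprocess = ", cfg$preprocess$method)
  invisible(state$spectra)
}

.stageSelectBands <- function(cfg) {
  state <- .loadState(cfg, c("spectra"), "spectra")
  split <- stratifiedSplit(state$spectra$vnir@labels,
                           trainFrac = cfg$split$trainFrac,
                           seed = cfg$seed)
  state$split <- split
  state$spa <- lapply(state$spectra, function(tab)
    spaSelect(tab@values[split$train, , drop = FALSE],
              tab@labels[split$train],
              nMin = cfg$spa$nMin, nMax = cfg$spa$nMax,
              folds = cfg$spa$folds, seed = cfg$seed,
              wavelengths = tab@wavelengths))
  for (r in names(state$spa)) {
    sel <- state$spa[[r]]
    utils::write.csv(data.frame(band_index = sel@bandIndices,
                                wavelength_nm = sel@wavelengthsNm),
                     file.path(cfg$out, paste0("spa_bands_", r, ".csv")),
                     row.names = FALSE)
  }
  .saveState(cfg, state)
  .log(cfg, "select-bands: ", length(state$spa$vnir@bandIndices), " VNIR + ",
       length(state$spa$swir@bandIndices), " SWIR bands")
  invisible(state$spa)
}

.stageTextures <- function(cfg) {
  state <- .loadState(cfg, c("calibrated", "rois", "spa"), "select-bands")
  collect <- function(range, method) {
    sel <- state$spa[[range]]
    vals <- do.call(rbind, lapply(seq_along(state$calibrated), function(i)
      featureValues(textureTable(state$calibrated[[i]][[range]],
                                 state$rois[[i]][[range]], sel,
                                 method = method, L = cfg$texture$L,
                                 distance = cfg$texture$distance))))
    vals
  }
  state$textures <- list(
    vnir = list(GLCM = collect("vnir", "GLCM"),
                GLRLM = collect("vnir", "GLRLM")),
    swir = list(GLCM = collect("swir", "GLCM"),
                GLRLM = collect("swir", "GLRLM")))
  .saveState(cfg, state)
  .log(cfg, "textures: GLCM ", ncol(state$textures$vnir$GLCM), "+",
       ncol(state$textures$swir$GLCM), " cols, GLRLM ",
       ncol(state$textures$vnir$GLRLM), "+",
       ncol(state$textures$swir$GLRLM), " cols")
  invisible(state$textures)
}

# Assemble the requested feature blocks; band = "full" or "spa",
# features in {"spectra", "GLCM", "GLRLM", "spec+tex"},
# ranges subset of c("vnir", "swir").
.gridBlocks <- function(state, ranges, features, band) {
  ids <- state$spectra$vnir@sampleIds
  blocks <- list()
  for (r in ranges) {
    tag <- toupper(r)
    if (features %in% c("spectra", "spec+tex")) {
      tab <- state$spectra[[r]]
      vals <- tab@values
      if (band == "spa")
        vals <- vals[, state$spa[[r]]@bandIndices, drop = FALSE]
      blocks <- c(blocks, list(featureBlock(
        vals, paste0(tag, "_spec"), sampleIds = ids)))
    }
    if (features %in% c("GLCM", "GLRLM")) {
      blocks <- c(blocks, list(featureBlock(
        state$textures[[r]][[features]], paste0(tag, "_tex"),
        sampleIds = ids)))
    }
    if (features == "spec+tex") {
      blocks <- c(blocks, list(featureBlock(
        state$textures[[r]][["GLRLM"]], paste0(tag, "_tex"),
        sampleIds = ids)))
    }
  }
  blocks
}

# Autoscale-and-concatenate helper used by grid/train: single blocks get
# a plain scaler, multiple blocks go through fuseBlocks with the
# dimension inferred from the tags.
.assembleX <- function(blocks, calRows) {
  if (length(blocks) == 1L) {
    scaler <- autoscaleFit(blocks[[1L]]@values[calRows, , drop = FALSE])
    return(autoscaleApply(blocks[[1L]]@values, scaler))
  }
  tags <- vapply(blocks, function(b) b@blockTag, character(1L))
  ranges <- unique(sub("_.*$", "", tags))
  mods <- unique(sub("^.*_", "", tags))
  dimension <- if (length(ranges) == 2L && length(mods) == 2L) "all"
               else if (length(ranges) == 2L) "range" else "modality"
  fuseBlocks(blocks, dimension = dimension, calRows = calRows)@values
}

.stageFuse <- function(cfg) {
  state <- .loadState(cfg, c("spectra", "textures", "split"), "textures")
  dims <- cfg$fusion$dimension
  blocks <- .gridBlocks(state, c("vnir", "swir"), "spec+tex", "full")
  state$fused <- fuseBlocks(blocks, dimension = "all",
                            calRows = state$split$train)
  .saveState(cfg, state)
  .log(cfg, "fuse: ", ncol(state$fused@values), " columns (", dims, ")")
  invisible(state$fused)
}

.stageTrain <- function(cfg) {
  state <- .loadState(cfg, c("fused", "split"), "fuse")
  y <- state$spectra$vnir@labels
  tr <- state$split$train
  X <- state$fused@values
  state$model <- .fitModel(cfg$model, X[tr, , drop = FALSE], y[tr],
                           seed = cfg$seed)
  .saveState(cfg, state)
  .log(cfg, "train: ", cfg$model$type)
  invisible(state$model)
}

.stageEvaluate <- function(cfg) {
  state <- .loadState(cfg, c("fused", "split"), "train")
  y <- state$spectra$vnir@labels
  tr <- state$split$train; te <- state$split$test
  X <- state$fused@values
  report <- evaluateModel(cfg$model, X[tr, , drop = FALSE], y[tr],
                          X[te, , drop = FALSE], y[te],
                          cv = TRUE, times = cfg$cv$times,
                          folds = cfg$cv$folds, seed = cfg$seed)
  writeModelReport(report, file.path(cfg$out, "model_report.json"))
  state$report <- report
  .saveState(cfg, state)
  .log(cfg, sprintf("evaluate: cal %.1f%%, pre %.1f%%, macro AUC %.3f",
                    report@accuracyCal, report@accuracyPre,
                    report@aucMacro))
  invisible(report)
}

.stageMap <- function(cfg) {
  state <- .loadState(cfg, c("scenes", "calibrated", "spectra", "split"),
                      "spectra")
  pp <- preprocessSpec(cfg$preprocess$method,
                       sgWindow = cfg$preprocess$sgWindow,
                       sgPolyorder = cfg$preprocess$sgPolyorder)
  y <- state$spectra$vnir@labels
  tr <- state$split$train
  tab <- state$spectra$vnir
  scaler <- autoscaleFit(tab@values[tr, , drop = FALSE])
  model <- plsdaFit(autoscaleApply(tab@values[tr, , drop = FALSE], scaler),
                    y[tr], nLatent = min(cfg$model$nLatent, length(tr) - 1L))
  small <- blockAverage(state$calibrated[[1L]]$vnir, cfg$map$block)
  map <- classifyPixels(small, model, preprocess = pp, scaler = scaler)
  renderRGB(map, file.path(cfg$out, "map_scene1_vnir.png"))
  utils::write.csv(map@labels, file.path(cfg$out, "map_scene1_vnir.csv"),
                   row.names = FALSE)
  state$map <- map
  .saveState(cfg, state)
  .log(cfg, "map: ", nrow(map@labels), "x", ncol(map@labels), " labels")
  invisible(map)
}

.stageGrid <- function(cfg) {
  state <- .loadState(cfg, c("spectra", "textures", "spa", "split"),
                      "textures")
  grid <- runGrid(state, models = cfg$model$type, nLatent = cfg$model$nLatent,
                  seed = cfg$seed)
  utils::write.csv(grid, file.path(cfg$out, "grid_results.csv"),
                   row.names = FALSE)
  state$grid <- grid
  .saveState(cfg, state)
  .log(cfg, "grid: ", nrow(grid), " rows")
  invisible(grid)
}

#' Run the consolidated experiment grid
#'
#' Crosses spectral type (VNIR, SWIR, VNIR+SWIR fusion) x feature set
#' (spectra, GLCM textures, GLRLM textures, spectrum+image fusion) x band
#' set (full, SPA) for the requested model(s), reporting calibration and
#' prediction accuracy plus macro AUC per configuration. Texture features
#' are always computed at the SPA effective wavelengths (per-band texture
#' extraction over hundreds of bands would be redundant), so texture-only
#' rows are identical across band sets; the spectrum+image set pairs
#' spectra with the GLRLM textures.
#'
#' @param state internal pipeline state holding `spectra`, `textures`,
#'   `spa` and `split` (see [runStage()]); assembled automatically when
#'   driving the pipeline through stages.
#' @param models character vector, subset of `c("plsda", "svm")`.
#' @param nLatent PLS-DA latent count.
#' @param seed integer seed.
#' @return data.frame with columns spectral_type, feature_set, band_set,
#'   model, acc_cal, acc_pre, auc_macro.
#' @export
runGrid <- function(state, models = "plsda", nLatent = 5L, seed = 1L) {
  y <- state$spectra$vnir@labels
  tr <- state$split$train; te <- state$split$test
  combos <- expand.grid(
    spectral_type = c("VNIR", "SWIR", "VNIR+SWIR"),
    feature_set = c("spectra", "GLCM", "GLRLM", "spec+tex"),
    band_set = c("full", "spa"),
    model = models, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    cb <- combos[k, ]
    ranges <- switch(cb$spectral_type, VNIR = "vnir", SWIR = "swir",
                     "VNIR+SWIR" = c("vnir", "swir"))
    blocks <- .gridBlocks(state, ranges, cb$feature_set, cb$band_set)
    X <- .assembleX(blocks, tr)
    spec <- if (cb$model == "plsda") list(type = "plsda", nLatent = nLatent)
            else list(type = "svm")
    rep <- evaluateModel(spec, X[tr, , drop = FALSE], y[tr],
                         X[te, , drop = FALSE], y[te], seed = seed)
    data.frame(cb, acc_cal = rep@accuracyCal, acc_pre = rep@accuracyPre,
               auc_macro = rep@aucMacro)
  })
  do.call(rbind, rows)
}
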