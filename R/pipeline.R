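# End-to-end orchestration: simulate -> features -> select -> train ->
# evaluate -> map, under one config and one root seed.

#' Assemble the feature row of one plot image
#'
#' Band means, the 11 vegetation indices, the 40 GLCM texture features
#' and, if `ti_specs` is non-empty, the texture-index columns.
#'
#' @param stack a [BandStack-class].
#' @param inner_buffer_frac ROI trim fraction.
#' @param texture list: `window`, `offset`, `levels` (and optionally
#'   `stride`) for the texture engine.
#' @param ti_specs list of [TextureIndexSpec-class].
#' @return one-row data.frame of named features.
#' @export
buildFeatureRow <- function(stack, inner_buffer_frac = 0,
                            texture = list(window = 4L, offset = c(1, 1),
                                           levels = 32L),
                            ti_specs = list()) {
  m <- extractRoiMeans(stack, inner_buffer_frac)
  vis <- computeVIs(m)
  tfs <- textureFeaturesForSample(
    stack, inner_buffer_frac,
    window = texture$window %||% 4L,
    offset = texture$offset %||% c(1, 1),
    levels = texture$levels %||% 32L,
    stride = texture$stride %||% 1L)
  row <- as.data.frame(as.list(c(m, vis, tfs)))
  addIndexColumns(row, ti_specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the feature table of a generated scenario
#'
#' @param experiment result of [generateExperiment()] or
#'   [generateIndependentScenario()].
#' @inheritParams buildFeatureRow
#' @return data.frame: the sample records (plot_id, density, nitrogen,
#'   replicate, date, scenario, lai_true) followed by feature columns.
#' @export
buildFeatureTable <- function(experiment, inner_buffer_frac = 0,
                              texture = list(window = 4L,
                                             offset = c(1, 1),
                                             levels = 32L),
                              ti_specs = list()) {
  rows <- lapply(experiment$stacks, buildFeatureRow,
                 inner_buffer_frac = inner_buffer_frac,
                 texture = texture, ti_specs = ti_specs)
  cbind(experiment$samples, do.call(rbind, rows), row.names = NULL)
}

#' Pipeline configuration
#'
#' Defaults reproduce the reference configuration: a 3-density x
#' 4-nitrogen x 3-replicate trial over 5 dates, 128 px plots, 32 gray
#' levels with a 4 x 4 window at offset (1, 1), p < 0.05 screening, 10
#' retained texture indices, PLSR+GBDT stacking and a 1/3 rank-systematic
#' validation split. `grids = "reduced"` keeps cross-validated runs at
#' simulation scale; `"full"` searches the complete printed-range grids.
#'
#' @param seed root seed for every stochastic choice.
#' @param synthetic list: overrides for [experimentDesign()] and a
#'   `canopy` sublist for [canopyModel()].
#' @param texture list: `levels`, `window`, `offset`, `stride`.
#' @param selection list: `alpha`, `ti_k`, `restrict_reference` (use the
#'   reference 10-VI/10-TF input pools).
#' @param model list: `pair` (ML base), `grids` ("reduced"/"full"),
#'   `meta_k`, `inner_k`.
#' @param evaluation list: `fraction` (validation share), `map_window`.
#' @return nested list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 42L, synthetic = list(),
                           texture = list(), selection = list(),
                           model = list(), evaluation = list()) {
  cfg <- list(
    seed = as.integer(seed),
    synthetic = modifyList(list(densities = c("D1", "D2", "D3"),
                                n_rates = c("N0", "N1", "N2", "N3"),
                                replicates = 3L, dates = 5L,
                                image_size = 128L, canopy = list()),
                           synthetic),
    texture = modifyList(list(levels = 32L, window = 4L,
                              offset = c(1, 1), stride = 1L), texture),
    selection = modifyList(list(alpha = 0.05, ti_k = 10L,
                                restrict_reference = TRUE), selection),
    model = modifyList(list(pair = "GBDT", grids = "reduced",
                            meta_k = 5L, inner_k = 5L), model),
    evaluation = modifyList(list(fraction = 1 / 3, map_window = 32L),
                            evaluation))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a file whose top-level keys mirror the [pipelineConfig()]
#' arguments (`seed`, `synthetic`, `texture`, `selection`, `model`,
#' `evaluation`); absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y[intersect(names(y),
                                      c("seed", "synthetic", "texture",
                                        "selection", "model",
                                        "evaluation"))])
}

cfgDesign <- function(cfg) {
  s <- cfg$synthetic
  experimentDesign(densities = s$densities, n_rates = s$n_rates,
                   replicates = s$replicates, dates = s$dates,
                   image_size = s$image_size, seed = cfg$seed)
}

cfgCanopy <- function(cfg) do.call(canopyModel, cfg$synthetic$canopy)

cfgGrids <- function(cfg) {
  if (is.list(cfg$model$grids)) cfg$model$grids
  else defaultGrids(reduced = identical(cfg$model$grids, "reduced"))
}

# Select texture indices and screen features on the modeling rows only,
# then return the model-input feature names per feature set.
selectInputs <- function(features, modeling_idx, cfg) {
  sel <- cfg$selection
  lai_m <- features$lai_true[modeling_idx]
  tf_pool <- if (isTRUE(sel$restrict_reference)) defaultTFInputs()
             else paste(rep(BAND_NAMES, each = 8), TF_METRICS, sep = "_")
  cand <- enumerateCandidates(tf_pool)
  ranked <- selectTopIndices(cand,
                             features[modeling_idx, , drop = FALSE],
                             lai_m, k = sel$ti_k, alpha = sel$alpha)
  features <- addIndexColumns(features, ranked$specs)
  ti_cols <- vapply(ranked$specs, function(sp)
    paste0(sp@indexType, ".", paste(sp@components, collapse = ";")),
    character(1))
  groups <- list(VI = VI_NAMES,
                 TF = paste(rep(BAND_NAMES, each = 8), TF_METRICS,
                            sep = "_"),
                 TI = ti_cols)
  restrict <- if (isTRUE(sel$restrict_reference))
    list(VI = defaultVIInputs(), TF = defaultTFInputs()) else NULL
  scr <- screenFeatures(features[modeling_idx, , drop = FALSE], lai_m,
                        alpha = sel$alpha, feature_groups = groups,
                        restrict = restrict)
  ret <- attr(scr, "retained")
  list(features = features, screening = scr, ti_ranking = ranked,
       ti_specs = ranked$specs,
       sets = list("VIs" = ret$VI,
                   "VIs+TFs" = c(ret$VI, ret$TF),
                   "VIs+TFs+TIs" = c(ret$VI, ret$TF, ret$TI)))
}

trainAndScore <- function(features, split, input_names, pair, cfg) {
  X <- features[, input_names, drop = FALSE]
  y <- features$lai_true
  m <- fitStack(X[split$modeling_idx, , drop = FALSE],
                y[split$modeling_idx],
                pair = c("PLSR", pair), grids = cfgGrids(cfg),
                meta_k = cfg$model$meta_k, inner_k = cfg$model$inner_k,
                seed = subSeed(cfg$seed, 5L))
  pr_tr <- predict(m, X[split$modeling_idx, , drop = FALSE])
  pr_va <- predict(m, X[split$validation_idx, , drop = FALSE])
  list(model = m,
       training = laiMetrics(y[split$modeling_idx], pr_tr),
       validation = laiMetrics(y[split$validation_idx], pr_va))
}

#' Run the full pipeline
#'
#' Stages in order: simulate the main and independent scenarios, extract
#' features, select texture indices and screen features on the modeling
#' split, train the stacked model, evaluate on the validation split and
#' the independent scenario, and render a coarse LAI map for the highest-
#' and lowest-LAI plot images. With `out_dir`, stage outputs are written
#' as CSV/JSON/TIFF.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir optional output directory.
#' @return list: `features` (feature table with TI columns), `split`,
#'   `screening`, `ti_ranking`, `model`, `reports` (training, validation,
#'   independent), `maps`.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = NULL) {
  cfg <- config
  design <- cfgDesign(cfg)
  canopy <- cfgCanopy(cfg)
  texture <- list(window = cfg$texture$window, offset = cfg$texture$offset,
                  levels = cfg$texture$levels, stride = cfg$texture$stride)
  if (nrow(makeSampleTable(design, "main")) < 30)
    message("note: fewer than 30 samples; metrics will be unstable")

  main <- generateExperiment(design, canopy)
  indep <- generateIndependentScenario(design, canopy)
  features <- buildFeatureTable(main, texture = texture)
  split <- sortedSplit(features$lai_true, cfg$evaluation$fraction)

  sel <- selectInputs(features, split$modeling_idx, cfg)
  features <- sel$features
  inputs <- sel$sets[["VIs+TFs+TIs"]]
  fit <- trainAndScore(features, split, inputs, cfg$model$pair, cfg)

  ifeat <- buildFeatureTable(indep, texture = texture,
                             ti_specs = sel$ti_specs)
  scen <- evaluateScenarios(
    fit$model,
    features[split$validation_idx, inputs, drop = FALSE],
    features$lai_true[split$validation_idx],
    ifeat[, inputs, drop = FALSE], ifeat$lai_true)

  hi <- which.max(features$lai_true)
  lo <- which.min(features$lai_true)
  maps <- list(high = predictMap(fit$model, main$stacks[[hi]],
                                 window = cfg$evaluation$map_window,
                                 ti_specs = sel$ti_specs,
                                 texture = texture),
               low = predictMap(fit$model, main$stacks[[lo]],
                                window = cfg$evaluation$map_window,
                                ti_specs = sel$ti_specs,
                                texture = texture))
  reports <- list(training = fit$training, validation = scen$main,
                  independent = scen$independent)
  out <- list(config = cfg, features = features, split = split,
              screening = sel$screening, ti_ranking = sel$ti_ranking,
              inputs = inputs, model = fit$model, reports = reports,
              maps = maps)
  if (!is.null(out_dir)) writePipelineOutputs(out, indep, ifeat, out_dir)
  out
}

writePipelineOutputs <- function(out, indep, ifeat, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(out$features, file.path(out_dir, "features_main.csv"),
            row.names = FALSE)
  write.csv(ifeat, file.path(out_dir, "features_independent.csv"),
            row.names = FALSE)
  writeScreeningReport(out$screening,
                       file.path(out_dir, "screening.csv"))
  writeIndexRanking(out$ti_ranking,
                    file.path(out_dir, "texture_indices.csv"))
  jsonlite::write_json(
    list(seed = out$config$seed,
         inputs = out$inputs,
         reports = lapply(out$reports, unclass)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLaiMap(out$maps$high, file.path(out_dir, "lai_map_high.tif"))
  writeLaiMap(out$maps$low, file.path(out_dir, "lai_map_low.tif"))
  invisible(out_dir)
}

#' Compare feature sets across stacking pairs
#'
#' Evaluates the three nested input sets (VIs; VIs+TFs; VIs+TFs+TIs)
#' under each requested PLSR+ML pair on the identical split and seed, and
#' returns the 3 x 3 comparison.
#'
#' @param config a [pipelineConfig()].
#' @param pairs ML base learners to pair with PLSR.
#' @param feature_sets subset of `c("VIs", "VIs+TFs", "VIs+TFs+TIs")`.
#' @return data.frame: pair, feature_set, n_features, and training /
#'   validation r2, rmse, mae.
#' @export
compareFeatureSets <- function(config = pipelineConfig(),
                               pairs = c("SVM", "RF", "GBDT"),
                               feature_sets = c("VIs", "VIs+TFs",
                                                "VIs+TFs+TIs")) {
  cfg <- config
  texture <- list(window = cfg$texture$window, offset = cfg$texture$offset,
                  levels = cfg$texture$levels, stride = cfg$texture$stride)
  main <- generateExperiment(cfgDesign(cfg), cfgCanopy(cfg))
  features <- buildFeatureTable(main, texture = texture)
  split <- sortedSplit(features$lai_true, cfg$evaluation$fraction)
  sel <- selectInputs(features, split$modeling_idx, cfg)
  features <- sel$features
  rows <- list()
  for (p in pairs) for (fs in feature_sets) {
    fit <- trainAndScore(features, split, sel$sets[[fs]], p, cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste0("PLSR+", p), feature_set = fs,
      n_features = length(sel$sets[[fs]]),
      train_r2 = fit$training$r2, train_rmse = fit$training$rmse,
      train_mae = fit$training$mae,
      val_r2 = fit$validation$r2, val_rmse = fit$validation$rmse,
      val_mae = fit$validation$mae)
  }
  out <- do.call(rbind, rows)
  attr(out, "split") <- split
  attr(out, "features") <- features
  attr(out, "ti_ranking") <- sel$ti_ranking
  out
}
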