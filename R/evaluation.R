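# Sample splitting, accuracy metrics, scenario-transfer evaluation and
# LAI map rendering.

#' Rank-systematic modeling/validation split
#'
#' Samples are sorted by LAI ascending; every `floor(1/fraction)`-th rank,
#' starting at rank 2 and capped at rank n - 1, is assigned to the
#' validation set until the quota `round(fraction * n)` is met (topped up
#' with evenly spaced interior ranks if the stride undershoots). Both sets
#' therefore span the LAI range: the smallest and largest values always
#' stay in the modeling set. Ties are broken by stable original order.
#'
#' @param lai_values numeric LAI vector (n >= 3).
#' @param fraction validation share in (0, 1), default 1/3.
#' @return list of class `SplitPlan`: `modeling_idx`, `validation_idx`
#'   (indices into the input), `fraction`.
#' @examples
#' sortedSplit(c(5, 1, 3, 2, 4, 6), 1/3)
#' @export
sortedSplit <- function(lai_values, fraction = 1 / 3) {
  n <- length(lai_values)
  stopifnot(n >= 3, fraction > 0, fraction < 1)
  quota <- round(fraction * n)
  step <- floor(1 / fraction)
  ranks <- seq(2L, n - 1L, by = step)
  if (length(ranks) > quota) ranks <- ranks[seq_len(quota)]
  if (length(ranks) < quota) {
    pool <- setdiff(2:(n - 1L), ranks)
    extra <- pool[unique(round(seq(1, length(pool),
                                   length.out = quota - length(ranks))))]
    ranks <- sort(c(ranks, extra))
  }
  ord <- order(lai_values)  # stable: ties keep original order
  val <- sort(ord[ranks])
  structure(list(modeling_idx = setdiff(seq_len(n), val),
                 validation_idx = val, fraction = fraction),
            class = "SplitPlan")
}

#' Accuracy metrics for LAI prediction
#'
#' R2 = 1 - sum((x - y)^2) / sum((x - mean(x))^2);
#' RMSE = sqrt(mean((x - y)^2)); MAE = mean(|x - y|), with x the measured
#' and y the predicted LAI.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return list of class `EvalReport`: `r2`, `rmse`, `mae`, `n`. R2 is
#'   `NA` (with a warning) when the observed values are constant.
#' @examples
#' laiMetrics(c(1, 2, 3), c(1, 2, 4))
#' @export
laiMetrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  err <- observed - predicted
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  ss <- sum((observed - mean(observed))^2)
  r2 <- if (ss == 0) {
    warning("R2 undefined: observed values are constant")
    NA_real_
  } else 1 - sum(err^2) / ss
  structure(list(r2 = r2, rmse = rmse, mae = mae, n = length(observed)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (n = %d): R2 = %.3f, RMSE = %.3f, MAE = %.3f\n",
              x$n, x$r2, x$rmse, x$mae))
  invisible(x)
}

#' Evaluate a model on the main validation split and an independent trial
#'
#' The model must have been trained only on the main-scenario modeling
#' split; independent-scenario samples never enter any fit.
#'
#' @param model a [StackedLAIModel-class].
#' @param main_features,main_lai validation-split features and LAI.
#' @param independent_features,independent_lai full independent-scenario
#'   features and LAI.
#' @return named list of two `EvalReport`s: `main`, `independent`.
#' @export
evaluateScenarios <- function(model, main_features, main_lai,
                              independent_features, independent_lai) {
  main <- laiMetrics(main_lai, predict(model, main_features))
  indep <- laiMetrics(independent_lai,
                      predict(model, independent_features))
  main$split_label <- "main_validation"
  indep$split_label <- "independent"
  list(main = main, independent = indep)
}

#' Predict a coarse LAI map over a plot image
#'
#' Tiles the stack with `window` x `window` sub-images at the given
#' stride, rebuilds the model's feature schema per tile (band means, VIs,
#' texture features and texture indices), and predicts LAI per tile.
#'
#' @param model a [StackedLAIModel-class].
#' @param stack a [BandStack-class] at least `window` pixels per side.
#' @param window tile side in pixels.
#' @param stride tile step; `stride = window` gives non-overlapping tiles.
#' @param ti_specs list of [TextureIndexSpec-class] used by the model's
#'   schema (may be empty).
#' @param texture list of texture parameters passed to
#'   [textureFeaturesForSample()] (`window`, `offset`, `levels`).
#' @return numeric matrix of predicted LAI (m2/m2), one cell per tile.
#' @export
predictMap <- function(model, stack, window = 32L, stride = window,
                       ti_specs = list(),
                       texture = list(window = 4L, offset = c(1, 1),
                                      levels = 32L)) {
  d <- imageSize(stack)
  if (d[1] < window || d[2] < window)
    stop("stack smaller than the map window")
  r0s <- seq(1L, d[1] - window + 1L, by = stride)
  c0s <- seq(1L, d[2] - window + 1L, by = stride)
  out <- matrix(NA_real_, length(r0s), length(c0s))
  for (ri in seq_along(r0s)) for (ci in seq_along(c0s)) {
    sub <- bandStack(stack@bands[r0s[ri]:(r0s[ri] + window - 1L),
                                 c0s[ci]:(c0s[ci] + window - 1L), ,
                                 drop = FALSE])
    row <- buildFeatureRow(sub, inner_buffer_frac = 0, texture = texture,
                           ti_specs = ti_specs)
    miss <- setdiff(modelFeatures(model), names(row))
    if (length(miss))
      stop("model schema features unavailable at tile scale: ",
           paste(miss, collapse = ", "))
    out[ri, ci] <- predict(model, row[, modelFeatures(model),
                                      drop = FALSE])
  }
  out
}

#' Write an LAI map as a single-band TIFF (values in m2/m2)
#'
#' @param map numeric matrix from [predictMap()].
#' @param path output file.
#' @param max_lai value mapped to full intensity (storage scaling only).
#' @export
writeLaiMap <- function(map, path, max_lai = 6) {
  tiff::writeTIFF(pmin(pmax(map / max_lai, 0), 1), path,
                  bits.per.sample = 32L)
  invisible(path)
}
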