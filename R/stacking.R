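# Stacked ensemble regression: a PLSR base learner paired with one
# nonlinear learner (SVM, RF or GBDT); their out-of-fold predictions form
# two meta-features on which a Lasso meta-model is fitted. Hyperparameters
# are tuned by inner-CV grid search minimizing RMSE; generalization is
# measured by nested (outer) cross-validation in which screening, tuning
# and stacking are all re-run inside every training fold.

asFeatureMatrix <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

cvFoldIds <- function(n, k, seed) {
  if (k < 2) stop("need at least 2 folds")
  ids <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  if (min(table(ids)) < 2) stop("a fold has fewer than 2 samples")
  ids
}

# Largest usable fold count for n samples (>= 2 samples per fold),
# warning when the requested k had to be degraded.
adaptFolds <- function(k, n, what) {
  k2 <- max(2L, min(as.integer(k), floor(n / 2)))
  if (k2 < k)
    warning(sprintf("degraded n: %s reduced from %d to %d folds (n = %d)",
                    what, k, k2, n), call. = FALSE)
  k2
}

#' Default hyperparameter grids
#'
#' Grid points lie inside the intended search ranges: GBDT learning rate
#' 0.05-0.2, depth 3-5, min leaf 2-5; RF 100-300 trees, feature ratio
#' 0.3-0.8; SVM (RBF) C 0.1-100, epsilon 0.01-1. `reduced = TRUE` returns
#' small grids for fast cross-validated runs at simulation scale.
#'
#' @param reduced use the compact grids.
#' @return named list of data.frame grids for PLSR, SVM, RF, GBDT.
#' @export
defaultGrids <- function(reduced = FALSE) {
  if (reduced) {
    list(
      PLSR = data.frame(n_components = c(2L, 5L, 10L)),
      SVM = expand.grid(C = c(1, 10, 100), epsilon = c(0.01, 0.1),
                        gamma = "scale", kernel = "radial",
                        stringsAsFactors = FALSE),
      RF = expand.grid(n_trees = 200L, max_feature_ratio = c(0.3, 0.8),
                       depth = NA_integer_, min_leaf = c(1L, 5L),
                       min_split = 2L),
      GBDT = expand.grid(learning_rate = c(0.05, 0.1), depth = c(3L, 5L),
                         min_leaf = 2L, n_trees = 200L, subsample = 0.8))
  } else {
    list(
      PLSR = data.frame(n_components = 1:15),
      SVM = expand.grid(C = c(0.1, 1, 10, 100),
                        epsilon = c(0.01, 0.1, 0.5, 1),
                        gamma = c("scale", "0.01", "0.1", "1"),
                        kernel = "radial", stringsAsFactors = FALSE),
      RF = expand.grid(n_trees = c(100L, 200L, 300L),
                       max_feature_ratio = c(0.3, 0.5, 0.8),
                       depth = c(NA_integer_, 5L, 10L),
                       min_leaf = c(1L, 2L, 5L), min_split = c(2L, 5L)),
      GBDT = expand.grid(learning_rate = c(0.05, 0.1, 0.2),
                         depth = c(3L, 4L, 5L), min_leaf = c(2L, 3L, 5L),
                         n_trees = c(100L, 200L), subsample = c(0.8, 1)))
  }
}

# Fit one base learner. PLSR, SVM and the Lasso meta-model are scale
# sensitive, so their inputs are z-scored with training-fold statistics;
# tree learners consume raw features.
fitLearner <- function(learner, X, y, params, seed = 1L) {
  X <- asFeatureMatrix(X)
  if (sd(y) == 0) stop("degenerate response: y is constant")
  obj <- list(learner = learner, params = params, features = colnames(X))
  if (learner %in% c("PLSR", "SVM")) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, ctr, scl)
    obj$center <- ctr
    obj$scale <- scl
  }
  if (learner == "PLSR") {
    ncomp <- min(params$n_components, ncol(X), nrow(X) - 1L)
    obj$ncomp <- ncomp
    obj$fit <- mixOmics::pls(Xs, y, ncomp = ncomp, mode = "regression",
                             scale = FALSE)
  } else if (learner == "SVM") {
    gam <- params$gamma
    gam <- if (identical(gam, "scale")) 1 / ncol(X) else as.numeric(gam)
    obj$fit <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                          kernel = params$kernel, cost = params$C,
                          epsilon = params$epsilon, gamma = gam,
                          scale = FALSE)
  } else if (learner == "RF") {
    mtry <- max(1L, round(params$max_feature_ratio * ncol(X)))
    obj$fit <- ranger::ranger(
      x = X, y = y, num.trees = params$n_trees, mtry = mtry,
      max.depth = if (is.na(params$depth)) 0 else params$depth,
      min.node.size = params$min_split, min.bucket = params$min_leaf,
      seed = seed, num.threads = 1)
  } else if (learner == "GBDT") {
    dtr <- xgboost::xgb.DMatrix(X, label = y)
    obj$fit <- xgboost::xgb.train(
      params = list(eta = params$learning_rate, max_depth = params$depth,
                    min_child_weight = params$min_leaf,
                    subsample = params$subsample,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = dtr, nrounds = params$n_trees, verbose = 0)
  } else stop("unknown learner: ", learner)
  class(obj) <- "laiLearner"
  obj
}

predictLearner <- function(obj, Xnew) {
  Xnew <- asFeatureMatrix(Xnew)
  miss <- setdiff(obj$features, colnames(Xnew))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  Xnew <- Xnew[, obj$features, drop = FALSE]
  switch(obj$learner,
         PLSR = {
           Xs <- scale(Xnew, obj$center, obj$scale)
           as.numeric(predict(obj$fit, Xs)$predict[, 1, obj$ncomp])
         },
         SVM = as.numeric(predict(obj$fit,
                                  scale(Xnew, obj$center, obj$scale))),
         RF = predict(obj$fit, data = as.data.frame(Xnew),
                      num.threads = 1)$predictions,
         GBDT = predict(obj$fit, xgboost::xgb.DMatrix(Xnew)))
}

#' Tune a base learner by grid search
#'
#' Evaluates every grid point by inner k-fold cross-validated RMSE, picks
#' the minimizer (ties broken by grid order), and refits the learner on
#' all of X. A single-point grid is fitted directly.
#'
#' @param learner one of "PLSR", "SVM", "RF", "GBDT".
#' @param X feature matrix or data.frame; `y` numeric response.
#' @param y numeric response.
#' @param grid data.frame of hyperparameter rows.
#' @param inner_k inner CV folds.
#' @param seed integer seed (folds and stochastic learners).
#' @return list: `model` (fitted on all data), `best` (grid row),
#'   `cv_rmse` (NA for a single-point grid).
#' @export
tuneBase <- function(learner, X, y, grid, inner_k = 5L, seed = 1L) {
  X <- asFeatureMatrix(X)
  if (nrow(grid) == 0) stop("empty grid")
  if (sd(y) == 0) stop("degenerate response: y is constant")
  if (nrow(grid) == 1L) {
    best <- 1L
    cv_rmse <- NA_real_
  } else {
    inner_k <- adaptFolds(inner_k, nrow(X), "inner CV")
    folds <- cvFoldIds(nrow(X), inner_k, subSeed(seed, 17L))
    rmse <- vapply(seq_len(nrow(grid)), function(gi) {
      se <- 0
      for (f in seq_len(inner_k)) {
        tr <- folds != f
        m <- fitLearner(learner, X[tr, , drop = FALSE], y[tr],
                        grid[gi, , drop = FALSE], seed = subSeed(seed, gi, f))
        pr <- predictLearner(m, X[!tr, , drop = FALSE])
        se <- se + sum((y[!tr] - pr)^2)
      }
      sqrt(se / nrow(X))
    }, numeric(1))
    best <- which.min(rmse)
    cv_rmse <- rmse[best]
  }
  list(model = fitLearner(learner, X, y, grid[best, , drop = FALSE],
                          seed = subSeed(seed, 99L)),
       best = grid[best, , drop = FALSE], cv_rmse = cv_rmse)
}

#' Out-of-fold meta-features for stacking
#'
#' Splits the samples into k folds; for each fold both base learners are
#' tuned and fitted on the other k - 1 folds and their predictions stored
#' for the held-out fold, so every sample receives exactly one
#' out-of-fold prediction per base learner.
#'
#' @param X features; `y` response.
#' @param y numeric response.
#' @param pair c("PLSR", ml) with ml one of "SVM", "RF", "GBDT".
#' @param grids named grid list as from [defaultGrids()].
#' @param k meta folds (>= 2).
#' @param inner_k folds of the tuning CV inside each meta fold.
#' @param seed integer seed.
#' @return n x 2 matrix (columns named after the two bases) with
#'   attribute `folds` recording the fold id of every sample.
#' @export
makeMetaFeatures <- function(X, y, pair, grids, k = 5L, inner_k = 5L,
                             seed = 1L) {
  X <- asFeatureMatrix(X)
  k <- adaptFolds(k, nrow(X), "meta-feature CV")
  folds <- cvFoldIds(nrow(X), k, subSeed(seed, 7L))
  meta <- matrix(NA_real_, nrow(X), 2, dimnames = list(NULL, pair))
  for (f in seq_len(k)) {
    tr <- folds != f
    for (b in 1:2) {
      tb <- tuneBase(pair[b], X[tr, , drop = FALSE], y[tr],
                     grids[[pair[b]]], inner_k,
                     seed = subSeed(seed, f, b))
      meta[!tr, b] <- predictLearner(tb$model, X[!tr, , drop = FALSE])
    }
  }
  attr(meta, "folds") <- folds
  meta
}

#' Fit a stacked PLSR + machine-learning model
#'
#' Builds out-of-fold meta-features, fits a Lasso meta-model on them
#' (penalty chosen by cross-validation), and refits both tuned base
#' learners on all data for deployment.
#'
#' @inheritParams makeMetaFeatures
#' @param meta_k folds for the meta-features.
#' @return a [StackedLAIModel-class].
#' @examples
#' \donttest{
#' X <- matrix(rnorm(400), 50, 8); colnames(X) <- paste0("f", 1:8)
#' y <- X %*% rnorm(8) + rnorm(50, 0, 0.1)
#' m <- fitStack(X, as.numeric(y), pair = c("PLSR", "GBDT"),
#'               grids = defaultGrids(reduced = TRUE), seed = 1)
#' }
#' @export
fitStack <- function(X, y, pair = c("PLSR", "GBDT"),
                     grids = defaultGrids(), meta_k = 5L, inner_k = 5L,
                     seed = 42L) {
  X <- asFeatureMatrix(X)
  pair <- as.character(pair)
  if (pair[1] != "PLSR" || !pair[2] %in% c("SVM", "RF", "GBDT"))
    stop("pair must be c('PLSR', <SVM|RF|GBDT>)")
  meta <- makeMetaFeatures(X, y, pair, grids, meta_k, inner_k,
                           seed = subSeed(seed, 1L))
  # Lasso meta-model; meta-features are standardized by glmnet internally
  nf <- min(5L, max(3L, floor(nrow(X) / 10)))
  foldid <- cvFoldIds(nrow(X), nf, subSeed(seed, 2L))
  cvfit <- glmnet::cv.glmnet(meta, y, alpha = 1, foldid = foldid)
  co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  base1 <- tuneBase(pair[1], X, y, grids[[pair[1]]], inner_k,
                    seed = subSeed(seed, 3L))
  base2 <- tuneBase(pair[2], X, y, grids[[pair[2]]], inner_k,
                    seed = subSeed(seed, 4L))
  new("StackedLAIModel", pair = pair,
      basePLSR = base1["model"], baseML = base2["model"],
      metaFit = list(fit = cvfit, lambda = cvfit$lambda.min,
                     coefficients = co),
      tunedParams = list(PLSR = base1$best, ML = base2$best),
      featureNames = colnames(X),
      metaK = as.integer(meta_k), seed = as.integer(seed))
}

#' Predict LAI with a fitted stack
#'
#' Base predictions from the deployed base learners are combined by the
#' Lasso meta-model. `newdata` must carry exactly the training feature
#' columns.
#'
#' @param object a [StackedLAIModel-class].
#' @param newdata feature matrix or data.frame.
#' @return numeric vector of predicted LAI (m2/m2).
#' @export
setMethod("predict", "StackedLAIModel", function(object, newdata) {
  Xn <- asFeatureMatrix(newdata)
  miss <- setdiff(object@featureNames, colnames(Xn))
  extra <- setdiff(colnames(Xn), object@featureNames)
  if (length(miss) || length(extra))
    stop("feature schema mismatch; missing: [",
         paste(miss, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  Xn <- Xn[, object@featureNames, drop = FALSE]
  mf <- cbind(predictLearner(object@basePLSR$model, Xn),
              predictLearner(object@baseML$model, Xn))
  colnames(mf) <- object@pair
  as.numeric(predict(object@metaFit$fit, newx = mf, s = "lambda.min"))
})

#' Nested cross-validated evaluation of the full procedure
#'
#' In every outer training fold the complete pipeline — optional
#' screening, hyperparameter tuning, and stacking — is re-run from
#' scratch; the outer test fold only ever sees predictions. Metrics are
#' aggregated as mean and sd over folds (and repeats).
#'
#' @inheritParams fitStack
#' @param outer_k outer folds.
#' @param repeats outer repeats with distinct shuffles.
#' @param screen_fun optional `function(X_train, y_train)` returning the
#'   feature names to use in that fold.
#' @return list: `per_fold` data.frame (repeat, fold, n, r2, rmse, mae),
#'   `aggregate` (mean and sd per metric), `predictions` (out-of-fold
#'   prediction matrix, samples x repeats) and `folds` (fold assignment
#'   per repeat) for leakage audits.
#' @export
nestedCvEvaluate <- function(X, y, pair = c("PLSR", "GBDT"),
                             grids = defaultGrids(), outer_k = 10L,
                             repeats = 1L, meta_k = 5L, inner_k = 5L,
                             seed = 42L, screen_fun = NULL) {
  X <- asFeatureMatrix(X)
  rows <- list()
  oof <- matrix(NA_real_, nrow(X), repeats)
  fold_of <- matrix(NA_integer_, nrow(X), repeats)
  for (rep in seq_len(repeats)) {
    folds <- cvFoldIds(nrow(X), outer_k, subSeed(seed, 1000L + rep))
    fold_of[, rep] <- folds
    for (f in seq_len(outer_k)) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[tr]
      feats <- if (is.null(screen_fun)) colnames(X)
               else screen_fun(Xtr, ytr)
      m <- fitStack(Xtr[, feats, drop = FALSE], ytr, pair, grids,
                    meta_k, inner_k, seed = subSeed(seed, rep, f))
      pr <- predict(m, X[!tr, feats, drop = FALSE])
      oof[!tr, rep] <- pr
      mt <- laiMetrics(y[!tr], pr)
      rows[[length(rows) + 1L]] <-
        data.frame(rep = rep, fold = f, n = sum(!tr),
                   r2 = mt$r2, rmse = mt$rmse, mae = mt$mae)
    }
  }
  per_fold <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("r2", "rmse", "mae"),
    mean = c(mean(per_fold$r2), mean(per_fold$rmse), mean(per_fold$mae)),
    sd = c(sd(per_fold$r2), sd(per_fold$rmse), sd(per_fold$mae)))
  list(per_fold = per_fold, aggregate = agg, predictions = oof,
       folds = fold_of)
}
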