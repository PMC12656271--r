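# Base-learner tuning, out-of-fold meta-features, stack fitting,
# prediction and nested cross-validation.

reducedGrids <- function() defaultGrids(reduced = TRUE)

test_that("grid search selects by inner-CV RMSE and honors grid bounds", {
  lp <- linearProblem(n = 40, noise = 0.05)
  one <- tuneBase("PLSR", lp$X, lp$y, data.frame(n_components = 3L),
                  seed = 1)
  expect_equal(one$best$n_components, 3L)
  expect_true(is.na(one$cv_rmse))
  tb <- tuneBase("PLSR", lp$X, lp$y,
                 data.frame(n_components = c(1L, 6L)), seed = 1)
  # noiseless-limit: full-rank PLSR explains a 6-feature linear response
  expect_equal(tb$best$n_components, 6L)
  expect_lt(tb$cv_rmse, 0.1)
  for (lrn in c("SVM", "RF", "GBDT")) {
    g <- reducedGrids()[[lrn]]
    r <- tuneBase(lrn, lp$X, lp$y, g, seed = 2)
    hit <- vapply(seq_len(nrow(g)), function(i)
      isTRUE(all.equal(g[i, ], r$best, check.attributes = FALSE)),
      logical(1))
    expect_true(any(hit))  # tuned point lies inside the declared grid
  }
  expect_error(tuneBase("PLSR", lp$X, rep(1, 40),
                        data.frame(n_components = 2L)), "constant")
  expect_identical(
    tuneBase("GBDT", lp$X, lp$y, reducedGrids()$GBDT, seed = 5)$best,
    tuneBase("GBDT", lp$X, lp$y, reducedGrids()$GBDT, seed = 5)$best)
})

test_that("meta-features are out-of-fold", {
  lp <- linearProblem(n = 40, noise = 0.05)
  meta <- makeMetaFeatures(lp$X, lp$y, c("PLSR", "GBDT"),
                           reducedGrids(), k = 5, seed = 11)
  expect_equal(dim(meta), c(40, 2))
  expect_identical(colnames(meta), c("PLSR", "GBDT"))
  folds <- attr(meta, "folds")
  expect_equal(sort(unique(folds)), 1:5)
  # exact-fit limit: the PLSR column reproduces a noiseless linear y
  lp0 <- linearProblem(n = 40, noise = 0)
  meta0 <- makeMetaFeatures(lp0$X, lp0$y, c("PLSR", "GBDT"),
                            list(PLSR = data.frame(n_components = 6L),
                                 GBDT = reducedGrids()$GBDT[1, ]),
                            k = 5, seed = 11)
  expect_lt(max(abs(meta0[, "PLSR"] - lp0$y)), 1e-6)
  # corruption audit: corrupting the labels of fold f cannot change the
  # out-of-fold predictions for fold f (its models never see fold f)
  f <- 1L
  y_bad <- lp0$y
  y_bad[folds0 <- attr(meta0, "folds") == f] <- 99
  meta_bad <- makeMetaFeatures(lp0$X, y_bad, c("PLSR", "GBDT"),
                               list(PLSR = data.frame(n_components = 6L),
                                    GBDT = reducedGrids()$GBDT[1, ]),
                               k = 5, seed = 11)
  expect_equal(meta_bad[folds0, ], meta0[folds0, ], tolerance = 1e-10)
})

test_that("stacks reach the exact-fit limit and are reproducible", {
  lp <- linearProblem(n = 60, noise = 0)
  m1 <- fitStack(lp$X, lp$y, c("PLSR", "GBDT"), reducedGrids(), seed = 4)
  pr <- predict(m1, lp$X)
  expect_gte(laiMetrics(lp$y, pr)$r2, 0.999)
  m2 <- fitStack(lp$X, lp$y, c("PLSR", "GBDT"), reducedGrids(), seed = 4)
  expect_identical(metaCoefficients(m1), metaCoefficients(m2))
  expect_identical(pr, predict(m2, lp$X))
  expect_error(fitStack(lp$X, lp$y, c("PLSR", "LM"), reducedGrids()),
               "pair")
})

test_that("the L1 meta-model shrinks a redundant collinear meta-feature", {
  set.seed(6)
  y <- runif(80, 1, 5)
  meta <- cbind(a = y + rnorm(80, 0, 1e-4), b = y + rnorm(80, 0, 1e-4))
  cv <- glmnet::cv.glmnet(meta, y, alpha = 1, foldid = rep(1:5, 16))
  co <- as.numeric(coef(cv, s = "lambda.min"))
  pr <- as.numeric(predict(cv, newx = meta, s = "lambda.min"))
  expect_gt(laiMetrics(y, pr)$r2, 0.995)  # prediction ~ y up to shrinkage
  expect_lt(min(abs(co[2:3])), 0.1)  # one duplicate weight driven to ~0
})

test_that("prediction enforces the schema and is row-equivariant", {
  lp <- linearProblem(n = 50, noise = 0.1)
  m <- fitStack(lp$X, lp$y, c("PLSR", "SVM"),
                list(PLSR = data.frame(n_components = 4L),
                     SVM = reducedGrids()$SVM[1, ]), seed = 2)
  expect_error(predict(m, lp$X[, -1]), "schema")
  extra <- cbind(lp$X, junk = 1)
  expect_error(predict(m, extra), "schema")
  expect_length(predict(m, lp$X[1, , drop = FALSE]), 1)
  perm <- sample(nrow(lp$X))
  expect_equal(predict(m, lp$X[perm, ]), predict(m, lp$X)[perm],
               tolerance = 1e-12)
  expect_identical(modelFeatures(m), colnames(lp$X))
  expect_length(metaCoefficients(m), 3)
})

test_that("nested CV recovers signal, rejects null labels, reproduces", {
  lp <- linearProblem(n = 50, noise = 0)
  g <- list(PLSR = data.frame(n_components = 6L),
            GBDT = reducedGrids()$GBDT[1, ])
  ev <- nestedCvEvaluate(lp$X, lp$y, c("PLSR", "GBDT"), g,
                         outer_k = 5, seed = 13)
  expect_gte(ev$aggregate$mean[ev$aggregate$metric == "r2"], 0.999)
  expect_equal(nrow(ev$per_fold), 5)
  ev2 <- nestedCvEvaluate(lp$X, lp$y, c("PLSR", "GBDT"), g,
                          outer_k = 5, seed = 13)
  expect_identical(ev$per_fold, ev2$per_fold)
  # a permuted response carries no transferable signal
  y_null <- sample(lp$y)
  evn <- nestedCvEvaluate(lp$X, y_null, c("PLSR", "GBDT"), g,
                          outer_k = 5, seed = 13)
  expect_lt(evn$aggregate$mean[evn$aggregate$metric == "r2"], 0.3)
})

test_that("outer-fold predictions are immune to own-fold label corruption", {
  lp <- linearProblem(n = 40, noise = 0.05)
  g <- list(PLSR = data.frame(n_components = 4L),
            GBDT = reducedGrids()$GBDT[1, ])
  ev1 <- nestedCvEvaluate(lp$X, lp$y, c("PLSR", "GBDT"), g,
                          outer_k = 4, seed = 17)
  f1 <- ev1$folds[, 1] == 1L
  y_bad <- lp$y
  y_bad[f1] <- 7  # constant garbage in fold 1's labels
  ev2 <- nestedCvEvaluate(lp$X, y_bad, c("PLSR", "GBDT"), g,
                          outer_k = 4, seed = 17)
  # fold 1's model is trained on folds 2..4 only, so its held-out
  # predictions cannot move when fold 1's labels are corrupted
  expect_equal(ev2$predictions[f1, 1], ev1$predictions[f1, 1],
               tolerance = 1e-10)
  # and the corruption does change what the other folds see
  expect_false(isTRUE(all.equal(ev2$predictions[!f1, 1],
                                ev1$predictions[!f1, 1])))
})

test_that("the stack is at least as good as its weaker base learner", {
  ft <- smallFeatures()
  X <- as.matrix(ft[, defaultVIInputs()])
  y <- ft$lai_true
  sp <- sortedSplit(y, 1 / 3)
  g <- reducedGrids()
  stack <- fitStack(X[sp$modeling_idx, ], y[sp$modeling_idx],
                    c("PLSR", "GBDT"), g, seed = 20)
  r2_stack <- laiMetrics(y[sp$validation_idx],
                         predict(stack, X[sp$validation_idx, ]))$r2
  r2_base <- vapply(c("PLSR", "GBDT"), function(lrn) {
    tb <- tuneBase(lrn, X[sp$modeling_idx, ], y[sp$modeling_idx],
                   g[[lrn]], seed = 20)
    laiMetrics(y[sp$validation_idx],
               canopyLAI:::predictLearner(tb$model,
                                          X[sp$validation_idx, ]))$r2
  }, numeric(1))
  expect_gte(r2_stack, min(r2_base) - 0.02)
})
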