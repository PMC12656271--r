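# Shared fixtures, built once per test run. The small experiment keeps
# unit tests fast; the full-scale comparisons are cached because several
# acceptance checks reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memoFixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

smallDesign <- function(seed = 7L)
  experimentDesign(replicates = 2, dates = 3, image_size = 48, seed = seed)

smallExperiment <- function()
  memoFixture("small_exp", generateExperiment(smallDesign()))

smallFeatures <- function()
  memoFixture("small_feat", buildFeatureTable(smallExperiment()))

# Full-scale (36 plots x 5 dates, 128 px) PLSR+GBDT comparison over the
# three nested feature sets, with the reduced tuning grids.
fullComparison <- function(seed) {
  memoFixture(paste0("cmp_", seed),
              compareFeatureSets(pipelineConfig(seed = seed),
                                 pairs = "GBDT"))
}

# A small noiseless linear regression problem for exact-fit limit checks.
linearProblem <- function(n = 50, p = 6, seed = 3, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  beta <- seq_len(p) / p
  list(X = X, y = as.numeric(X %*% beta + rnorm(n, 0, noise)))
}
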