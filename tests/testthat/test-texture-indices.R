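# Texture-index formulas, candidate enumeration and correlation ranking.

test_that("index formulas match direct arithmetic", {
  tf <- data.frame(a = 0.6, b = 0.2, c = 0.3)
  expect_equal(evaluateIndex(textureIndexSpec("NDTI", c("a", "b")), tf), 0.5)
  expect_equal(evaluateIndex(textureIndexSpec("DTI", c("a", "b")), tf), 0.4)
  expect_equal(evaluateIndex(textureIndexSpec("RTI", c("a", "b")), tf), 3.0)
  tf3 <- data.frame(a = 1.0, b = 0.3, c = 0.2)
  expect_equal(evaluateIndex(textureIndexSpec("DTTI", c("a", "b", "c")),
                             tf3), 0.5)
  expect_equal(evaluateIndex(textureIndexSpec("NDTTI", c("a", "b", "c")),
                             tf3), 0.5 / 1.5)
  expect_equal(evaluateIndex(textureIndexSpec("RTTI", c("a", "b", "c")),
                             tf3), 1 / 0.06)
  same <- data.frame(a = 0.4, b = 0.4)
  expect_equal(evaluateIndex(textureIndexSpec("NDTI", c("a", "b")), same), 0)
  expect_equal(evaluateIndex(textureIndexSpec("DTI", c("a", "b")), same), 0)
  expect_equal(evaluateIndex(textureIndexSpec("RTI", c("a", "b")), same), 1)
  # randomized formula suite
  set.seed(5)
  for (i in 1:1000) {
    v <- runif(3, 0.05, 2)
    tfr <- data.frame(a = v[1], b = v[2], c = v[3])
    expect_equal(evaluateIndex(textureIndexSpec("NDTI", c("a", "b")), tfr),
                 (v[1] - v[2]) / (v[1] + v[2]))
    expect_equal(evaluateIndex(textureIndexSpec("NDTTI", c("a", "b", "c")),
                               tfr),
                 (v[1] - v[2] - v[3]) / (v[1] + v[2] + v[3]))
    expect_equal(evaluateIndex(textureIndexSpec("RTTI", c("a", "b", "c")),
                               tfr), v[1] / (v[2] * v[3]))
  }
})

test_that("antisymmetry and boundedness properties hold", {
  set.seed(9)
  for (i in 1:200) {
    v <- runif(3, 0.01, 3)
    tf <- data.frame(a = v[1], b = v[2], c = v[3])
    ndti_ab <- evaluateIndex(textureIndexSpec("NDTI", c("a", "b")), tf)
    ndti_ba <- evaluateIndex(textureIndexSpec("NDTI", c("b", "a")), tf)
    expect_equal(ndti_ab, -ndti_ba)
    expect_equal(evaluateIndex(textureIndexSpec("DTI", c("a", "b")), tf),
                 -evaluateIndex(textureIndexSpec("DTI", c("b", "a")), tf))
    expect_equal(evaluateIndex(textureIndexSpec("RTI", c("a", "b")), tf),
                 1 / evaluateIndex(textureIndexSpec("RTI", c("b", "a")), tf))
    expect_true(abs(ndti_ab) <= 1)
    ndtti <- evaluateIndex(textureIndexSpec("NDTTI", c("a", "b", "c")), tf)
    expect_true(ndtti >= -1 && ndtti <= 1)
  }
  # T2 <-> T3 symmetry of the 3-D families
  tf <- data.frame(a = 1.2, b = 0.4, c = 0.9)
  for (ty in c("NDTTI", "DTTI", "RTTI"))
    expect_equal(evaluateIndex(textureIndexSpec(ty, c("a", "b", "c")), tf),
                 evaluateIndex(textureIndexSpec(ty, c("a", "c", "b")), tf))
})

test_that("zero denominators yield missing values", {
  tf <- data.frame(a = c(0.5, 0.5), b = c(-0.5, 0.2), c = c(0.1, 0))
  expect_true(is.na(evaluateIndex(textureIndexSpec("NDTI", c("a", "b")),
                                  tf)[1]))
  expect_true(is.na(evaluateIndex(textureIndexSpec("RTTI",
                                                   c("a", "b", "c")),
                                  tf)[2]))
})

test_that("candidate enumeration counts and symmetry dedup are exact", {
  expect_length(enumerateCandidates(c("a", "b"), "NDTI"), 2)
  expect_length(enumerateCandidates(c("a", "b", "c"), "NDTTI"), 3)
  pool <- paste0("t", 1:10)
  all6 <- enumerateCandidates(pool)
  # 2-D: 3 families x 10*9 ordered pairs; 3-D: 3 families x 10*9*8/2
  expect_length(all6, 3 * 90 + 3 * 360)
  # brute-force check: no two retained 3-D specs are T2<->T3 duplicates
  keys <- vapply(all6, function(sp) {
    cmp <- sp@components
    if (length(cmp) == 3) cmp <- c(cmp[1], sort(cmp[2:3]))
    paste(sp@indexType, paste(cmp, collapse = ","))
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_error(enumerateCandidates(c("a", "b"), "NDTTI"), "at least 3")
  expect_error(textureIndexSpec("NDTI", c("a", "a")))
  expect_error(textureIndexSpec("XTI", c("a", "b")))
})

test_that("ranking equals a brute-force recomputation of all correlations", {
  set.seed(21)
  n <- 60
  tf <- data.frame(a = runif(n), b = runif(n), c = runif(n),
                   d = runif(n))
  lai <- 2 * tf$a - tf$b + rnorm(n, 0, 0.3)
  cand <- enumerateCandidates(names(tf))
  got <- selectTopIndices(cand, tf, lai, k = 5)
  # independent oracle: evaluate every candidate formula by hand and rank
  oracle <- do.call(rbind, lapply(cand, function(sp) {
    cmp <- sp@components
    T1 <- tf[[cmp[1]]]; T2 <- tf[[cmp[2]]]
    T3 <- if (length(cmp) == 3) tf[[cmp[3]]] else NULL
    v <- switch(sp@indexType,
                NDTI = (T1 - T2) / (T1 + T2), DTI = T1 - T2,
                RTI = T1 / T2,
                NDTTI = (T1 - T2 - T3) / (T1 + T2 + T3),
                DTTI = T1 - T2 - T3, RTTI = T1 / (T2 * T3))
    ok <- is.finite(v)
    ct <- cor.test(v[ok], lai[ok])
    data.frame(type = sp@indexType,
               comp = paste(cmp, collapse = ";"),
               r = unname(ct$estimate), p = ct$p.value)
  }))
  oracle <- oracle[oracle$p < 0.05, ]
  oracle <- oracle[order(-abs(oracle$r), oracle$type, oracle$comp), ]
  expect_equal(got$table$r[1:5], oracle$r[1:5], tolerance = 1e-12)
  expect_identical(got$table$components[1:5], oracle$comp[1:5])
})

test_that("degenerate and perfect candidates are handled", {
  n <- 40
  set.seed(2)
  lai <- runif(n, 1, 5)
  tf <- data.frame(x = lai, z = rep(0, n), w = runif(n))
  cand <- list(textureIndexSpec("DTI", c("x", "z")),   # equals lai: r = 1
               textureIndexSpec("DTI", c("z", "z2")),  # constant
               textureIndexSpec("NDTI", c("w", "x")))
  tf$z2 <- rep(0, n)
  got <- selectTopIndices(cand, tf, lai, k = 2)
  expect_equal(got$table$r[1], 1, tolerance = 1e-12)
  expect_identical(got$table$components[1], "x;z")
  expect_false("z;z2" %in% got$table$components)  # dropped: undefined r
})
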