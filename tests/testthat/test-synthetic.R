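# Synthetic canopy generator: LAI trajectories, scene rendering, and the
# statistical structure downstream stages rely on.

test_that("expected LAI peaks at early grain filling under D3N2", {
  grid <- expand.grid(d = c("D1", "D2", "D3"),
                      n = c("N0", "N1", "N2", "N3"), t = 1:5,
                      stringsAsFactors = FALSE)
  grid$mu <- mapply(expectedLai, grid$d, grid$n, grid$t)
  top <- grid[which.max(grid$mu), ]
  expect_equal(top$d, "D3")
  expect_equal(top$n, "N2")
  expect_equal(top$t, 4)
  # unimodal over dates for every treatment, peaking at date 4
  for (d in c("D1", "D2", "D3")) for (n in c("N0", "N1", "N2", "N3")) {
    mu <- sapply(1:5, function(t) expectedLai(d, n, t))
    expect_equal(which.max(mu), 4)
    expect_true(all(diff(mu[1:4]) > 0) && mu[5] < mu[4])
  }
  # mean LAI increases with density, and with nitrogen up to N2
  dens <- sapply(c("D1", "D2", "D3"),
                 function(d) mean(sapply(1:5, expectedLai,
                                         density_label = d,
                                         nitrogen_label = "N2")))
  expect_true(all(diff(dens) > 0))
  nit <- sapply(c("N0", "N1", "N2"),
                function(n) mean(sapply(1:5, expectedLai,
                                        density_label = "D3",
                                        nitrogen_label = n)))
  expect_true(all(diff(nit) > 0))
})

test_that("simulated LAI stays in range, is deterministic, rejects bad labels", {
  vals <- replicate(200, laiTrajectory(
    sample(c("D1", "D2", "D3"), 1), sample(c("N0", "N1", "N2", "N3"), 1),
    sample(1:5, 1), seed = sample(1e6, 1)))
  expect_true(all(vals >= 0.77 & vals <= 5.28))
  expect_identical(laiTrajectory("D2", "N1", 3, seed = 9),
                   laiTrajectory("D2", "N1", 3, seed = 9))
  expect_error(laiTrajectory("D9", "N1", 1), "density")
  expect_error(laiTrajectory("D1", "N9", 1), "nitrogen")
})

test_that("rendered scenes hit the Beer-Lambert gap fraction", {
  cm <- canopyModel(k_ext = 0.6, noise_sd = 0)
  s <- renderCanopy(3, cm, image_size = 128, seed = 5)
  # one disc is at most pi r^2 / 128^2 ~ 0.002 of the image, so the
  # stopping rule lands within 0.01 of the closed form
  expect_lt(abs(soilFraction(s, cm) - exp(-0.6 * 3)), 0.01)
  # near-zero LAI: almost pure soil, so ROI NDVI matches the soil NDVI
  s0 <- renderCanopy(1e-6, cm, image_size = 64, seed = 5)
  m <- extractRoiMeans(s0)
  soil_ndvi <- (cm$soil_spectrum["NIR"] - cm$soil_spectrum["R"]) /
    (cm$soil_spectrum["NIR"] + cm$soil_spectrum["R"])
  expect_lt(abs(computeVIs(m)[["NDVI"]] - soil_ndvi), 0.02)
  # soil fraction non-increasing in LAI on a fixed seed grid
  fr <- sapply(c(0.5, 1, 2, 3, 4, 5),
               function(l) soilFraction(renderCanopy(l, cm, 96, seed = 2),
                                        cm))
  expect_true(all(diff(fr) <= 0))
  expect_error(renderCanopy(2, canopyModel(blob_radius_px = 10),
                            image_size = 12), "too small")
})

test_that("generated experiments have the factorial shape", {
  e <- smallExperiment()
  d <- smallDesign()
  expect_equal(nrow(e$samples), 3 * 4 * d$replicates * d$dates)
  expect_equal(length(unique(e$samples$plot_id)), 3 * 4 * d$replicates)
  expect_equal(length(e$stacks), nrow(e$samples))
  expect_true(all(e$samples$scenario == "main"))
  tiny <- generateExperiment(experimentDesign(replicates = 1, dates = 1,
                                              image_size = 32, seed = 1))
  expect_equal(nrow(tiny$samples), 12)
})

test_that("regeneration under a fixed seed is bitwise identical", {
  d <- experimentDesign(replicates = 1, dates = 2, image_size = 32,
                        seed = 31)
  e1 <- generateExperiment(d)
  e2 <- generateExperiment(d)
  expect_identical(e1$samples, e2$samples)
  expect_identical(lapply(e1$stacks, function(s) s@bands),
                   lapply(e2$stacks, function(s) s@bands))
})

test_that("independent scenario is a genuine distribution shift", {
  d <- experimentDesign(replicates = 1, dates = 2, image_size = 32,
                        seed = 31)
  main <- generateExperiment(d)
  ind <- generateIndependentScenario(d)
  expect_equal(length(unique(ind$samples$date)), 4)
  expect_true(all(ind$samples$scenario == "independent"))
  # darker soil: mean reflectance of near-bare scenes drops
  cm <- canopyModel()
  bare_main <- renderCanopy(0.8, cm, 64, seed = 3)
  cm_dark <- cm; cm_dark$soil_spectrum <- cm$soil_spectrum * 0.8
  bare_ind <- renderCanopy(0.8, cm_dark, 64, seed = 3)
  expect_lt(mean(bare_ind@bands), mean(bare_main@bands))
  # disjoint seed streams: no stack coincides with a main-scenario stack
  for (k in seq_along(ind$stacks))
    expect_false(any(vapply(main$stacks, function(s)
      identical(s@bands, ind$stacks[[k]]@bands), logical(1))))
})

test_that("reflectance and gap fraction carry a monotone LAI signal", {
  ft <- smallFeatures()
  e <- smallExperiment()
  expect_gt(cor(ft$NIR, ft$lai_true), 0.5)
  sf <- vapply(e$stacks, soilFraction, numeric(1))
  expect_lt(cor(sf, e$samples$lai_true), -0.5)
})

test_that("band stacks round-trip through five-band TIFF files", {
  s <- smallExperiment()$stacks[[1]]
  path <- withr::local_tempfile(fileext = ".tif")
  writeBandStack(s, path)
  s2 <- readBandStack(path)
  expect_equal(s2@bands, s@bands, tolerance = 1e-6)
  rec <- withr::local_tempfile(fileext = ".csv")
  writeSampleRecords(smallExperiment()$samples, rec)
  back <- read.csv(rec)
  expect_identical(names(back), c("plot_id", "density", "nitrogen",
                                  "replicate", "date", "scenario",
                                  "lai_true"))
  expect_equal(nrow(back), nrow(smallExperiment()$samples))
})
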