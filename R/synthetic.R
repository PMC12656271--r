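# Synthetic five-band plot imagery with known LAI. A two-endmember
# (leaf/soil) scene: leaf cover is laid down as random disc clumps until the
# visible-soil fraction matches the Beer-Lambert gap fraction exp(-k * LAI),
# then band reflectances are mixed, scaled by per-date illumination and
# perturbed by sensor noise.

# Evaluate expr under a local RNG state seeded by `seed`, restoring the
# caller's stream afterwards so generator calls are order-independent.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-stream id from a root seed and integer coordinates,
# kept inside 32-bit integer range.
subSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483629
  for (v in idx) h <- (h * 69069 + as.double(v) + 1) %% 2147483629
  as.integer(h) + 1L
}

#' Experiment design for the synthetic trial
#'
#' Describes the factorial plot layout the generator reproduces: three
#' planting densities (D1/D2/D3, 42,000 / 63,000 / 84,000 plants per ha)
#' crossed with four nitrogen rates (N0..N3, 0/80/160/240 kg N per ha),
#' replicated, imaged on several dates.
#'
#' @param densities density labels.
#' @param n_rates nitrogen-rate labels.
#' @param replicates replicate blocks per treatment.
#' @param dates number of acquisition dates.
#' @param image_size pixels per side of each plot region of interest.
#' @param seed integer root seed; the same seed regenerates the experiment
#'   bitwise-identically.
#' @return a list of class `ExperimentDesign`.
#' @examples
#' d <- experimentDesign(replicates = 1, dates = 1)
#' @export
experimentDesign <- function(densities = c("D1", "D2", "D3"),
                             n_rates = c("N0", "N1", "N2", "N3"),
                             replicates = 3L, dates = 5L,
                             image_size = 128L, seed = 42L) {
  stopifnot(replicates >= 1, dates >= 1, image_size >= 8)
  structure(list(densities = densities, n_rates = n_rates,
                 replicates = as.integer(replicates),
                 dates = as.integer(dates),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "ExperimentDesign")
}

#' Canopy radiometry model
#'
#' Two-endmember scene model: a leaf spectrum and a soil spectrum per band,
#' a Beer-Lambert extinction coefficient governing the visible-soil (gap)
#' fraction `exp(-k_ext * LAI)`, the mean leaf-clump radius, per-pixel
#' Gaussian reflectance noise, and a multiplicative illumination gain.
#' `band_gain_sd` and `noise_jitter_sd` add per-sample radiometric
#' calibration error and acquisition-quality variation (log-scale sd).
#'
#' @param k_ext extinction coefficient, in (0, 2].
#' @param leaf_spectrum,soil_spectrum length-5 reflectances in \[0, 1\]
#'   for bands B, G, R, RE, NIR.
#' @param blob_radius_px mean leaf-clump radius in pixels.
#' @param noise_sd per-pixel reflectance noise standard deviation.
#' @param illumination_gain multiplicative per-date factor.
#' @param band_gain_sd log-sd of per-sample per-band calibration gain.
#' @param noise_jitter_sd log-sd of per-sample noise-floor variation.
#' @return a list of class `CanopyModel`.
#' @export
canopyModel <- function(k_ext = 0.6,
                        leaf_spectrum = c(0.05, 0.12, 0.06, 0.35, 0.50),
                        soil_spectrum = c(0.12, 0.18, 0.22, 0.26, 0.30),
                        blob_radius_px = 3, noise_sd = 0.01,
                        illumination_gain = 1,
                        band_gain_sd = 0.03, noise_jitter_sd = 0.25) {
  stopifnot(k_ext > 0, k_ext <= 2,
            length(leaf_spectrum) == 5, length(soil_spectrum) == 5,
            all(leaf_spectrum >= 0 & leaf_spectrum <= 1),
            all(soil_spectrum >= 0 & soil_spectrum <= 1),
            blob_radius_px >= 1, noise_sd >= 0)
  structure(list(k_ext = k_ext,
                 leaf_spectrum = stats::setNames(leaf_spectrum, BAND_NAMES),
                 soil_spectrum = stats::setNames(soil_spectrum, BAND_NAMES),
                 blob_radius_px = blob_radius_px, noise_sd = noise_sd,
                 illumination_gain = illumination_gain,
                 band_gain_sd = band_gain_sd,
                 noise_jitter_sd = noise_jitter_sd),
            class = "CanopyModel")
}

# Treatment effect multipliers and the seasonal shape. The season curve
# rises to a peak at the early grain-filling date (date 4 of 5) and then
# declines; density and nitrogen scale the amplitude, with the response to
# nitrogen saturating above N2 so D3N2 attains the maximum expected LAI.
DENSITY_MULT <- c(D1 = 0.62, D2 = 0.80, D3 = 1.00)
NITROGEN_MULT <- c(N0 = 0.55, N1 = 0.78, N2 = 1.00, N3 = 0.93)
LAI_RANGE <- c(0.77, 5.28)
LAI_PEAK_DATE <- 4

seasonCurve <- function(t, peak = LAI_PEAK_DATE, shape = 3) {
  (t / peak)^shape * exp(shape * (1 - t / peak))
}

#' Expected (noise-free) LAI for a treatment and date
#'
#' @param density_label,nitrogen_label treatment labels (D1..D3, N0..N3).
#' @param date_index acquisition date index (1-based).
#' @return expected LAI in m2/m2.
#' @export
expectedLai <- function(density_label, nitrogen_label, date_index) {
  if (!density_label %in% names(DENSITY_MULT))
    stop("unknown density label: ", density_label)
  if (!nitrogen_label %in% names(NITROGEN_MULT))
    stop("unknown nitrogen label: ", nitrogen_label)
  amp <- DENSITY_MULT[[density_label]] * NITROGEN_MULT[[nitrogen_label]]
  LAI_RANGE[1] + diff(LAI_RANGE) * amp * seasonCurve(date_index)
}

#' Simulate a plot-date LAI value
#'
#' Unimodal seasonal trajectory (rising to the early grain-filling date,
#' then declining) scaled by density and nitrogen multipliers, with
#' lognormal plot-level noise (additive on the log scale), clipped to the
#' configured range \[0.77, 5.28\].
#'
#' @inheritParams expectedLai
#' @param seed integer seed; identical arguments and seed give identical
#'   values.
#' @param noise_sd log-scale plot noise sd (0 gives the expected value).
#' @return simulated LAI in m2/m2.
#' @examples
#' laiTrajectory("D3", "N2", 4, seed = 1)
#' @export
laiTrajectory <- function(density_label, nitrogen_label, date_index,
                          seed = 42L, noise_sd = 0.08) {
  if (date_index < 1) stop("date_index must be >= 1")
  mu <- expectedLai(density_label, nitrogen_label, date_index)
  if (noise_sd > 0) {
    di <- match(density_label, names(DENSITY_MULT))
    ni <- match(nitrogen_label, names(NITROGEN_MULT))
    eps <- withSeed(subSeed(seed, di, ni, date_index),
                    rnorm(1, 0, noise_sd))
    mu <- mu * exp(eps)
  }
  min(max(mu, LAI_RANGE[1]), LAI_RANGE[2])
}

# Stamp one disc of radius r at integer center (cr, cc) into logical mask.
stampDisc <- function(mask, cr, cc, r) {
  n <- nrow(mask)
  rows <- max(1, cr - r):min(n, cr + r)
  cols <- max(1, cc - r):min(ncol(mask), cc + r)
  dr <- outer((rows - cr)^2, (cols - cc)^2, "+")
  mask[rows, cols] <- mask[rows, cols] | (dr <= r^2)
  mask
}

#' Render a synthetic five-band canopy scene
#'
#' Places leaf clumps (discs of roughly `blob_radius_px`) at random until
#' the visible-soil fraction reaches the Beer-Lambert gap fraction
#' `exp(-k_ext * lai_true)`, mixes leaf and soil spectra per band, applies
#' the illumination gain and per-pixel Gaussian noise, and clips to
#' \[0, 1\].
#'
#' @param lai_true true LAI (> 0).
#' @param canopy_model a [canopyModel()].
#' @param image_size pixels per side.
#' @param seed integer seed.
#' @return a [BandStack-class].
#' @examples
#' s <- renderCanopy(3, canopyModel(), image_size = 64, seed = 1)
#' imageSize(s)
#' @export
renderCanopy <- function(lai_true, canopy_model = canopyModel(),
                         image_size = 128L, seed = 42L) {
  stopifnot(lai_true > 0)
  cm <- canopy_model
  r <- max(1L, as.integer(round(cm$blob_radius_px)))
  if (image_size < 2 * r + 1)
    stop("image too small to place a single leaf clump")
  target <- exp(-cm$k_ext * lai_true)
  withSeed(seed, {
    mask <- matrix(FALSE, image_size, image_size)
    npix <- image_size^2
    # expected disc count, used only to pre-draw random centers in bulk
    nmax <- ceiling(-log(target) * npix / (pi * r^2) * 3) + 10
    crs <- sample.int(image_size, nmax, replace = TRUE)
    ccs <- sample.int(image_size, nmax, replace = TRUE)
    k <- 0
    while (sum(!mask) / npix > target && k < nmax) {
      k <- k + 1
      mask <- stampDisc(mask, crs[k], ccs[k], r)
    }
    gain <- cm$illumination_gain
    if (length(gain) == 1) gain <- rep(gain, 5)
    arr <- array(NA_real_, c(image_size, image_size, 5),
                 dimnames = list(NULL, NULL, BAND_NAMES))
    for (b in seq_len(5)) {
      ref <- ifelse(mask, cm$leaf_spectrum[b], cm$soil_spectrum[b])
      ref <- ref * gain[b] + rnorm(npix, 0, cm$noise_sd)
      arr[, , b] <- pmin(pmax(ref, 0), 1)
    }
    bandStack(arr)
  })
}

#' Visible-soil (gap) fraction of a rendered scene
#'
#' Classifies pixels as soil where the NIR band lies closer to the soil
#' than to the leaf NIR reflectance; on noiseless unit-gain scenes this
#' recovers the exact disc mask complement.
#'
#' @param stack a [BandStack-class].
#' @param canopy_model the [canopyModel()] the scene was rendered under.
#' @return fraction of soil-visible pixels in \[0, 1\].
#' @export
soilFraction <- function(stack, canopy_model = canopyModel()) {
  nir <- getBand(stack, "NIR")
  thr <- mean(c(canopy_model$leaf_spectrum["NIR"],
                canopy_model$soil_spectrum["NIR"]))
  mean(nir < thr)
}

makeSampleTable <- function(design, scenario) {
  g <- expand.grid(replicate = seq_len(design$replicates),
                   nitrogen = design$n_rates,
                   density = design$densities,
                   stringsAsFactors = FALSE)
  g$plot_id <- sprintf("%s%s_r%d", g$density, g$nitrogen, g$replicate)
  out <- merge(g, data.frame(date = seq_len(design$dates)), by = NULL)
  out$scenario <- scenario
  out[order(out$plot_id, out$date),
      c("plot_id", "density", "nitrogen", "replicate", "date", "scenario")]
}

generateScenario <- function(design, canopy_model, scenario,
                             seed_offset = 0L) {
  cm <- canopy_model
  root <- subSeed(design$seed, seed_offset)
  gains <- withSeed(subSeed(root, 1L),
                    runif(design$dates, 0.9, 1.1))
  samples <- makeSampleTable(design, scenario)
  samples$lai_true <- NA_real_
  stacks <- vector("list", nrow(samples))
  names(stacks) <- sprintf("%s:d%d", samples$plot_id, samples$date)
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    di <- match(s$density, design$densities)
    ni <- match(s$nitrogen, design$n_rates)
    plot_seed <- subSeed(root, di, ni, s$replicate, s$date)
    lai <- laiTrajectory(s$density, s$nitrogen, s$date,
                         seed = subSeed(plot_seed, 1L))
    # replicate-level spread on top of the treatment trajectory
    lai <- lai * exp(withSeed(subSeed(plot_seed, 2L), rnorm(1, 0, 0.05)))
    lai <- min(max(lai, LAI_RANGE[1]), LAI_RANGE[2])
    samples$lai_true[i] <- lai
    pert <- withSeed(subSeed(plot_seed, 3L), {
      list(band_gain = exp(rnorm(5, 0, cm$band_gain_sd)),
           noise_mult = exp(rnorm(1, 0, cm$noise_jitter_sd)))
    })
    cm_i <- cm
    cm_i$illumination_gain <- gains[s$date] * pert$band_gain
    cm_i$noise_sd <- cm$noise_sd * pert$noise_mult
    stacks[[i]] <- renderCanopy(lai, cm_i, design$image_size,
                                seed = subSeed(plot_seed, 4L))
  }
  rownames(samples) <- NULL
  list(samples = samples, stacks = stacks)
}

#' Generate the full synthetic experiment
#'
#' One sample (plot-date) per plot per acquisition date; per-date
#' illumination gain is drawn uniformly in \[0.9, 1.1\] to emulate
#' acquisition differences between flights.
#'
#' @param design an [experimentDesign()].
#' @param canopy_model a [canopyModel()].
#' @return list with `samples` (data.frame: plot_id, density, nitrogen,
#'   replicate, date, scenario, lai_true) and `stacks` (named list of
#'   [BandStack-class], keyed `plot_id:dN`).
#' @examples
#' e <- generateExperiment(experimentDesign(replicates = 1, dates = 1,
#'                                          image_size = 32))
#' nrow(e$samples)
#' @export
generateExperiment <- function(design = experimentDesign(),
                               canopy_model = canopyModel()) {
  generateScenario(design, canopy_model, "main", seed_offset = 0L)
}

#' Generate the distribution-shifted independent scenario
#'
#' A second trial for external validation: four acquisition dates, darker
#' soil (spectrum scaled by `soil_darken`) and a higher noise floor
#' (`noise_inflate`), drawn from seeds disjoint from the main scenario.
#'
#' @inheritParams generateExperiment
#' @param soil_darken multiplier (< 1) on the soil spectrum.
#' @param noise_inflate multiplier (> 1) on `noise_sd`.
#' @return same shape as [generateExperiment()], scenario = "independent".
#' @export
generateIndependentScenario <- function(design = experimentDesign(dates = 4L),
                                        canopy_model = canopyModel(),
                                        soil_darken = 0.8,
                                        noise_inflate = 1.5) {
  design$dates <- 4L
  cm <- canopy_model
  cm$soil_spectrum <- cm$soil_spectrum * soil_darken
  cm$noise_sd <- cm$noise_sd * noise_inflate
  generateScenario(design, cm, "independent", seed_offset = 104729L)
}

#' Write a BandStack as a five-band TIFF (band order B, G, R, RE, NIR)
#'
#' @param stack a [BandStack-class].
#' @param path output file path.
#' @export
writeBandStack <- function(stack, path) {
  imgs <- lapply(BAND_NAMES, function(b) getBand(stack, b))
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a five-band TIFF written by [writeBandStack()]
#'
#' @param path file path.
#' @return a [BandStack-class].
#' @export
readBandStack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (length(imgs) != 5) stop("expected a five-band TIFF")
  names(imgs) <- BAND_NAMES
  bandStack(imgs)
}

#' Write sample records as CSV
#'
#' Header: plot_id, density, nitrogen, replicate, date, scenario, lai_true.
#' @param samples data.frame as produced by [generateExperiment()].
#' @param path output file path.
#' @export
writeSampleRecords <- function(samples, path) {
  write.csv(samples[, c("plot_id", "density", "nitrogen", "replicate",
                        "date", "scenario", "lai_true")],
            path, row.names = FALSE)
  invisible(path)
}
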