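# GLCM texture features: per-band quantization, co-occurrence matrices,
# the eight Haralick-style metrics, and the sliding-window engine that
# averages window-level metrics over a plot ROI (compiled backend).

#' Quantize a band to integer gray levels
#'
#' Linear min-max mapping of the values onto 0..levels-1
#' (`floor((v - min)/(max - min) * levels)` clipped to `levels - 1`).
#' A constant band maps entirely to level 0.
#'
#' @param band_array numeric matrix.
#' @param levels number of gray levels (>= 2).
#' @return integer matrix of levels in 0..levels-1.
#' @examples
#' quantizeBand(matrix(c(0, 0.5, 1, 1), 2), levels = 2)
#' @export
quantizeBand <- function(band_array, levels = 32L) {
  stopifnot(levels >= 2)
  rng <- range(band_array)
  if (rng[1] == rng[2])
    return(matrix(0L, nrow(band_array), ncol(band_array)))
  lv <- floor((band_array - rng[1]) / (rng[2] - rng[1]) * levels)
  mode(lv) <- "integer"
  lv[lv > levels - 1L] <- levels - 1L
  matrix(lv, nrow(band_array), ncol(band_array))
}

#' Gray-level co-occurrence matrix of a window
#'
#' Counts ordered pairs of a pixel at (row, col) with the pixel at
#' (row + dy, col + dx) inside the window; with `symmetric = TRUE` each
#' pair is counted in both orders. Counts are normalized to sum to 1.
#'
#' @param level_window integer matrix of gray levels (0-based).
#' @param offset integer (dx, dy) displacement; dx shifts columns, dy rows.
#' @param symmetric count pairs in both orders.
#' @param levels gray-level count (defaults to max level + 1).
#' @return list of class `CooccurrenceMatrix`: `p` (levels x levels
#'   probability matrix), `levels`, `offset`, `symmetric`.
#' @examples
#' cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
#' computeGlcm(cb, offset = c(1, 0))$p
#' @export
computeGlcm <- function(level_window, offset = c(1, 1), symmetric = TRUE,
                        levels = max(level_window) + 1L) {
  dx <- offset[1]; dy <- offset[2]
  nr <- nrow(level_window); nc <- ncol(level_window)
  rows <- seq_len(nr); rows <- rows[rows + dy >= 1 & rows + dy <= nr]
  cols <- seq_len(nc); cols <- cols[cols + dx >= 1 & cols + dx <= nc]
  if (length(rows) == 0 || length(cols) == 0)
    stop("window contains no valid pixel pair at this offset")
  p <- matrix(0, levels, levels)
  for (r in rows) for (cc in cols) {
    a <- level_window[r, cc] + 1L
    b <- level_window[r + dy, cc + dx] + 1L
    p[a, b] <- p[a, b] + 1
    if (symmetric) p[b, a] <- p[b, a] + 1
  }
  structure(list(p = p / sum(p), levels = as.integer(levels),
                 offset = c(dx = dx, dy = dy), symmetric = symmetric),
            class = "CooccurrenceMatrix")
}

#' The eight GLCM texture metrics
#'
#' With marginal means `mu_i = sum(i p(i,j))`, `mu_j` analogous and
#' `sigma_i`, `sigma_j` their standard deviations (gray levels indexed
#' from 0): mean = mu_i; var = sum((i - mu_i)^2 p);
#' hom = sum(p / (1 + (i - j)^2)); con = sum((i - j)^2 p);
#' dis = sum(|i - j| p); et = -sum(p log p) (0 log 0 := 0);
#' sem = sum(p^2) (angular second moment);
#' cor = sum((i - mu_i)(j - mu_j) p) / (sigma_i sigma_j), 0 when
#' `sigma_i * sigma_j = 0`.
#'
#' @param g a [computeGlcm()] result, or a bare probability matrix.
#' @return named numeric vector `mean, var, hom, con, dis, et, sem, cor`.
#' @examples
#' cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
#' glcmMetrics(computeGlcm(cb, offset = c(1, 0)))
#' @export
glcmMetrics <- function(g) {
  p <- if (inherits(g, "CooccurrenceMatrix")) g$p else g
  n <- nrow(p)
  i <- matrix(0:(n - 1), n, n)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  d <- i - j
  et <- -sum(ifelse(p > 0, p * log(p), 0))
  sds <- sqrt(var_i) * sqrt(var_j)
  cr <- if (sds > 0) sum((i - mu_i) * (j - mu_j) * p) / sds else 0
  c(mean = mu_i, var = var_i,
    hom = sum(p / (1 + d^2)), con = sum(d^2 * p),
    dis = sum(abs(d) * p), et = et, sem = sum(p^2), cor = cr)
}

#' Sliding-window GLCM texture features for one band
#'
#' Quantizes the band, slides a `window` x `window` frame over it at the
#' given stride, computes the eight metrics of the window GLCM at the
#' single (dx, dy) offset, and averages each metric over all positions.
#'
#' @param band_array numeric matrix (one band of a ROI).
#' @param window window side in pixels.
#' @param offset integer (dx, dy) displacement.
#' @param levels gray levels for quantization.
#' @param symmetric symmetric pair counting.
#' @param stride window step; `stride = window` tiles in blocks.
#' @return named numeric vector of the 8 window-averaged metrics.
#' @export
bandTextureFeatures <- function(band_array, window = 4L, offset = c(1, 1),
                                levels = 32L, symmetric = TRUE,
                                stride = 1L) {
  lv <- quantizeBand(band_array, levels)
  .glcmWindowMeansCpp(lv, as.integer(window), as.integer(offset[1]),
                      as.integer(offset[2]), isTRUE(symmetric),
                      as.integer(stride))
}

#' The 40 GLCM texture features of a plot sample
#'
#' Applies [bandTextureFeatures()] to each of the five bands of the ROI and
#' concatenates the results into 40 named features `<band>_<metric>`
#' (e.g. `B_var`, `NIR_cor`).
#'
#' @param stack a [BandStack-class].
#' @param inner_buffer_frac ROI trim fraction as in [extractRoiMeans()].
#' @param window,offset,levels,symmetric,stride see
#'   [bandTextureFeatures()].
#' @return named numeric vector of 40 texture features.
#' @examples
#' s <- renderCanopy(2, image_size = 32, seed = 1)
#' tf <- textureFeaturesForSample(s)
#' length(tf)
#' @export
textureFeaturesForSample <- function(stack, inner_buffer_frac = 0,
                                     window = 4L, offset = c(1, 1),
                                     levels = 32L, symmetric = TRUE,
                                     stride = 1L) {
  d <- imageSize(stack)
  tr <- floor(d[1] * inner_buffer_frac)
  tc <- floor(d[2] * inner_buffer_frac)
  rows <- (tr + 1):(d[1] - tr)
  cols <- (tc + 1):(d[2] - tc)
  if (length(rows) < window || length(cols) < window)
    stop("ROI smaller than the texture window")
  out <- numeric(0)
  for (b in BAND_NAMES) {
    m <- bandTextureFeatures(stack@bands[rows, cols, b], window, offset,
                             levels, symmetric, stride)
    names(m) <- paste(b, TF_METRICS, sep = "_")
    out <- c(out, m)
  }
  out
}

#' Texture features used as the default model-input and index pool
#'
#' The ten texture features with the strongest LAI association in the
#' reference configuration: blue-band var, mean, con, dis, cor; red-band
#' var, con, dis; NIR-band cor; green-band con.
#' @return character vector of 10 feature names.
#' @export
defaultTFInputs <- function() {
  c("B_var", "B_mean", "B_con", "B_dis", "B_cor",
    "R_var", "R_con", "R_dis", "NIR_cor", "G_con")
}
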