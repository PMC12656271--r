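# Region-of-interest band means and the eleven vegetation indices.

#' Mean reflectance per band over a centered region of interest
#'
#' Trims `inner_buffer_frac` of each dimension from every side (avoiding
#' plot edges) and averages each band over the remaining sub-window.
#'
#' @param stack a [BandStack-class].
#' @param inner_buffer_frac fraction in \[0, 0.5) trimmed from each side.
#' @return named numeric vector `B, G, R, RE, NIR` of means in \[0, 1\].
#' @examples
#' s <- renderCanopy(2, image_size = 32, seed = 1)
#' extractRoiMeans(s, 0.1)
#' @export
extractRoiMeans <- function(stack, inner_buffer_frac = 0) {
  stopifnot(inner_buffer_frac >= 0, inner_buffer_frac < 0.5)
  d <- imageSize(stack)
  tr <- floor(d[1] * inner_buffer_frac)
  tc <- floor(d[2] * inner_buffer_frac)
  rows <- (tr + 1):(d[1] - tr)
  cols <- (tc + 1):(d[2] - tc)
  if (length(rows) < 1 || length(cols) < 1)
    stop("ROI empty after trimming")
  vapply(BAND_NAMES,
         function(b) mean(stack@bands[rows, cols, b]),
         numeric(1))
}

#' Compute the eleven vegetation indices from band means
#'
#' GNDVI = (NIR-G)/(NIR+G); NDVI = (NIR-R)/(NIR+R); DVI = NIR-R;
#' RVI = NIR/R; OSAVI = 1.16(NIR-R)/(NIR+R+0.16);
#' SAVI = 1.5(NIR-R)/(NIR+R+0.5); EVI = 2.5(NIR-R)/(NIR+6R-7.5B+1);
#' VARI = (G-R)/(G+R-B); EXG = 2G-R-B; EXR = 1.4R-G;
#' CIRE = (NIR/RE)-1.
#'
#' A ratio index whose denominator is zero is returned as `NA` and listed
#' in the `"flagged"` attribute rather than yielding an infinity.
#'
#' @param m named band means as returned by [extractRoiMeans()].
#' @return named numeric vector of the 11 indices, attribute `flagged`
#'   naming any index with a zero denominator.
#' @examples
#' computeVIs(c(B = 0.05, G = 0.1, R = 0.2, RE = 0.4, NIR = 0.6))
#' @export
computeVIs <- function(m) {
  stopifnot(all(BAND_NAMES %in% names(m)))
  B <- m[["B"]]; G <- m[["G"]]; R <- m[["R"]]
  RE <- m[["RE"]]; NIR <- m[["NIR"]]
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  v <- c(GNDVI = safe(NIR - G, NIR + G),
         NDVI  = safe(NIR - R, NIR + R),
         DVI   = NIR - R,
         RVI   = safe(NIR, R),
         OSAVI = safe(1.16 * (NIR - R), NIR + R + 0.16),
         SAVI  = safe(1.5 * (NIR - R), NIR + R + 0.5),
         EVI   = safe(2.5 * (NIR - R), NIR + 6 * R - 7.5 * B + 1),
         VARI  = safe(G - R, G + R - B),
         EXG   = 2 * G - R - B,
         EXR   = 1.4 * R - G,
         CIRE  = if (RE == 0) NA_real_ else NIR / RE - 1)
  attr(v, "flagged") <- names(v)[is.na(v)]
  v
}

#' Vegetation indices used as default model inputs
#'
#' Ten of the eleven indices; EXG is computed and reported but excluded
#' from the default model-input set because of its weak association with
#' LAI in dense canopies.
#' @return character vector of VI names.
#' @export
defaultVIInputs <- function() {
  c("OSAVI", "SAVI", "DVI", "GNDVI", "RVI", "EVI", "NDVI",
    "CIRE", "EXR", "VARI")
}
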