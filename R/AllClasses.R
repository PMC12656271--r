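#' @import methods
#' @importFrom stats cor cor.test predict rnorm runif sd var quantile
#' @importFrom stats setNames coef
#' @importFrom utils write.csv read.csv modifyList
#' @useDynLib canopyLAI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BAND_NAMES <- c("B", "G", "R", "RE", "NIR")
TF_METRICS <- c("mean", "var", "hom", "con", "dis", "et", "sem", "cor")
VI_NAMES <- c("GNDVI", "NDVI", "DVI", "RVI", "OSAVI", "SAVI", "EVI",
              "VARI", "EXG", "EXR", "CIRE")
TI_2D <- c("NDTI", "DTI", "RTI")
TI_3D <- c("NDTTI", "DTTI", "RTTI")

#' BandStack: a five-band reflectance image for one plot-date
#'
#' Container for co-registered blue (450 nm), green (560 nm), red (650 nm),
#' red-edge (730 nm) and near-infrared (840 nm) reflectance rasters of a
#' single plot region of interest. Reflectances are unitless in \[0, 1\].
#'
#' @slot bands numeric 3-D array (rows x cols x 5) with dimnames
#'   `B, G, R, RE, NIR` on the third margin.
#' @export
setClass("BandStack", representation(bands = "array"))

setValidity("BandStack", function(object) {
  b <- object@bands
  if (length(dim(b)) != 3L || dim(b)[3] != 5L)
    return("bands must be a rows x cols x 5 array")
  if (!identical(dimnames(b)[[3]], BAND_NAMES))
    return("third margin must be named B, G, R, RE, NIR")
  if (anyNA(b) || min(b) < 0 || max(b) > 1)
    return("reflectance values must lie in [0, 1]")
  TRUE
})

#' Construct a BandStack
#'
#' @param bands either a rows x cols x 5 array or a named list of five
#'   equal-sized matrices (names `B, G, R, RE, NIR`).
#' @return a [BandStack-class] object.
#' @examples
#' m <- matrix(0.2, 8, 8)
#' s <- bandStack(list(B = m, G = m, R = m, RE = m, NIR = m))
#' bandNames(s)
#' @export
bandStack <- function(bands) {
  if (is.list(bands)) {
    if (!setequal(names(bands), BAND_NAMES))
      stop("band list must be named B, G, R, RE, NIR")
    bands <- bands[BAND_NAMES]
    d <- dim(bands[[1]])
    arr <- array(NA_real_, c(d[1], d[2], 5),
                 dimnames = list(NULL, NULL, BAND_NAMES))
    for (k in seq_len(5)) {
      if (!identical(dim(bands[[k]]), d)) stop("all bands must share a shape")
      arr[, , k] <- bands[[k]]
    }
    bands <- arr
  }
  if (is.null(dimnames(bands)[[3]])) dimnames(bands)[[3]] <- BAND_NAMES
  new("BandStack", bands = bands)
}

#' @describeIn bandStack band names (always `B, G, R, RE, NIR`)
#' @param x a `BandStack`
#' @export
bandNames <- function(x) dimnames(x@bands)[[3]]

#' @describeIn bandStack extract one band as a matrix
#' @param name band name
#' @export
getBand <- function(x, name) {
  if (!name %in% BAND_NAMES) stop("unknown band: ", name)
  x@bands[, , name]
}

#' @describeIn bandStack image dimensions (rows, cols)
#' @export
imageSize <- function(x) dim(x@bands)[1:2]

setMethod("show", "BandStack", function(object) {
  d <- dim(object@bands)
  cat(sprintf("BandStack: %d x %d px, bands %s\n", d[1], d[2],
              paste(BAND_NAMES, collapse = "/")))
  mu <- apply(object@bands, 3, mean)
  cat("  mean reflectance:",
      paste(sprintf("%s=%.3f", names(mu), mu), collapse = " "), "\n")
})

#' TextureIndexSpec: a texture-index recipe
#'
#' Identifies one member of the two-component (NDTI, DTI, RTI) or
#' three-component (NDTTI, DTTI, RTTI) texture-index families together with
#' the ordered GLCM texture features (e.g. `B_con`, `R_dis`) it combines.
#'
#' @slot indexType one of `NDTI, DTI, RTI, NDTTI, DTTI, RTTI`.
#' @slot components ordered character vector of 2 (2-D types) or 3
#'   (3-D types) distinct texture-feature names.
#' @export
setClass("TextureIndexSpec",
         representation(indexType = "character", components = "character"))

setValidity("TextureIndexSpec", function(object) {
  t <- object@indexType
  if (length(t) != 1L || !t %in% c(TI_2D, TI_3D))
    return("indexType must be one of NDTI, DTI, RTI, NDTTI, DTTI, RTTI")
  need <- if (t %in% TI_2D) 2L else 3L
  if (length(object@components) != need)
    return(sprintf("%s needs %d components", t, need))
  if (anyDuplicated(object@components))
    return("components must be distinct")
  TRUE
})

#' Construct a TextureIndexSpec
#'
#' @param indexType index family name.
#' @param components ordered texture-feature names (T1, T2\[, T3\]).
#' @return a [TextureIndexSpec-class] object.
#' @examples
#' textureIndexSpec("NDTTI", c("B_con", "B_dis", "R_dis"))
#' @export
textureIndexSpec <- function(indexType, components) {
  new("TextureIndexSpec", indexType = indexType,
      components = as.character(components))
}

setMethod("show", "TextureIndexSpec", function(object) {
  cat(sprintf("%s(%s)\n", object@indexType,
              paste(object@components, collapse = ", ")))
})

#' StackedLAIModel: a fitted PLSR + machine-learning stack
#'
#' Holds the two deployed base learners (PLSR and one of SVM / RF / GBDT),
#' their tuned hyperparameters, and the Lasso meta-model that fuses the two
#' base predictions.
#'
#' @slot pair character(2): `c("PLSR", <ml>)`.
#' @slot basePLSR fitted PLSR base learner (internal learner object).
#' @slot baseML fitted nonlinear base learner.
#' @slot metaFit list: glmnet fit, selected lambda, coefficient vector
#'   (intercept + one weight per base learner).
#' @slot tunedParams list of the chosen grid point per base learner.
#' @slot featureNames character: training feature schema.
#' @slot metaK integer: folds used for out-of-fold meta-features.
#' @slot seed integer seed controlling every stochastic choice.
#' @export
setClass("StackedLAIModel",
         representation(pair = "character", basePLSR = "list",
                        baseML = "list", metaFit = "list",
                        tunedParams = "list", featureNames = "character",
                        metaK = "integer", seed = "integer"))

setValidity("StackedLAIModel", function(object) {
  if (length(object@pair) != 2L || object@pair[1] != "PLSR")
    return("pair must be c('PLSR', <SVM|RF|GBDT>)")
  if (!object@pair[2] %in% c("SVM", "RF", "GBDT"))
    return("second base learner must be SVM, RF or GBDT")
  if (length(object@metaFit$coefficients) != 3L)
    return("meta-model must have an intercept and one weight per base")
  TRUE
})

setMethod("show", "StackedLAIModel", function(object) {
  cat(sprintf("StackedLAIModel: %s + %s (meta: Lasso)\n",
              object@pair[1], object@pair[2]))
  cat(sprintf("  features: %d  meta folds: %d  seed: %d\n",
              length(object@featureNames), object@metaK, object@seed))
  co <- object@metaFit$coefficients
  cat(sprintf("  meta coefficients: intercept=%.4f %s=%.4f %s=%.4f\n",
              co[1], object@pair[1], co[2], object@pair[2], co[3]))
})

#' @describeIn StackedLAIModel-class tuned hyperparameters per base learner
#' @param object a `StackedLAIModel`
#' @export
tunedParams <- function(object) object@tunedParams

#' @describeIn StackedLAIModel-class meta-model coefficient vector
#'   (intercept, PLSR weight, ML weight)
#' @export
metaCoefficients <- function(object) object@metaFit$coefficients

#' @describeIn StackedLAIModel-class feature schema the model expects
#' @export
modelFeatures <- function(object) object@featureNames
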