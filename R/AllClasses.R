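#' @import methods
#' @importFrom stats coef lm median pt rnorm runif sd setNames weighted.mean
#' @importFrom utils read.csv write.csv
#' @useDynLib bctdensity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Integer codes of the seven tissue classes
#'
#' Every voxel of a segmented breast CT volume carries exactly one of these
#' labels: air (background), adipose tissue, glandular tissue, skin (the
#' nipple is part of the skin class), pectoralis major muscle, rib, and the
#' skin-fold section of the thoracic or abdominal wall that reaches into the
#' field of view.
#'
#' @return Named integer vector mapping class names to label codes.
#' @export
#' @examples
#' tissueCodes()
tissueCodes <- function() {
    c(air = 0L, adipose = 1L, gland = 2L, skin = 3L,
      pectoralis = 4L, rib = 5L, skinfold = 6L)
}

.validSpacing <- function(spacing) {
    if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
        return("'spacing' must be three positive finite values (mm)")
    TRUE
}

#' CTVolume: a breast CT volume in Hounsfield units
#'
#' A 3D grid of Hounsfield unit values with isotropic or anisotropic voxel
#' spacing. The fixed axis convention is: axis 1 runs from the chest wall
#' toward the nipple (the nipple sits at the highest tissue-bearing slice,
#' the scan's most posterior slice in the prone, pendant-breast geometry),
#' axis 2 indexes image rows (low row = upper breast), axis 3 indexes image
#' columns.
#'
#' @slot hu 3D numeric array of HU values.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot laterality `"left"` or `"right"`.
#' @export
setClass("CTVolume", representation(
    hu = "array", spacing = "numeric", laterality = "character"))

setValidity("CTVolume", function(object) {
    if (length(dim(object@hu)) != 3L)
        return("'hu' must be a 3D array")
    if (anyNA(object@hu) || any(!is.finite(object@hu)))
        return("'hu' must be finite")
    v <- .validSpacing(object@spacing)
    if (!isTRUE(v)) return(v)
    if (!object@laterality %in% c("left", "right"))
        return("'laterality' must be \"left\" or \"right\"")
    TRUE
})

#' Construct a CTVolume
#'
#' @param hu 3D numeric array of Hounsfield units (axis 1: chest wall to
#'   nipple; axis 2: rows; axis 3: columns).
#' @param spacing Voxel size in mm; a single value is recycled to all axes.
#' @param laterality `"left"` or `"right"` breast.
#' @return A [CTVolume-class] object.
#' @export
ctVolume <- function(hu, spacing = 0.3, laterality = "right") {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("CTVolume", hu = hu, spacing = as.numeric(spacing),
        laterality = laterality)
}

#' LabelMap: per-voxel tissue classes
#'
#' Integer-coded tissue classification on the same grid as the source
#' [CTVolume-class]; see [tissueCodes()] for the code table. The `meta` list
#' carries segmentation diagnostics (the running-density trace, reference HU
#' means) when produced by [segmentAll()].
#'
#' @slot labels 3D integer array of class codes.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot laterality `"left"` or `"right"`.
#' @slot meta list of diagnostics.
#' @export
setClass("LabelMap", representation(
    labels = "array", spacing = "numeric", laterality = "character",
    meta = "list"))

setValidity("LabelMap", function(object) {
    if (length(dim(object@labels)) != 3L)
        return("'labels' must be a 3D array")
    if (!all(object@labels %in% tissueCodes()))
        return("'labels' contains codes outside tissueCodes()")
    v <- .validSpacing(object@spacing)
    if (!isTRUE(v)) return(v)
    TRUE
})

#' Construct a LabelMap
#'
#' @param labels 3D integer array with values from [tissueCodes()].
#' @param spacing Voxel size in mm (recycled if scalar).
#' @param laterality `"left"` or `"right"`.
#' @param meta Optional list of diagnostics.
#' @return A [LabelMap-class] object.
#' @export
labelMap <- function(labels, spacing = 0.3, laterality = "right",
                     meta = list()) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    storage.mode(labels) <- "integer"
    new("LabelMap", labels = labels, spacing = as.numeric(spacing),
        laterality = laterality, meta = meta)
}

#' QuadrantPartition: nipple landmark and quadrant assignment
#'
#' The two perpendicular planes parallel to the image rows and columns that
#' intersect the nipple split the breast-tissue voxels into the four
#' clinical quadrants: upper outer (UOQ), upper inner (UIQ), lower outer
#' (LOQ) and lower inner (LIQ). Quadrant codes in `quadrant` are
#' 1 = UOQ, 2 = UIQ, 3 = LOQ, 4 = LIQ; 0 marks non-breast-tissue voxels.
#'
#' @slot nipple integer(3) voxel coordinate (slice, row, column).
#' @slot quadrant 3D integer array of quadrant codes.
#' @slot laterality `"left"` or `"right"`.
#' @slot outerSide `"low"` or `"high"`: which column side is lateral (outer).
#' @export
setClass("QuadrantPartition", representation(
    nipple = "integer", quadrant = "array", laterality = "character",
    outerSide = "character"))

setValidity("QuadrantPartition", function(object) {
    if (length(object@nipple) != 3L)
        return("'nipple' must be a (slice, row, column) triple")
    if (!all(object@quadrant %in% 0:4))
        return("'quadrant' codes must be 0..4")
    if (!object@outerSide %in% c("low", "high"))
        return("'outerSide' must be \"low\" or \"high\"")
    TRUE
})

#' BreastComposition: volumetric composition of one breast
#'
#' Holds breast tissue volume (BTV, cm^3), mammary gland volume (MGV, cm^3)
#' and percent breast density (PBD, %) for the entire breast and each
#' quadrant, together with each quadrant's percentage share of whole-breast
#' BTV and MGV and the ratio of quadrant PBD to whole-breast PBD. PBD is
#' reported in two variants: `pbd_hu_pct`, the mean per-voxel glandular
#' fraction derived from the HU values (primary), and `pbd_vol_pct`, the
#' voxel-count ratio 100 * MGV / BTV.
#'
#' @slot table data.frame with one row per region
#'   (Entire, UOQ, UIQ, LOQ, LIQ).
#' @export
setClass("BreastComposition", representation(table = "data.frame"))

setValidity("BreastComposition", function(object) {
    need <- c("region", "btv_cm3", "mgv_cm3", "pbd_hu_pct", "pbd_vol_pct",
              "share_btv_pct", "share_mgv_pct", "pbd_ratio_pct")
    if (!all(need %in% names(object@table)))
        return(paste("composition table must have columns:",
                     paste(need, collapse = ", ")))
    tb <- object@table
    if (any(tb$mgv_cm3 > tb$btv_cm3 + 1e-9))
        return("MGV must not exceed BTV")
    ok <- is.na(tb$pbd_hu_pct) | (tb$pbd_hu_pct >= 0 & tb$pbd_hu_pct <= 100)
    if (!all(ok)) return("PBD must lie in [0, 100]")
    TRUE
})

#' RegressionFit: an age-regression model fit
#'
#' One of the two model families used for breast composition versus age:
#' logarithmic, y = a * ln(Age) + b (breast tissue volume), or
#' multiplicative inverse, y = a / Age + b (gland volume and percent
#' density), fitted by (optionally weighted) least squares.
#'
#' @slot family `"log"` or `"inverse"`.
#' @slot a,b fitted coefficient and constant.
#' @slot se named numeric(2), standard errors of a and b.
#' @slot p named numeric(2), two-sided p-values (t distribution, n - 2 df).
#' @slot rse residual standard error, in the units of y.
#' @slot df residual degrees of freedom, n - 2.
#' @slot n number of observations.
#' @slot weighted whether weights were used.
#' @export
setClass("RegressionFit", representation(
    family = "character", a = "numeric", b = "numeric", se = "numeric",
    p = "numeric", rse = "numeric", df = "numeric", n = "numeric",
    weighted = "logical"))

setValidity("RegressionFit", function(object) {
    if (!object@family %in% c("log", "inverse"))
        return("'family' must be \"log\" or \"inverse\"")
    if (object@df != object@n - 2)
        return("df must equal n - 2 (one regressor plus intercept)")
    if (any(object@se < 0) || object@rse < 0)
        return("standard errors must be non-negative")
    TRUE
})
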