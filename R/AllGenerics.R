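#' Accessors for bctdensity objects
#'
#' `huData()` returns the raw HU array of a [CTVolume-class]; `labelData()`
#' the integer class array of a [LabelMap-class]; `voxelSpacing()` the voxel
#' size in mm; `laterality()` the breast side; `nipplePosition()` the nipple
#' voxel coordinate of a [QuadrantPartition-class]; `compositionTable()` the
#' per-region feature table of a [BreastComposition-class]; `densityTrace()`
#' the per-sweep running average breast density recorded by the adaptive
#' region growing.
#'
#' @param x An object of the documented classes.
#' @return The corresponding slot value (see description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("huData", function(x) standardGeneric("huData"))
#' @rdname accessors
#' @export
setMethod("huData", "CTVolume", function(x) x@hu)

#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setMethod("labelData", "LabelMap", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))
#' @rdname accessors
#' @export
setMethod("laterality", "CTVolume", function(x) x@laterality)
#' @rdname accessors
#' @export
setMethod("laterality", "LabelMap", function(x) x@laterality)
#' @rdname accessors
#' @export
setMethod("laterality", "QuadrantPartition", function(x) x@laterality)

#' @rdname accessors
#' @export
setGeneric("nipplePosition", function(x) standardGeneric("nipplePosition"))
#' @rdname accessors
#' @export
setMethod("nipplePosition", "QuadrantPartition", function(x) x@nipple)

#' @rdname accessors
#' @export
setGeneric("quadrantData", function(x) standardGeneric("quadrantData"))
#' @rdname accessors
#' @export
setMethod("quadrantData", "QuadrantPartition", function(x) x@quadrant)

#' @rdname accessors
#' @export
setGeneric("compositionTable", function(x) standardGeneric("compositionTable"))
#' @rdname accessors
#' @export
setMethod("compositionTable", "BreastComposition", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("densityTrace", function(x) standardGeneric("densityTrace"))
#' @rdname accessors
#' @export
setMethod("densityTrace", "LabelMap", function(x) x@meta$density_trace)

#' Coefficients of an age-regression fit
#'
#' @param object A [RegressionFit-class].
#' @param ... Ignored.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
setMethod("coef", "RegressionFit", function(object, ...) {
    c(a = object@a, b = object@b)
})

setMethod("show", "CTVolume", function(object) {
    d <- dim(object@hu)
    cat(sprintf("CTVolume: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, %s breast\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3], object@laterality))
    cat(sprintf("  HU range: [%.1f, %.1f]\n",
                min(object@hu), max(object@hu)))
})

setMethod("show", "LabelMap", function(object) {
    d <- dim(object@labels)
    cat(sprintf("LabelMap: %d x %d x %d voxels, %s breast\n",
                d[1], d[2], d[3], object@laterality))
    tc <- tissueCodes()
    counts <- tabulate(object@labels + 1L, length(tc))
    names(counts) <- names(tc)
    print(counts)
})

setMethod("show", "QuadrantPartition", function(object) {
    cat(sprintf("QuadrantPartition: nipple at (%d, %d, %d), %s breast, outer side = %s columns\n",
                object@nipple[1], object@nipple[2], object@nipple[3],
                object@laterality, object@outerSide))
    counts <- tabulate(object@quadrant[object@quadrant > 0L], 4L)
    names(counts) <- c("UOQ", "UIQ", "LOQ", "LIQ")
    print(counts)
})

setMethod("show", "BreastComposition", function(object) {
    cat("BreastComposition (BTV/MGV in cm^3, PBD in %):\n")
    tb <- object@table
    num <- vapply(tb, is.numeric, logical(1))
    tb[num] <- lapply(tb[num], round, 2)
    print(tb, row.names = FALSE)
})

setMethod("show", "RegressionFit", function(object) {
    form <- if (object@family == "log") "y = a * ln(Age) + b"
            else "y = a / Age + b"
    cat(sprintf("RegressionFit (%s): %s%s\n", object@family, form,
                if (object@weighted) ", weighted" else ""))
    cat(sprintf("  a = %.4g (se %.3g, p %.3g)\n  b = %.4g (se %.3g, p %.3g)\n",
                object@a, object@se[["a"]], object@p[["a"]],
                object@b, object@se[["b"]], object@p[["b"]]))
    cat(sprintf("  RSE = %.4g on %d degrees of freedom (n = %d)\n",
                object@rse, as.integer(object@df), as.integer(object@n)))
})
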