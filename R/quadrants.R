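# Which column side is the outer (lateral) side of the breast. The image
# convention is that columns run from the patient's right to the patient's
# left, so for a right breast the lower column indices are lateral.
.resolveOuterSide <- function(laterality, outerSide = c("auto", "low", "high")) {
    outerSide <- match.arg(outerSide)
    if (outerSide != "auto") return(outerSide)
    if (laterality == "right") "low" else "high"
}

# quadrant code for every voxel of a grid, from the two perpendicular
# planes through the nipple: 1 UOQ, 2 UIQ, 3 LOQ, 4 LIQ. Voxels on the
# dividing row plane count as upper, on the column plane as outer.
.quadrantCodes <- function(d, nipple, laterality, outerSide) {
    upperRow <- seq_len(d[2]) <= nipple[2]
    outerCol <- if (outerSide == "low") seq_len(d[3]) <= nipple[3]
                else seq_len(d[3]) >= nipple[3]
    # codes: upper&outer 1, upper&inner 2, lower&outer 3, lower&inner 4
    code <- outer(ifelse(upperRow, 0L, 2L), ifelse(outerCol, 1L, 2L), `+`)
    aperm(array(code, dim = c(d[2], d[3], d[1])), c(3L, 1L, 2L))
}

#' Locate the nipple landmark
#'
#' The nipple position is the centre of mass of the skin voxels in the most
#' posterior slice of the scan, i.e. the highest-index slice containing
#' skin (the nipple hangs lowest in the prone, pendant-breast geometry),
#' rounded to the nearest voxel.
#'
#' @param labels A [LabelMap-class].
#' @return integer(3) voxel coordinate (slice, row, column).
#' @export
locateNipple <- function(labels) {
    lm <- labelData(labels)
    skin <- lm == tissueCodes()[["skin"]]
    if (!any(skin)) stop("no skin voxels: cannot locate the nipple")
    perSlice <- apply(skin, 1L, any)
    slice <- max(which(perSlice))
    idx <- which(skin[slice, , ], arr.ind = TRUE)
    c(slice, as.integer(round(mean(idx[, 1]))),
      as.integer(round(mean(idx[, 2]))))
}

#' Partition breast tissue into the four quadrants
#'
#' Splits the adipose and glandular voxels into upper outer, upper inner,
#' lower outer and lower inner quadrants by the two perpendicular planes
#' parallel to the image rows and columns that intersect the nipple. Rows
#' below the nipple row index are "upper" (the patient is prone); the
#' outer (lateral) column side follows the laterality via `outerSide`.
#' Voxels exactly on the row plane count as upper and on the column plane
#' as outer.
#'
#' @param labels A [LabelMap-class].
#' @param nipple integer(3) nipple voxel, e.g. from [locateNipple()].
#' @param laterality `"left"` or `"right"`; defaults to the label map's.
#' @param outerSide `"auto"` (derive from laterality under the
#'   patient-right-to-left column convention), `"low"` or `"high"`.
#' @return A [QuadrantPartition-class].
#' @export
assignQuadrants <- function(labels, nipple = locateNipple(labels),
                            laterality = NULL, outerSide = "auto") {
    if (is.null(laterality)) laterality <- laterality(labels)
    side <- .resolveOuterSide(laterality, outerSide)
    lm <- labelData(labels)
    d <- dim(lm)
    tc <- tissueCodes()
    tissue <- lm == tc[["adipose"]] | lm == tc[["gland"]]
    q <- .quadrantCodes(d, nipple, laterality, side)
    q[!tissue] <- 0L
    new("QuadrantPartition", nipple = as.integer(nipple), quadrant = q,
        laterality = laterality, outerSide = side)
}
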