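#' Read a breast CT volume from NIfTI
#'
#' Reads the HU grid and voxel spacing (pixdim, mm) from a NIfTI file. The
#' stored axis order is taken as the package convention (axis 1 chest wall
#' to nipple, axis 2 rows, axis 3 columns).
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param laterality `"left"` or `"right"`.
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path, laterality = "right") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:3]
    hu <- array(as.numeric(img), dim = dim(img)[1:3])
    if (anyNA(hu) || any(!is.finite(hu)))
        stop(sprintf("malformed volume '%s': non-finite HU values", path))
    ctVolume(hu, spacing = spacing, laterality = laterality)
}

#' Write a CTVolume to NIfTI
#'
#' HU values are stored as doubles so a read-after-write round trip
#' reproduces the grid bit-identically.
#'
#' @param volume A [CTVolume-class].
#' @param path Destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
    img <- RNifti::asNifti(huData(volume))
    RNifti::pixdim(img) <- voxelSpacing(volume)
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' Read / write a LabelMap as integer-coded NIfTI
#'
#' Codes follow [tissueCodes()].
#'
#' @param path NIfTI path.
#' @param laterality `"left"` or `"right"`.
#' @return [readLabelMap()] returns a [LabelMap-class]; [writeLabelMap()]
#'   returns `path` invisibly.
#' @export
readLabelMap <- function(path, laterality = "right") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:3]
    labels <- array(as.integer(img), dim = dim(img)[1:3])
    if (!all(labels %in% tissueCodes()))
        stop(sprintf("malformed label map '%s': codes outside tissueCodes()",
                     path))
    labelMap(labels, spacing = spacing, laterality = laterality)
}

#' @rdname readLabelMap
#' @param labels A [LabelMap-class].
#' @export
writeLabelMap <- function(labels, path) {
    img <- RNifti::asNifti(labelData(labels))
    RNifti::pixdim(img) <- voxelSpacing(labels)
    RNifti::writeNifti(img, path, datatype = "int16")
    invisible(path)
}

#' Write / read a phantom with its ground truth
#'
#' The HU volume and ground-truth label map are written as NIfTI files
#' (`volume.nii.gz`, `labels.nii.gz`) with the voxel spacing in the
#' header; the truth quantities (true BTV/MGV/PBD, per-quadrant truth,
#' nipple voxel, laterality) go to a `truth.json` sidecar printed at full
#' double precision, so a round trip reproduces them to the last printed
#' digit. The per-voxel glandular-fraction array is not serialized.
#'
#' @param phantom list with `volume` and `truth`, from [generatePhantom()].
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeVolume(phantom$volume, file.path(dir, "volume.nii.gz"))
    writeLabelMap(phantom$truth@labelMap, file.path(dir, "labels.nii.gz"))
    truth <- phantom$truth
    sidecar <- list(btv_cm3 = truth@btv, mgv_cm3 = truth@mgv,
                    pbd_pct = truth@pbd, nipple = truth@nipple,
                    quadrant = truth@quadrant,
                    laterality = laterality(phantom$volume),
                    spacing_mm = voxelSpacing(phantom$volume))
    jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    invisible(dir)
}

#' @rdname writePhantom
#' @return `readPhantom()` returns a list with `volume`
#'   ([CTVolume-class]), `labels` ([LabelMap-class]) and `truth` (the
#'   parsed sidecar list).
#' @export
readPhantom <- function(dir) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    lat <- truth$laterality
    volume <- readVolume(file.path(dir, "volume.nii.gz"), laterality = lat)
    labels <- readLabelMap(file.path(dir, "labels.nii.gz"), laterality = lat)
    if (!isTRUE(all.equal(voxelSpacing(volume), voxelSpacing(labels),
                          tolerance = 1e-6)))
        stop("spacing mismatch between volume and label map")
    list(volume = volume, labels = labels, truth = truth)
}

#' Write per-region composition features as CSV
#'
#' Fixed column order: region, btv_cm3, mgv_cm3, pbd_hu_pct, pbd_vol_pct,
#' share_btv_pct, share_mgv_pct, pbd_ratio_pct (volumes cm^3, densities
#' and shares in percent).
#'
#' @param composition A [BreastComposition-class], or the long data.frame
#'   from [compositionLong()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(composition, path) {
    tb <- if (is(composition, "BreastComposition"))
        compositionTable(composition) else composition
    write.csv(tb, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) read.csv(path)
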