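.REGIONS <- c("Entire", "UOQ", "UIQ", "LOQ", "LIQ")

# logical tissue mask and per-region index list shared by the feature ops
.regionMasks <- function(labels, partition) {
    lm <- labelData(labels)
    tc <- tissueCodes()
    tissue <- lm == tc[["adipose"]] | lm == tc[["gland"]]
    q <- quadrantData(partition)
    if (!identical(dim(q), dim(lm)))
        stop("partition and label map have different grid shapes")
    masks <- list(Entire = tissue)
    for (i in 1:4) masks[[.REGIONS[i + 1L]]] <- tissue & (q == i)
    masks
}

#' Breast tissue and gland volumes per region
#'
#' BTV sums the voxel volumes of the adipose and glandular classes, MGV
#' those of the glandular class only, for the entire breast and each
#' quadrant. Whole-breast values equal the sum over quadrants exactly.
#'
#' @param labels A [LabelMap-class].
#' @param partition A [QuadrantPartition-class] on the same grid.
#' @return data.frame with columns `region`, `btv_cm3`, `mgv_cm3`.
#' @export
computeVolumes <- function(labels, partition) {
    lm <- labelData(labels)
    gland <- lm == tissueCodes()[["gland"]]
    masks <- .regionMasks(labels, partition)
    voxvol <- prod(voxelSpacing(labels)) / 1000
    btvQ <- vapply(masks[-1], sum, numeric(1)) * voxvol
    mgvQ <- vapply(masks[-1], function(m) sum(m & gland), numeric(1)) * voxvol
    # whole-breast volumes are the sums of the per-quadrant volumes, so the
    # partition additivity holds to the last bit
    data.frame(
        region = .REGIONS,
        btv_cm3 = c(sum(btvQ), btvQ),
        mgv_cm3 = c(sum(mgvQ), mgvQ),
        row.names = NULL)
}

# reference means from 2-voxel-eroded tissue cores, robust to
# partial-volume contamination at class boundaries
.coreReferences <- function(volume, labels) {
    hu <- huData(volume)
    lm <- labelData(labels)
    tc <- tissueCodes()
    sp <- voxelSpacing(volume)
    r <- 2 * min(sp)
    fatCore <- erodeBall(lm == tc[["adipose"]], sp, r)
    glandCore <- erodeBall(lm == tc[["gland"]], sp, r)
    muFat <- if (any(fatCore)) mean(hu[fatCore])
             else if (any(lm == tc[["adipose"]])) mean(hu[lm == tc[["adipose"]]])
             else NA_real_
    muGland <- if (any(glandCore)) mean(hu[glandCore])
               else if (any(lm == tc[["gland"]])) mean(hu[lm == tc[["gland"]]])
               else NA_real_
    c(fat = muFat, gland = muGland)
}

#' Percent breast density per region
#'
#' The primary, HU-based PBD maps each tissue voxel to its glandular
#' fraction `g = clamp((HU - muFat) / (muGland - muFat), 0, 1)` and reports
#' 100 times the mean fraction over the region, which accounts for partial
#' glandularity inside voxels. The secondary, volumetric PBD is the percent
#' ratio 100 * MGV / BTV of the classified voxel counts. Reference means
#' default to the mean HU of 2-voxel-eroded adipose and gland cores.
#'
#' @param volume A [CTVolume-class].
#' @param labels A [LabelMap-class].
#' @param partition A [QuadrantPartition-class].
#' @param muFat,muGland Optional fixed reference HU means.
#' @return data.frame with columns `region`, `pbd_hu_pct`, `pbd_vol_pct`.
#' @export
computePBD <- function(volume, labels, partition,
                       muFat = NULL, muGland = NULL) {
    if (is.null(muFat) || is.null(muGland)) {
        refs <- .coreReferences(volume, labels)
        if (is.null(muFat)) muFat <- refs[["fat"]]
        if (is.null(muGland)) muGland <- refs[["gland"]]
    }
    masks <- .regionMasks(labels, partition)
    gland <- labelData(labels) == tissueCodes()[["gland"]]
    if (is.na(muFat) || is.na(muGland)) {
        # no glandular class to estimate references from: the breast is
        # all-adipose and its density is zero wherever tissue exists
        pbd_hu <- vapply(masks, function(m) if (any(m)) 0 else NA_real_,
                         numeric(1))
        return(data.frame(region = .REGIONS, pbd_hu_pct = pbd_hu,
                          pbd_vol_pct = pbd_hu, row.names = NULL))
    }
    if (!is.finite(muFat) || !is.finite(muGland) || muGland <= muFat)
        stop("degenerate HU references: need muGland > muFat")
    g <- clamp((huData(volume) - muFat) / (muGland - muFat), 0, 1)
    data.frame(
        region = .REGIONS,
        pbd_hu_pct = vapply(masks, function(m)
            if (any(m)) 100 * mean(g[m]) else NA_real_, numeric(1)),
        pbd_vol_pct = vapply(masks, function(m)
            if (any(m)) 100 * sum(gland & m) / sum(m) else NA_real_,
            numeric(1)),
        row.names = NULL)
}

#' Assemble the full breast composition
#'
#' Combines [computeVolumes()] and [computePBD()] and derives each
#' quadrant's percentage share of whole-breast BTV and MGV and the ratio of
#' quadrant PBD to whole-breast PBD. Shares are reported as missing when
#' the whole-breast denominator is zero.
#'
#' @inheritParams computePBD
#' @return A [BreastComposition-class].
#' @export
composeFeatures <- function(volume, labels, partition,
                            muFat = NULL, muGland = NULL) {
    vols <- computeVolumes(labels, partition)
    pbd <- computePBD(volume, labels, partition, muFat, muGland)
    tb <- merge(vols, pbd, by = "region", sort = FALSE)
    tb <- tb[match(.REGIONS, tb$region), ]
    whole <- tb[tb$region == "Entire", ]
    shareOf <- function(x, total) {
        s <- 100 * x / total
        s[tb$region == "Entire"] <- NA_real_
        if (!is.finite(total) || total == 0) s[] <- NA_real_
        s
    }
    tb$share_btv_pct <- shareOf(tb$btv_cm3, whole$btv_cm3)
    tb$share_mgv_pct <- shareOf(tb$mgv_cm3, whole$mgv_cm3)
    tb$pbd_ratio_pct <- shareOf(tb$pbd_hu_pct, whole$pbd_hu_pct)
    row.names(tb) <- NULL
    new("BreastComposition", table = tb)
}
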