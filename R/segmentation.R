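#' SegmentationParams: tunable parameters of the tissue segmentation
#'
#' All values are stated in physical units where possible so behaviour is
#' resolution independent. `seedFraction`, `floorFraction` and `alpha`
#' drive the adaptive region growing of the glandular class (see
#' [segmentGland()]); `chestExtent` gates where pectoralis muscle, ribs and
#' skin folds are searched for (the fraction of slices adjacent to the
#' chest end of the scan); `minModeSeparation` is the smallest distance
#' between the fat and gland HU modes accepted as evidence of a glandular
#' population.
#'
#' @slot airThreshold HU above which a voxel counts as tissue (default -500).
#' @slot skinThickness skin shell thickness in mm (default 1.5).
#' @slot ribThreshold HU at or above which in-gate voxels are ribs
#'   (default 150).
#' @slot pectoralisThreshold HU at or above which in-gate voxels are
#'   candidate muscle (default 0: above the skin-to-fat partial-volume
#'   range so sub-skin boundary voxels cannot bridge breast tissue to the
#'   chest wall, yet well below muscle even under noise).
#' @slot chestExtent fraction of slices at the chest end searched for chest
#'   structures (default 0.15).
#' @slot seedFraction glandular-fraction level at which voxels seed the
#'   region growing (default 0.8).
#' @slot floorFraction hard lower bound of the acceptance threshold
#'   (default 0.25).
#' @slot alpha coupling between the running average breast density and the
#'   acceptance threshold (default 0.5).
#' @slot tol convergence tolerance on the running average density
#'   (default 1e-4).
#' @slot maxIterations maximum region-growing sweeps (default 50).
#' @slot minModeSeparation minimum fat-gland HU mode distance (default 60,
#'   well below the roughly 140 HU fat-to-gland distance but above what
#'   noise or partial-volume blends produce without a real gland).
#' @export
setClass("SegmentationParams", representation(
    airThreshold = "numeric", skinThickness = "numeric",
    ribThreshold = "numeric", pectoralisThreshold = "numeric",
    chestExtent = "numeric", seedFraction = "numeric",
    floorFraction = "numeric", alpha = "numeric", tol = "numeric",
    maxIterations = "integer", minModeSeparation = "numeric"))

setValidity("SegmentationParams", function(object) {
    if (!(object@floorFraction > 0 && object@floorFraction <
          object@seedFraction && object@seedFraction <= 1))
        return("need 0 < floorFraction < seedFraction <= 1")
    if (object@tol <= 0) return("'tol' must be positive")
    if (object@chestExtent <= 0 || object@chestExtent > 1)
        return("'chestExtent' must be in (0, 1]")
    if (object@skinThickness < 0) return("'skinThickness' must be >= 0")
    TRUE
})

#' Construct SegmentationParams
#'
#' @param airThreshold,skinThickness,ribThreshold,pectoralisThreshold
#'   See [SegmentationParams-class].
#' @param chestExtent,seedFraction,floorFraction,alpha,tol,maxIterations
#'   See [SegmentationParams-class].
#' @param minModeSeparation See [SegmentationParams-class].
#' @return A [SegmentationParams-class].
#' @export
segmentationParams <- function(airThreshold = -500, skinThickness = 1.5,
                               ribThreshold = 150, pectoralisThreshold = 0,
                               chestExtent = 0.15, seedFraction = 0.8,
                               floorFraction = 0.25, alpha = 0.5,
                               tol = 1e-4, maxIterations = 50L,
                               minModeSeparation = 60) {
    new("SegmentationParams", airThreshold = airThreshold,
        skinThickness = skinThickness, ribThreshold = ribThreshold,
        pectoralisThreshold = pectoralisThreshold, chestExtent = chestExtent,
        seedFraction = seedFraction, floorFraction = floorFraction,
        alpha = alpha, tol = tol, maxIterations = as.integer(maxIterations),
        minModeSeparation = minModeSeparation)
}

#' Body mask: all tissue of the scanned volume
#'
#' Thresholds the HU volume at `airThreshold`, keeps the largest connected
#' component and fills interior cavities.
#'
#' @param volume A [CTVolume-class].
#' @param params A [SegmentationParams-class].
#' @return Logical 3D array.
#' @export
bodyMask <- function(volume, params = segmentationParams()) {
    mask <- huData(volume) > params@airThreshold
    if (!any(mask)) stop("no tissue found: volume is entirely air")
    fillHoles(largestComponent(mask, connectivity = 6L))
}

#' Skin segmentation
#'
#' The skin is the shell of thickness `skinThickness` inside the body
#' surface: the body mask minus its morphological erosion by a ball of that
#' radius. Space beyond the image border counts as body, so the chest cut
#' face is not turned into skin. The nipple protrusion, being thinner than
#' the shell, falls entirely in the skin class.
#'
#' @param volume A [CTVolume-class].
#' @param body Logical body mask from [bodyMask()].
#' @param params A [SegmentationParams-class].
#' @return list with logical arrays `skin` and `interior`.
#' @export
segmentSkin <- function(volume, body, params = segmentationParams()) {
    if (!any(body)) stop("empty body mask")
    interior <- erodeBall(body, voxelSpacing(volume), params@skinThickness)
    if (!any(interior))
        stop("skin thickness leaves no interior: body entirely skin")
    list(skin = body & !interior, interior = interior)
}

#' Chest structure segmentation: pectoralis, ribs, skin fold
#'
#' Within the `chestExtent` fraction of slices adjacent to the chest end:
#' ribs are interior voxels at or above `ribThreshold` HU; the pectoralis
#' muscle is the soft-tissue-dense component (HU >= `pectoralisThreshold`)
#' touching the chest face of the scan; skin-fold sections are the tissue
#' components left disconnected from the main breast component once muscle
#' and ribs are removed. Empty masks are legitimate results.
#'
#' @param volume A [CTVolume-class].
#' @param interior Logical interior mask from [segmentSkin()].
#' @param params A [SegmentationParams-class].
#' @return list with logical arrays `pectoralis`, `rib`, `skinfold` and
#'   `breast` (the interior that remains).
#' @export
segmentChestStructures <- function(volume, interior,
                                   params = segmentationParams()) {
    if (!any(interior)) stop("empty interior mask")
    d <- dim(interior)
    hu <- huData(volume)
    gate <- array(FALSE, d)
    gate[seq_len(max(1L, ceiling(params@chestExtent * d[1]))), , ] <- TRUE

    rib <- interior & gate & (hu >= params@ribThreshold)

    cand <- interior & gate & (hu >= params@pectoralisThreshold) & !rib
    pect <- array(FALSE, d)
    if (any(cand)) {
        lab <- labelComponents(cand, connectivity = 26L)
        touching <- setdiff(unique(as.vector(lab[1L, , ])), 0L)
        if (length(touching)) pect <- array(lab %in% touching, d)
    }

    remaining <- interior & !pect & !rib
    skinfold <- array(FALSE, d)
    if (any(remaining)) {
        lab <- labelComponents(remaining, connectivity = 26L)
        n <- attr(lab, "ncomponents")
        if (n > 1L) {
            counts <- tabulate(lab[lab > 0L], n)
            main <- which.max(counts)
            inGate <- setdiff(unique(lab[gate & remaining]), c(0L, main))
            if (length(inGate)) skinfold <- array(lab %in% inGate, d)
        }
    }
    list(pectoralis = pect, rib = rib, skinfold = skinfold,
         breast = remaining & !skinfold)
}

# reference HU means of the fat and gland populations of the breast
# interior: histogram-based two-class (Otsu) split, then the medians of the
# two sides as robust population means
.estimateTissueReferences <- function(hu, interior, nbins = 256L) {
    vals <- hu[interior]
    thr <- otsuThreshold(vals, nbins)
    lower <- vals[vals <= thr]
    upper <- vals[vals > thr]
    if (!length(lower) || !length(upper))
        return(c(fat = thr, gland = thr))
    c(fat = median(lower), gland = median(upper))
}

#' Glandular tissue segmentation by adaptive region growing
#'
#' Realizes the adaptive region growing that classifies glandular tissue by
#' applying the average breast density, computed from the HU values during
#' the segmentation itself, as the voxel-wise acceptance rule:
#'
#' 1. estimate the fat and gland reference HU means from a two-class
#'    histogram split of the breast interior;
#' 2. map every interior voxel to its glandular fraction
#'    `g = clamp((HU - muFat) / (muGland - muFat), 0, 1)`;
#' 3. seed the gland region with voxels of `g >= seedFraction`;
#' 4. repeatedly accept 26-connected neighbours with
#'    `g >= max(floorFraction, alpha * (1 - D))`, where `D`, the running
#'    average breast density, is the mean glandular fraction over the
#'    currently grown region, recomputed after each exhaustive sweep;
#' 5. stop when a sweep adds no voxel and `D` has moved less than `tol`,
#'    or after `maxIterations` sweeps.
#'
#' The procedure is fully deterministic. If the interior HU histogram shows
#' no glandular population (mode separation below `minModeSeparation`), an
#' empty gland mask is returned with a warning.
#'
#' @param volume A [CTVolume-class].
#' @param breastInterior Logical mask of the breast interior (adipose +
#'   gland candidate region).
#' @param params A [SegmentationParams-class].
#' @return list with logical arrays `gland` and `adipose`, the per-sweep
#'   density trace `trace`, the glandular-fraction array `g`, and the
#'   reference means `muFat`, `muGland`.
#' @export
segmentGland <- function(volume, breastInterior,
                         params = segmentationParams()) {
    if (!any(breastInterior)) stop("empty breast interior")
    hu <- huData(volume)
    refs <- .estimateTissueReferences(hu, breastInterior)
    d <- dim(hu)
    if (refs[["gland"]] - refs[["fat"]] < params@minModeSeparation) {
        warning("no glandular HU population found; returning empty gland mask")
        return(list(gland = array(FALSE, d), adipose = breastInterior,
                    trace = numeric(0), g = NULL,
                    muFat = refs[["fat"]], muGland = refs[["gland"]]))
    }
    g <- clamp((hu - refs[["fat"]]) / (refs[["gland"]] - refs[["fat"]]), 0, 1)
    g[!breastInterior] <- 0
    res <- cpp_region_grow(as.numeric(g), as.logical(breastInterior),
                           dimOf(hu), params@seedFraction,
                           params@floorFraction, params@alpha, params@tol,
                           params@maxIterations)
    gland <- array(res$mask, d)
    list(gland = gland, adipose = breastInterior & !gland,
         trace = res$trace, g = array(g, d),
         muFat = refs[["fat"]], muGland = refs[["gland"]])
}

#' Full tissue segmentation
#'
#' Composes [bodyMask()], [segmentSkin()], [segmentChestStructures()] and
#' [segmentGland()] into a complete per-voxel classification. Every voxel
#' receives exactly one label from [tissueCodes()].
#'
#' @param volume A [CTVolume-class].
#' @param params A [SegmentationParams-class].
#' @return A [LabelMap-class] whose `meta` carries the density trace
#'   (`density_trace`), the reference means (`mu_fat`, `mu_gland`) and the
#'   parameter echo (`params`).
#' @export
#' @examples
#' spec <- phantomSpec(gridShape = c(64, 64, 64), breastSemiaxes = c(12, 6, 6),
#'                     glandVolumeTarget = 0.1, nGlandComponents = 2,
#'                     includeRibs = FALSE, includeSkinfold = FALSE,
#'                     noiseSD = 0)
#' ph <- generatePhantom(spec)
#' labels <- segmentAll(ph$volume)
#' table(labelData(labels))
segmentAll <- function(volume, params = segmentationParams()) {
    body <- bodyMask(volume, params)
    sk <- segmentSkin(volume, body, params)
    chest <- segmentChestStructures(volume, sk$interior, params)
    gl <- segmentGland(volume, chest$breast, params)

    tc <- tissueCodes()
    labels <- array(tc[["air"]], dim(huData(volume)))
    labels[sk$skin] <- tc[["skin"]]
    labels[chest$pectoralis] <- tc[["pectoralis"]]
    labels[chest$rib] <- tc[["rib"]]
    labels[chest$skinfold] <- tc[["skinfold"]]
    labels[gl$adipose] <- tc[["adipose"]]
    labels[gl$gland] <- tc[["gland"]]

    labelMap(labels, spacing = voxelSpacing(volume),
             laterality = laterality(volume),
             meta = list(density_trace = gl$trace, mu_fat = gl$muFat,
                         mu_gland = gl$muGland, params = params))
}
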