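#' PhantomSpec: parameters of the synthetic pendant-breast CT phantom
#'
#' Describes a prone-position (pendant) breast CT acquisition to emulate:
#' a half-ellipsoidal breast hanging from a pectoral slab at the chest end
#' of the scan, wrapped in a skin shell with a nipple protrusion at the tip,
#' with glandular inclusions placed inside the adipose interior according to
#' per-quadrant weights, optional ribs embedded in the slab and an optional
#' skin-fold flap of the thoracic wall, on a (300 um)^3 voxel grid by
#' default. Tissue boundaries carry partial-volume HU computed from the
#' analytic sub-voxel fraction of each geometric primitive, so the phantom's
#' per-voxel glandular fraction (and hence its true percent breast density)
#' is known exactly.
#'
#' @slot gridShape integer(3), voxels per axis (slices, rows, columns).
#' @slot voxelSize isotropic voxel edge length, mm.
#' @slot breastSemiaxes numeric(3) half-axes of the breast ellipsoid, mm
#'   (axis 1 = chest-to-nipple length).
#' @slot skinThickness skin shell thickness, mm.
#' @slot nGlandComponents number of glandular ellipsoid inclusions.
#' @slot glandVolumeTarget total true gland volume to place, cm^3.
#' @slot quadrantWeights numeric(4), placement probabilities for
#'   (UOQ, UIQ, LOQ, LIQ); must sum to 1.
#' @slot pectoralDepth pectoral slab depth in slices.
#' @slot includeRibs,includeSkinfold logical flags.
#' @slot hu named numeric(6): reference HU means for fat, gland, skin,
#'   muscle, rib, air.
#' @slot noiseSD additive Gaussian HU noise standard deviation.
#' @slot seed RNG seed; identical specs give bit-identical phantoms.
#' @slot laterality `"left"` or `"right"`.
#' @export
setClass("PhantomSpec", representation(
    gridShape = "integer", voxelSize = "numeric", breastSemiaxes = "numeric",
    skinThickness = "numeric", nGlandComponents = "integer",
    glandVolumeTarget = "numeric", quadrantWeights = "numeric",
    pectoralDepth = "integer", includeRibs = "logical",
    includeSkinfold = "logical", hu = "numeric", noiseSD = "numeric",
    seed = "integer", laterality = "character"))

setValidity("PhantomSpec", function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
        return("'gridShape' must be three axis lengths of at least 4 voxels")
    if (object@voxelSize <= 0) return("'voxelSize' must be positive (mm)")
    if (object@skinThickness < object@voxelSize)
        return("'skinThickness' must be at least one voxel")
    if (length(object@quadrantWeights) != 4L ||
        any(object@quadrantWeights < 0) ||
        abs(sum(object@quadrantWeights) - 1) > 1e-9)
        return("'quadrantWeights' must be 4 non-negative weights summing to 1")
    h <- object@hu
    need <- c("fat", "gland", "skin", "muscle", "rib", "air")
    if (!all(need %in% names(h)))
        return(paste("'hu' must name:", paste(need, collapse = ", ")))
    if (!(h[["air"]] < h[["fat"]] && h[["fat"]] < h[["gland"]]))
        return("HU ordering air < fat < gland violated")
    if (!object@laterality %in% c("left", "right"))
        return("'laterality' must be \"left\" or \"right\"")
    TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe the emulated acquisition: a 200^3 grid of (0.3 mm)^3
#' voxels (a 60 mm field of view; a scaled-down pendant breast so that whole
#' phantoms stay cheap to generate), a 40 x 19 x 19 mm half-ellipsoid
#' breast, a 1.5 mm skin shell, 6 glandular components totalling 3.2 cm^3
#' (about 14% true density, typical of the screening-age breast), gland
#' placement weights (0.343, 0.212, 0.263, 0.182) for (UOQ, UIQ, LOQ, LIQ)
#' mirroring the heterogeneous quadrant gland shares reported for real
#' cohorts, and literature-typical HU means (fat -100, gland +40, skin +30,
#' muscle +45, rib +700, air -1000).
#'
#' @param gridShape Voxels per axis (slices, rows, columns).
#' @param voxelSize Isotropic voxel size in mm.
#' @param breastSemiaxes Breast half-axes in mm.
#' @param skinThickness Skin shell thickness in mm.
#' @param nGlandComponents Number of glandular inclusions.
#' @param glandVolumeTarget Total true gland volume, cm^3.
#' @param quadrantWeights Placement weights (UOQ, UIQ, LOQ, LIQ).
#' @param pectoralDepth Pectoral slab depth in slices.
#' @param includeRibs,includeSkinfold Include ribs / a skin-fold flap.
#' @param hu Named HU reference means.
#' @param noiseSD Gaussian HU noise SD.
#' @param seed RNG seed.
#' @param laterality `"left"` or `"right"`.
#' @return A [PhantomSpec-class].
#' @export
#' @examples
#' spec <- phantomSpec(gridShape = c(64, 64, 64), breastSemiaxes = c(12, 6, 6),
#'                     glandVolumeTarget = 0.1, nGlandComponents = 2,
#'                     includeRibs = FALSE, includeSkinfold = FALSE,
#'                     noiseSD = 0)
#' ph <- generatePhantom(spec)
#' ph$truth@btv
phantomSpec <- function(gridShape = c(200L, 200L, 200L), voxelSize = 0.3,
                        breastSemiaxes = c(40, 19, 19), skinThickness = 1.5,
                        nGlandComponents = 6L, glandVolumeTarget = 3.2,
                        quadrantWeights = c(34, 21, 26, 18) / 99,
                        pectoralDepth = 16L, includeRibs = TRUE,
                        includeSkinfold = TRUE,
                        hu = c(fat = -100, gland = 40, skin = 30,
                               muscle = 45, rib = 700, air = -1000),
                        noiseSD = 20, seed = 1L, laterality = "right") {
    new("PhantomSpec", gridShape = as.integer(gridShape),
        voxelSize = voxelSize, breastSemiaxes = as.numeric(breastSemiaxes),
        skinThickness = skinThickness,
        nGlandComponents = as.integer(nGlandComponents),
        glandVolumeTarget = glandVolumeTarget,
        quadrantWeights = as.numeric(quadrantWeights),
        pectoralDepth = as.integer(pectoralDepth),
        includeRibs = includeRibs, includeSkinfold = includeSkinfold,
        hu = hu, noiseSD = noiseSD, seed = as.integer(seed),
        laterality = laterality)
}

#' PhantomTruth: exact ground truth of a synthetic phantom
#'
#' @slot labelMap Ground-truth [LabelMap-class].
#' @slot glandFraction 3D array of the true per-voxel glandular fraction.
#' @slot btv,mgv true breast tissue / mammary gland volume, cm^3.
#' @slot pbd true percent breast density (mean glandular fraction), %.
#' @slot quadrant data.frame of per-quadrant true BTV, MGV, PBD.
#' @slot nipple integer(3) true nipple voxel (slice, row, column).
#' @export
setClass("PhantomTruth", representation(
    labelMap = "LabelMap", glandFraction = "array", btv = "numeric",
    mgv = "numeric", pbd = "numeric", quadrant = "data.frame",
    nipple = "integer"))

setMethod("show", "PhantomTruth", function(object) {
    cat(sprintf("PhantomTruth: BTV %.2f cm^3, MGV %.3f cm^3, PBD %.2f%%, nipple (%d, %d, %d)\n",
                object@btv, object@mgv, object@pbd, object@nipple[1],
                object@nipple[2], object@nipple[3]))
})

# coordinate vector (mm, voxel centers) broadcast along the given axis
.axisCoord <- function(d, axis, s) {
    v <- (seq_len(d[axis]) - 0.5) * s
    if (axis == 1L) rep(v, times = d[2] * d[3])
    else if (axis == 2L) rep(rep(v, each = d[1]), times = d[3])
    else rep(v, each = d[1] * d[2])
}

# approximate signed distance (mm, negative inside) to an axis-aligned
# ellipsoid, from the normalized implicit function and its gradient
.sdEllipsoid <- function(z, r, c, center, ax) {
    u1 <- (z - center[1]) / ax[1]
    u2 <- (r - center[2]) / ax[2]
    u3 <- (c - center[3]) / ax[3]
    rho <- sqrt(u1^2 + u2^2 + u3^2)
    gn <- sqrt((u1 / ax[1])^2 + (u2 / ax[2])^2 + (u3 / ax[3])^2)
    d <- (rho - 1) * rho / pmax(gn, 1e-12)
    d[rho < 1e-12] <- -min(ax)
    d
}

.sdBox <- function(z, r, c, lo, hi) {
    pmax(lo[1] - z, z - hi[1], lo[2] - r, r - hi[2], lo[3] - c, c - hi[3])
}

# sub-voxel fraction from a signed distance: linear ramp one voxel wide
.fracFromSd <- function(d, h) clamp(0.5 - d / h, 0, 1)

.bboxIdx <- function(lo, hi, s, n) {
    i0 <- max(1L, as.integer(floor(lo / s)))
    i1 <- min(n, as.integer(ceiling(hi / s) + 1L))
    if (i0 > i1) integer(0) else i0:i1
}

#' Generate a synthetic pendant-breast CT phantom
#'
#' Builds the HU volume and its exact ground truth from the geometric
#' primitives described by the [PhantomSpec-class]. Boundary voxels carry
#' partial-volume HU via the analytic sub-voxel fraction of each primitive;
#' glandular components are random ellipsoids placed by the quadrant
#' weights and rescaled by a common factor until the true gland volume is
#' within 5% of `glandVolumeTarget`. With the same spec (including seed)
#' the output is bit-identical.
#'
#' @param spec A [PhantomSpec-class].
#' @return A list with elements `volume` ([CTVolume-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @export
generatePhantom <- function(spec) {
    validObject(spec)
    d <- spec@gridShape
    s <- spec@voxelSize
    h <- s
    ext <- d * s
    hu0 <- spec@hu
    t <- spec@skinThickness
    bs <- spec@breastSemiaxes
    zTop <- spec@pectoralDepth * s
    cr <- ext[2] / 2
    cc <- ext[3] / 2

    nippleR <- min(3, 0.5 * min(bs[2:3]))
    nippleProtrusion <- min(1.5, nippleR / 2)
    zTip <- zTop + bs[1] + nippleProtrusion
    if (zTip + 2 * s >= ext[1])
        stop("degenerate grid: breast plus nipple does not fit along axis 1")
    slabR <- pmin(bs[2:3] + 10, ext[2:3] / 2 - 1.2)
    if (any(slabR <= bs[2:3] + t))
        stop("degenerate grid: pectoral slab does not fit in the field of view")
    if (zTop <= 0) stop("pectoralDepth must be at least 1 slice")

    z <- .axisCoord(d, 1L, s)
    r <- .axisCoord(d, 2L, s)
    cl <- .axisCoord(d, 3L, s)

    # breast: ellipsoid centred on the slab top plane z = zTop. The full
    # ellipsoid (not the half) enters the union: its lower half lies inside
    # the slab, which keeps the union's signed distance free of a spurious
    # internal seam at the attachment plane, so the analytic skin shell
    # matches a true morphological erosion there. The visible breast is the
    # z > zTop half.
    dBreast <- .sdEllipsoid(z, r, cl, c(zTop, cr, cc), bs)
    # pectoral slab: elliptic cylinder, open toward the chest cut (z <= 0)
    rho <- sqrt(((r - cr) / slabR[1])^2 + ((cl - cc) / slabR[2])^2)
    gn <- sqrt(((r - cr) / slabR[1]^2)^2 + ((cl - cc) / slabR[2]^2)^2)
    dSlab <- pmax((rho - 1) * rho / pmax(gn, 1e-12), z - zTop)
    rm(rho, gn)
    # nipple: sphere protruding from the breast tip by less than the skin
    # thickness, so the whole protruding cap lies inside the skin shell
    dNipple <- sqrt((z - (zTip - nippleR))^2 + (r - cr)^2 + (cl - cc)^2) -
        nippleR

    if (spec@includeSkinfold) {
        foldLo <- c(-s, cr + slabR[1] - 6, cc - min(15, slabR[2] - 2))
        foldHi <- c(min(zTop + 5, 0.15 * ext[1] - 1),
                    cr + slabR[1] - 0.6, cc + min(15, slabR[2] - 2))
        if (foldLo[2] - (cr + bs[2] + t) < 1.2)
            stop("grid too small for a skin fold separated from the breast")
        dFold <- .sdBox(z, r, cl, foldLo, foldHi)
    } else {
        dFold <- NULL
    }

    dInner <- pmin(dBreast, dSlab, dNipple)
    # 1 breast (above the attachment plane), 2 slab/chest, 3 fold
    zone <- ifelse(z > zTop, 1L, 2L)
    if (!is.null(dFold)) {
        zone[dFold < dInner] <- 3L
        dInner <- pmin(dInner, dFold)
    }

    fracBody <- .fracFromSd(dInner, h)
    fracInt <- .fracFromSd(dInner + t, h)
    rm(dBreast, dSlab, dNipple, dFold, dInner)

    # rib fraction inside the slab
    fracRib <- 0
    if (spec@includeRibs) {
        ribR <- max(min(1.4, 0.28 * zTop), s)
        zc <- 0.35 * zTop
        rowOff <- min(14, slabR[1] - ribR - t - 1)
        fracRib <- numeric(length(z))
        for (ro in c(-rowOff, 0, rowOff)) {
            dRib <- pmax(sqrt((z - zc)^2 + (r - (cr + ro))^2) - ribR,
                         abs(cl - cc) - min(20, slabR[2] - 2))
            fracRib <- pmax(fracRib, .fracFromSd(dRib, h))
        }
        rm(dRib)
    }

    interiorVox <- fracInt >= 0.5
    breastInterior <- interiorVox & zone == 1L
    voxvol <- s^3 / 1000  # cm^3

    # glandular inclusions
    g <- numeric(length(z))
    dim(g) <- d
    nipTruth <- c(max(1L, min(d[1], as.integer(floor(zTip / s + 0.5)))),
                  as.integer(round(cr / s + 0.5)),
                  as.integer(round(cc / s + 0.5)))
    outerSide <- .resolveOuterSide(spec@laterality, "auto")

    if (spec@nGlandComponents > 0L && spec@glandVolumeTarget > 0) {
        interiorVol <- sum(breastInterior) * voxvol
        if (spec@glandVolumeTarget > 0.5 * interiorVol)
            stop(sprintf(
                "glandVolumeTarget (%.2f cm^3) exceeds half the breast interior volume (%.2f cm^3)",
                spec@glandVolumeTarget, interiorVol))
        comps <- withSeed(spec@seed, .placeGlandComponents(
            spec, zTop, cr, cc, bs, t, outerSide))
        # rescale all components by a common factor until the voxelized true
        # gland volume matches the target
        sfac <- 1
        vol <- 0
        for (it in 1:12) {
            g[] <- 0
            for (k in seq_along(comps$cz)) {
                ctr <- c(comps$cz[k], comps$cr[k], comps$cc[k])
                ax <- sfac * c(comps$a1[k], comps$a2[k], comps$a3[k])
                iz <- .bboxIdx(ctr[1] - ax[1] - 2 * h, ctr[1] + ax[1] + 2 * h, s, d[1])
                ir <- .bboxIdx(ctr[2] - ax[2] - 2 * h, ctr[2] + ax[2] + 2 * h, s, d[2])
                ic <- .bboxIdx(ctr[3] - ax[3] - 2 * h, ctr[3] + ax[3] + 2 * h, s, d[3])
                if (!length(iz) || !length(ir) || !length(ic)) next
                zz <- rep((iz - 0.5) * s, times = length(ir) * length(ic))
                rr <- rep(rep((ir - 0.5) * s, each = length(iz)), times = length(ic))
                cc2 <- rep((ic - 0.5) * s, each = length(iz) * length(ir))
                f <- .fracFromSd(.sdEllipsoid(zz, rr, cc2, ctr, ax), h)
                g[iz, ir, ic] <- pmax(g[iz, ir, ic],
                                      array(f, c(length(iz), length(ir), length(ic))))
            }
            g[!breastInterior] <- 0
            vol <- sum(g) * voxvol
            if (vol > 0 && abs(vol - spec@glandVolumeTarget) /
                spec@glandVolumeTarget <= 0.02) break
            if (vol <= 0) stop("gland placement failed: no gland volume realized")
            sfac <- min(sfac * (spec@glandVolumeTarget / vol)^(1 / 3), 1.25)
        }
        if (abs(vol - spec@glandVolumeTarget) / spec@glandVolumeTarget > 0.05)
            stop(sprintf(
                "could not realize gland volume target within 5%% (got %.2f of %.2f cm^3)",
                vol, spec@glandVolumeTarget))
    }

    # HU assembly: air outside, skin between the body and interior surfaces,
    # zone-specific core values inside, all partial-volume blended
    huCore <- hu0[["fat"]] + g * (hu0[["gland"]] - hu0[["fat"]])
    slabVox <- zone == 2L
    huCore[slabVox] <- hu0[["muscle"]]
    if (spec@includeRibs)
        huCore[slabVox] <- hu0[["muscle"]] +
            fracRib[slabVox] * (hu0[["rib"]] - hu0[["muscle"]])
    huCore[zone == 3L] <- hu0[["fat"]]
    hu <- (1 - fracBody) * hu0[["air"]] + (fracBody - fracInt) * hu0[["skin"]] +
        fracInt * huCore
    rm(huCore)
    dim(hu) <- d

    if (spec@noiseSD > 0) {
        hu <- hu + withSeed(spec@seed + 1L,
                            array(rnorm(prod(d), 0, spec@noiseSD), d))
    }

    # ground-truth labels
    tc <- tissueCodes()
    labels <- array(tc[["air"]], d)
    bodyVox <- fracBody >= 0.5
    labels[bodyVox] <- tc[["skin"]]
    labels[interiorVox & zone == 2L] <- tc[["pectoralis"]]
    if (spec@includeRibs)
        labels[interiorVox & zone == 2L & fracRib >= 0.5] <- tc[["rib"]]
    labels[interiorVox & zone == 3L] <- tc[["skinfold"]]
    labels[breastInterior] <- ifelse(g[breastInterior] >= 0.5,
                                     tc[["gland"]], tc[["adipose"]])

    btv <- sum(breastInterior) * voxvol
    mgv <- sum(g[breastInterior]) * voxvol
    pbd <- if (btv > 0) 100 * mgv / btv else 0

    qcode <- .quadrantCodes(d, nipTruth, spec@laterality, outerSide)
    qtab <- data.frame(region = c("UOQ", "UIQ", "LOQ", "LIQ"),
                       btv_cm3 = NA_real_, mgv_cm3 = NA_real_,
                       pbd_pct = NA_real_)
    for (q in 1:4) {
        m <- breastInterior & qcode == q
        qtab$btv_cm3[q] <- sum(m) * voxvol
        qtab$mgv_cm3[q] <- sum(g[m]) * voxvol
        qtab$pbd_pct[q] <- if (qtab$btv_cm3[q] > 0)
            100 * qtab$mgv_cm3[q] / qtab$btv_cm3[q] else NA_real_
    }

    lm <- labelMap(labels, spacing = rep(s, 3), laterality = spec@laterality)
    truth <- new("PhantomTruth", labelMap = lm, glandFraction = g,
                 btv = btv, mgv = mgv, pbd = pbd, quadrant = qtab,
                 nipple = nipTruth)
    list(volume = ctVolume(hu, spacing = rep(s, 3),
                           laterality = spec@laterality),
         truth = truth)
}

# sample gland component semiaxes, then centers: quadrant chosen by weight,
# and the whole component (with rescale headroom) must stay inside the
# skin and clear of the chest-wall junction so ground truth is unambiguous
.placeGlandComponents <- function(spec, zTop, cr, cc, bs, t, outerSide) {
    n <- spec@nGlandComponents
    r0 <- (3 * (spec@glandVolumeTarget * 1000 / n) / (4 * pi))^(1 / 3)
    quad <- sample.int(4L, n, replace = TRUE, prob = spec@quadrantWeights)
    cz <- crv <- ccv <- a1 <- a2 <- a3 <- numeric(n)
    h <- spec@voxelSize
    for (k in seq_len(n)) {
        ax <- runif(3, 0.8, 1.2)
        ax <- r0 * ax / prod(ax)^(1 / 3)  # anisotropy with unit volume factor
        shrink <- t + 1.3 * max(ax) + h
        axAllow <- pmax(bs - shrink, 0.15 * bs)
        zLo <- zTop + 2 + 1.3 * ax[1]
        if (zLo >= zTop + bs[1] - shrink)
            stop("breast too small for the requested gland components")
        ok <- FALSE
        for (try in 1:4000) {
            pz <- runif(1, zLo, zTop + bs[1] - shrink)
            pr <- runif(1, cr - axAllow[2], cr + axAllow[2])
            pc <- runif(1, cc - axAllow[3], cc + axAllow[3])
            inEll <- ((pz - zTop) / axAllow[1])^2 +
                ((pr - cr) / axAllow[2])^2 + ((pc - cc) / axAllow[3])^2 <= 1
            if (!inEll) next
            upper <- pr < cr
            outer <- if (outerSide == "low") pc < cc else pc > cc
            q <- if (upper && outer) 1L else if (upper) 2L
                 else if (outer) 3L else 4L
            if (q == quad[k]) { ok <- TRUE; break }
        }
        if (!ok) stop("gland placement failed: could not honor quadrant weights")
        cz[k] <- pz; crv[k] <- pr; ccv[k] <- pc
        a1[k] <- ax[1]; a2[k] <- ax[2]; a3[k] <- ax[3]
    }
    list(cz = cz, cr = crv, cc = ccv, a1 = a1, a2 = a2, a3 = a3, quad = quad)
}
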