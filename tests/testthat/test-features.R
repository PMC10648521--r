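# uniform synthetic label map with explicit counts for arithmetic checks
makeCountedLabels <- function(nGland = 1000L, nFat = 3000L, spacing = 0.3) {
    tc <- tissueCodes()
    lab <- array(tc[["air"]], c(20, 20, 20))
    lab[1:10, , ][seq_len(nFat)] <- tc[["adipose"]]
    lab[11:20, , ][seq_len(nGland)] <- tc[["gland"]]
    labelMap(lab, spacing = spacing)
}

fullGridPartition <- function(labels, nipple = c(1L, 10L, 10L)) {
    assignQuadrants(labels, nipple = nipple)
}

test_that("volumes are voxel counts times voxel volume", {
    labs <- makeCountedLabels(nGland = 1000L, nFat = 0L)
    part <- fullGridPartition(labs)
    v <- computeVolumes(labs, part)
    expect_equal(v$mgv_cm3[v$region == "Entire"], 1000 * 0.3^3 / 1000)
    expect_equal(v$btv_cm3[v$region == "Entire"], 0.027)
    labs0 <- makeCountedLabels(nGland = 0L, nFat = 500L)
    v0 <- computeVolumes(labs0, fullGridPartition(labs0))
    expect_equal(v0$mgv_cm3[v0$region == "Entire"], 0)
})

test_that("whole-breast volumes equal the sum over quadrants exactly", {
    labs <- fixtureLabels("full")
    part <- assignQuadrants(labs)
    v <- computeVolumes(labs, part)
    expect_identical(v$btv_cm3[1], sum(v$btv_cm3[2:5]))
    expect_identical(v$mgv_cm3[1], sum(v$mgv_cm3[2:5]))
})

test_that("HU-based PBD is linear in the glandular fraction", {
    tc <- tissueCodes()
    lab <- array(tc[["air"]], c(10, 10, 10))
    lab[2:9, 2:9, 2:9] <- tc[["adipose"]]
    tissue <- lab != tc[["air"]]
    labs <- labelMap(lab, spacing = 0.3)
    part <- fullGridPartition(labs, c(1L, 5L, 5L))
    mk <- function(hu) ctVolume(array(hu, c(10, 10, 10)), spacing = 0.3)
    pureFat <- computePBD(mk(-100), labs, part, muFat = -100, muGland = 40)
    expect_equal(pureFat$pbd_hu_pct[1], 0)
    pureGland <- computePBD(mk(40), labs, part, muFat = -100, muGland = 40)
    expect_equal(pureGland$pbd_hu_pct[1], 100)
    huHalf <- array(-100, c(10, 10, 10))
    half <- which(tissue)[seq_len(sum(tissue) / 2)]
    huHalf[half] <- 40
    halfRes <- computePBD(mk(0 * huHalf + huHalf), labs, part,
                          muFat = -100, muGland = 40)
    expect_equal(halfRes$pbd_hu_pct[1], 50)
})

test_that("in the binary-image limit HU-based and volumetric PBD agree", {
    tc <- tissueCodes()
    lab <- array(tc[["air"]], c(12, 12, 12))
    lab[2:11, 2:11, 2:11] <- tc[["adipose"]]
    set.seed(31)
    glandIdx <- sample(which(lab == tc[["adipose"]]), 200)
    lab[glandIdx] <- tc[["gland"]]
    hu <- array(-1000, dim(lab))
    hu[lab == tc[["adipose"]]] <- -100
    hu[lab == tc[["gland"]]] <- 40
    labs <- labelMap(lab, spacing = 0.3)
    part <- fullGridPartition(labs, c(1L, 6L, 6L))
    res <- computePBD(ctVolume(hu, 0.3), labs, part,
                      muFat = -100, muGland = 40)
    expect_equal(res$pbd_hu_pct, res$pbd_vol_pct, tolerance = 1e-12)
})

test_that("scaling the voxel size scales volumes by k^3 and not PBD", {
    labs1 <- makeCountedLabels(spacing = 0.3)
    labs2 <- makeCountedLabels(spacing = 0.6)
    p1 <- fullGridPartition(labs1)
    p2 <- fullGridPartition(labs2)
    v1 <- computeVolumes(labs1, p1)
    v2 <- computeVolumes(labs2, p2)
    expect_equal(v2$btv_cm3, v1$btv_cm3 * 8, tolerance = 1e-12)
    hu <- array(-100, c(20, 20, 20))
    hu[labelData(labs1) == tissueCodes()[["gland"]]] <- 40
    r1 <- computePBD(ctVolume(hu, 0.3), labs1, p1, muFat = -100, muGland = 40)
    r2 <- computePBD(ctVolume(hu, 0.6), labs2, p2, muFat = -100, muGland = 40)
    expect_equal(r1$pbd_hu_pct, r2$pbd_hu_pct, tolerance = 1e-12)
})

test_that("shares sum to 100 and a symmetric phantom splits near 25", {
    spec <- phantomSpec(gridShape = c(64, 64, 64), breastSemiaxes = c(12, 6, 6),
                        nGlandComponents = 0L, glandVolumeTarget = 0,
                        pectoralDepth = 8L, includeRibs = FALSE,
                        includeSkinfold = FALSE, noiseSD = 0)
    ph <- generatePhantom(spec)
    expect_warning(labs <- segmentAll(ph$volume), "no glandular")
    part <- assignQuadrants(labs)
    comp <- composeFeatures(ph$volume, labs, part)
    tb <- compositionTable(comp)
    expect_equal(sum(tb$share_btv_pct[2:5]), 100, tolerance = 0.01)
    expect_true(all(abs(tb$share_btv_pct[2:5] - 25) <= 1))
    # degenerate whole-breast MGV: shares reported as missing
    expect_true(all(is.na(tb$share_mgv_pct)))
})

test_that("end-to-end phantom composition matches truth", {
    ph <- fixturePhantom("full")
    labs <- fixtureLabels("full")
    part <- assignQuadrants(labs)
    comp <- composeFeatures(ph$volume, labs, part)
    tb <- compositionTable(comp)
    expect_lt(abs(tb$btv_cm3[1] - ph$truth@btv) / ph$truth@btv, 0.05)
    expect_lt(abs(tb$mgv_cm3[1] - ph$truth@mgv) / ph$truth@mgv, 0.1)
    expect_lt(abs(tb$pbd_hu_pct[1] - ph$truth@pbd), 2)
})

test_that("degenerate HU references fail explicitly", {
    labs <- makeCountedLabels()
    part <- fullGridPartition(labs)
    vol <- ctVolume(array(-100, c(20, 20, 20)), 0.3)
    expect_error(computePBD(vol, labs, part, muFat = 40, muGland = -100),
                 "degenerate")
})
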