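test_that("phantom without gland components has zero gland truth", {
    spec <- phantomSpec(gridShape = c(48, 48, 48), breastSemiaxes = c(9, 4, 4),
                        nGlandComponents = 0L, glandVolumeTarget = 0,
                        pectoralDepth = 6L, includeRibs = FALSE,
                        includeSkinfold = FALSE, noiseSD = 0)
    ph <- generatePhantom(spec)
    expect_equal(ph$truth@mgv, 0)
    expect_equal(ph$truth@pbd, 0)
    expect_gt(ph$truth@btv, 0)
    expect_false(any(labelData(ph$truth@labelMap) ==
                     tissueCodes()[["gland"]]))
})

test_that("voxelized ellipsoid volume matches the closed form and converges", {
    # independent check of the sub-voxel fraction machinery: a 6 x 5 x 4 mm
    # ellipsoid has volume 4/3 * pi * 6 * 5 * 4 = 502.65 mm^3
    voxSum <- function(s) {
        n <- ceiling(16 / s)
        ax <- bctdensity:::.axisCoord(rep(n, 3), 1L, s)
        ay <- bctdensity:::.axisCoord(rep(n, 3), 2L, s)
        az <- bctdensity:::.axisCoord(rep(n, 3), 3L, s)
        ctr <- rep(n * s / 2, 3)
        d <- bctdensity:::.sdEllipsoid(ax, ay, az, ctr, c(6, 5, 4))
        sum(bctdensity:::.fracFromSd(d, s)) * s^3
    }
    vTrue <- 4 / 3 * pi * 6 * 5 * 4
    err03 <- abs(voxSum(0.3) - vTrue) / vTrue
    expect_lt(err03, 0.02)
    err015 <- abs(voxSum(0.15) - vTrue) / vTrue
    expect_lt(err015, err03 / 2)
})

test_that("gland volume is realized within 5% of the target", {
    ph <- fixturePhantom("full")
    expect_lt(abs(ph$truth@mgv - 0.5) / 0.5, 0.05)
})

test_that("phantom generation is deterministic under the seed", {
    spec <- phantomSpec(gridShape = c(64, 64, 64), breastSemiaxes = c(12, 6, 6),
                        glandVolumeTarget = 0.05, nGlandComponents = 2L,
                        pectoralDepth = 8L, includeRibs = FALSE,
                        includeSkinfold = FALSE, noiseSD = 5, seed = 42L)
    a <- generatePhantom(spec)
    b <- generatePhantom(spec)
    expect_identical(huData(a$volume), huData(b$volume))
    expect_identical(labelData(a$truth@labelMap), labelData(b$truth@labelMap))
    expect_identical(a$truth@mgv, b$truth@mgv)
    spec2 <- phantomSpec(gridShape = c(64, 64, 64),
                         breastSemiaxes = c(12, 6, 6),
                         glandVolumeTarget = 0.05, nGlandComponents = 2L,
                         pectoralDepth = 8L, includeRibs = FALSE,
                         includeSkinfold = FALSE, noiseSD = 5, seed = 43L)
    expect_false(identical(huData(a$volume),
                           huData(generatePhantom(spec2)$volume)))
})

test_that("quadrant truth partitions the whole-breast truth", {
    for (nm in c("mini", "full")) {
        tr <- fixturePhantom(nm)$truth
        voxvol <- prod(voxelSpacing(tr@labelMap)) / 1000
        expect_lt(abs(sum(tr@quadrant$btv_cm3) - tr@btv), voxvol + 1e-12)
        expect_lt(abs(sum(tr@quadrant$mgv_cm3) - tr@mgv), voxvol + 1e-12)
        expect_true(tr@mgv <= tr@btv)
        expect_true(tr@pbd >= 0 && tr@pbd <= 100)
    }
})

test_that("invalid phantom specs fail explicitly", {
    expect_error(phantomSpec(quadrantWeights = c(0.4, 0.3, 0.2, 0.2)),
                 "sum")
    expect_error(phantomSpec(skinThickness = 0.1), "voxel")
    expect_error(phantomSpec(hu = c(fat = -100, gland = -200, skin = 30,
                                    muscle = 45, rib = 700, air = -1000)),
                 "ordering")
    # breast that cannot fit in the grid
    expect_error(generatePhantom(
        phantomSpec(gridShape = c(40, 40, 40), breastSemiaxes = c(30, 5, 5),
                    includeRibs = FALSE, includeSkinfold = FALSE)),
        "degenerate grid")
    # gland target beyond the interior volume
    expect_error(generatePhantom(
        phantomSpec(gridShape = c(64, 64, 64), breastSemiaxes = c(12, 6, 6),
                    glandVolumeTarget = 5, nGlandComponents = 2L,
                    pectoralDepth = 8L, includeRibs = FALSE,
                    includeSkinfold = FALSE, noiseSD = 0)),
        "exceeds")
})

test_that("nipple protrudes as skin in the last tissue-bearing slice", {
    tl <- labelData(fixturePhantom("mini")$truth@labelMap)
    tissueSlices <- which(apply(tl != tissueCodes()[["air"]], 1, any))
    last <- max(tissueSlices)
    expect_true(any(tl[last, , ] == tissueCodes()[["skin"]]))
    # and the nipple coordinate sits there (within partial-volume rounding)
    expect_lte(abs(fixturePhantom("mini")$truth@nipple[1] - last), 1)
})
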