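test_that("an all-air volume fails with an explicit error", {
    vol <- ctVolume(array(-1000, c(8, 8, 8)))
    expect_error(bodyMask(vol), "no tissue")
})

test_that("body mask recovers the phantom body and is one component", {
    ph <- fixturePhantom("full")
    body <- bodyMask(ph$volume)
    truthBody <- labelData(ph$truth@labelMap) != tissueCodes()[["air"]]
    expect_lt(abs(sum(body) - sum(truthBody)) / sum(truthBody), 0.01)
    lab <- bctdensity:::labelComponents(body, 6L)
    expect_equal(attr(lab, "ncomponents"), 1L)
})

test_that("skin segmentation matches the analytic shell", {
    ph <- fixturePhantom("full")
    body <- bodyMask(ph$volume)
    sk <- segmentSkin(ph$volume, body)
    truthSkin <- labelData(ph$truth@labelMap) == tissueCodes()[["skin"]]
    expect_gte(diceCoef(sk$skin, truthSkin), 0.85)
    # skin exists in the last tissue-bearing slice (the nipple)
    lastSlice <- max(which(apply(body, 1, any)))
    expect_true(any(sk$skin[lastSlice, , ]))
    # zero thickness: no skin, interior is the whole body
    sk0 <- segmentSkin(ph$volume, body, segmentationParams(skinThickness = 0))
    expect_false(any(sk0$skin))
    expect_identical(sk0$interior, body)
})

test_that("chest structures are recovered and removed", {
    ph <- fixturePhantom("full")
    p <- segmentationParams()
    body <- bodyMask(ph$volume, p)
    sk <- segmentSkin(ph$volume, body, p)
    chest <- segmentChestStructures(ph$volume, sk$interior, p)
    tl <- labelData(ph$truth@labelMap)
    tc <- tissueCodes()
    truthPect <- tl == tc[["pectoralis"]]
    expect_gte(sum(chest$pectoralis & truthPect) / sum(truthPect), 0.9)
    expect_gt(sum(chest$rib), 0)
    expect_gt(sum(chest$skinfold), 0)
    # removed structures leave no rib-dense voxel in the breast interior
    expect_false(any(huData(ph$volume)[chest$breast] >= p@ribThreshold))
    # a phantom without ribs yields an empty rib mask
    ph2 <- fixturePhantom("mini")
    body2 <- bodyMask(ph2$volume, p)
    sk2 <- segmentSkin(ph2$volume, body2, p)
    chest2 <- segmentChestStructures(ph2$volume, sk2$interior, p)
    expect_false(any(chest2$rib))
    expect_false(any(chest2$skinfold))
})

test_that("a pure-fat interior yields an empty gland mask with a warning", {
    hu <- array(-1000, c(24, 24, 24))
    hu[6:18, 6:18, 6:18] <- -100
    vol <- ctVolume(hu)
    interior <- array(FALSE, dim(hu))
    interior[8:16, 8:16, 8:16] <- TRUE
    expect_warning(res <- segmentGland(vol, interior), "no glandular")
    expect_false(any(res$gland))
    expect_identical(res$adipose, interior)
})

test_that("noiseless gland segmentation matches the truth closely", {
    ph <- fixturePhantom("full")
    labs <- fixtureLabels("full")
    tc <- tissueCodes()
    tl <- labelData(ph$truth@labelMap)
    sl <- labelData(labs)
    expect_gte(diceCoef(sl == tc[["gland"]], tl == tc[["gland"]]), 0.95)
    # label-wise volumes within 10% of truth for adipose and gland
    for (cls in c("adipose", "gland")) {
        expect_lt(abs(sum(sl == tc[[cls]]) - sum(tl == tc[[cls]])) /
                  sum(tl == tc[[cls]]), 0.1)
    }
})

test_that("region growing equals the threshold-component oracle on small grids", {
    p <- segmentationParams()
    set.seed(77)
    for (rep in 1:5) {
        d <- c(18, 20, 16)
        g <- array(runif(prod(d), 0, 0.2), d)  # sub-floor clutter
        # a few solid blobs with one-voxel partial shells
        for (b in 1:3) {
            ctr <- sapply(d, function(n) sample(4:(n - 3), 1))
            rad <- sample(2:3, 1)
            idx <- which(array(TRUE, d), arr.ind = TRUE)
            dist <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
                         (idx[, 3] - ctr[3])^2)
            g[dist <= rad] <- 1
            shell <- dist > rad & dist <= rad + 1
            g[shell] <- pmax(g[shell], runif(sum(shell), 0.3, 0.6))
        }
        interior <- array(TRUE, d)
        hu <- -100 + 140 * g  # exact linear mixing, fixed references
        res <- bctdensity:::cpp_region_grow(
            as.numeric(g), as.logical(interior), as.integer(d),
            p@seedFraction, p@floorFraction, p@alpha, p@tol, p@maxIterations)
        grown <- array(res$mask, d)
        oracle <- glandOracle(g, interior, p@seedFraction, p@floorFraction)
        expect_identical(grown, oracle)
    }
})

test_that("raising the floor never grows the gland region", {
    ph <- fixturePhantom("mini")
    p0 <- segmentationParams()
    body <- bodyMask(ph$volume, p0)
    sk <- segmentSkin(ph$volume, body, p0)
    chest <- segmentChestStructures(ph$volume, sk$interior, p0)
    counts <- sapply(c(0.15, 0.25, 0.4, 0.6, 0.79), function(fl) {
        res <- segmentGland(ph$volume, chest$breast,
                            segmentationParams(floorFraction = fl))
        sum(res$gland)
    })
    expect_true(all(diff(counts) <= 0))
})

test_that("the density trace converges without oscillation", {
    labs <- fixtureLabels("full")
    tr <- densityTrace(labs)
    expect_true(length(tr) >= 1)
    expect_lt(length(tr), segmentationParams()@maxIterations)
    if (length(tr) > 3) {
        tail_d <- diff(tr[-(1:3)])
        expect_true(all(tail_d <= 1e-12) || all(tail_d >= -1e-12))
    }
})

test_that("segmentation labels partition the grid deterministically", {
    ph <- fixturePhantom("full")
    labs <- fixtureLabels("full")
    sl <- labelData(labs)
    expect_equal(length(sl), prod(dim(huData(ph$volume))))
    expect_true(all(sl %in% tissueCodes()))
    tc <- tissueCodes()
    # gland lies strictly inside the skin-stripped interior
    interior <- segmentSkin(ph$volume, bodyMask(ph$volume))$interior
    expect_true(all(interior[sl == tc[["gland"]]]))
    labs2 <- segmentAll(ph$volume)
    expect_identical(labelData(labs), labelData(labs2))
})
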