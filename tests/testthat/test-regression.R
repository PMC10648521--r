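test_that("noiseless data are recovered exactly", {
    ages <- 40:74
    y <- 2 * log(ages) + 1
    fit <- fitAgeModel(ages, y, "log")
    expect_equal(fit@a, 2, tolerance = 1e-9)
    expect_equal(fit@b, 1, tolerance = 1e-9)
    expect_equal(fit@rse, 0, tolerance = 1e-9)
    yi <- 100 / ages - 3
    fiti <- fitAgeModel(ages, yi, "inverse")
    expect_equal(fiti@a, 100, tolerance = 1e-9)
    expect_equal(fiti@b, -3, tolerance = 1e-9)
})

test_that("count-weighted group-mean fits reproduce the published models", {
    ref <- referenceAgeGroupStats()
    fb <- fitAgeModel(ref$age_mean, ref$btv_mean, "log", weights = ref$n)
    expect_lt(abs(fb@a - 290) / 290, 0.1)
    expect_lt(abs(fb@b - (-554)) / 554, 0.1)
    fm <- fitAgeModel(ref$age_mean, ref$mgv_mean, "inverse", weights = ref$n)
    expect_lt(abs(fm@a - 4885) / 4885, 0.1)
})

test_that("fits agree with a normal-equations oracle", {
    set.seed(55)
    ages <- c(41, 48, 55, 63, 71)
    y <- c(12.1, 9.8, 8.4, 7.9, 7.1)
    w <- c(3, 1, 2, 5, 4)
    for (fam in c("log", "inverse")) {
        x <- if (fam == "log") log(ages) else 1 / ages
        fit <- fitAgeModel(ages, y, fam, weights = w)
        oracle <- olsOracle(x, y, w)
        expect_equal(fit@a, unname(oracle["a"]), tolerance = 1e-10)
        expect_equal(fit@b, unname(oracle["b"]), tolerance = 1e-10)
        fitU <- fitAgeModel(ages, y, fam)
        oracleU <- olsOracle(x, y)
        expect_equal(fitU@a, unname(oracleU["a"]), tolerance = 1e-10)
    }
})

test_that("integer-weighted fits equal fits on row-replicated data", {
    ref <- referenceAgeGroupStats()
    fitW <- fitAgeModel(ref$age_mean, ref$btv_mean, "log", weights = ref$n)
    agesR <- rep(ref$age_mean, ref$n)
    yR <- rep(ref$btv_mean, ref$n)
    fitR <- fitAgeModel(agesR, yR, "log")
    expect_equal(fitW@a, fitR@a, tolerance = 1e-9)
    expect_equal(fitW@b, fitR@b, tolerance = 1e-9)
})

test_that("residual standard error follows its definition", {
    fit <- new("RegressionFit", family = "log", a = 2, b = 1,
               se = c(a = 0, b = 0), p = c(a = 0, b = 0), rse = 0,
               df = 2, n = 4, weighted = FALSE)
    ages <- c(45, 50, 60, 70)
    y <- predict(fit, ages) + c(1, -1, 1, -1)
    expect_equal(residualStandardError(fit, ages, y), sqrt(2),
                 tolerance = 1e-12)
    expect_equal(residualStandardError(fit, ages, predict(fit, ages)), 0)
    # rse equals rms residual scaled by sqrt(n / (n - 2))
    set.seed(99)
    ages2 <- sample(40:74, 40, replace = TRUE)
    y2 <- 3 * log(ages2) + rnorm(40)
    f2 <- fitAgeModel(ages2, y2, "log")
    rms <- sqrt(mean((y2 - predict(f2, ages2))^2))
    expect_equal(f2@rse, rms * sqrt(40 / 38), tolerance = 1e-9)
    expect_equal(residualStandardError(f2, ages2, y2), f2@rse,
                 tolerance = 1e-9)
})

test_that("grouped SSE reconstruction is exact for group-constant ages", {
    # single group, zero SD, mean on the curve: zero residual error
    fit <- new("RegressionFit", family = "inverse", a = 4885, b = -26,
               se = c(a = 0, b = 0), p = c(a = 0, b = 0), rse = 0,
               df = 5, n = 7, weighted = FALSE)
    expect_equal(rseFromGroupStats(50, 10, predict(fit, 50), 0, fit), 0)
    # grouped formula equals the raw-data SSE when ages are group-constant
    set.seed(14)
    gAges <- c(42, 52, 62, 72)
    ns <- c(8L, 12L, 9L, 11L)
    ages <- rep(gAges, ns)
    y <- 4000 / ages + rnorm(length(ages), sd = 20)
    f <- fitAgeModel(ages, y, "inverse")
    raw <- residualStandardError(f, ages, y)
    means <- tapply(y, ages, mean)
    sds <- tapply(y, ages, sd)
    grouped <- rseFromGroupStats(gAges, ns, as.numeric(means),
                                 as.numeric(sds), f)
    expect_equal(grouped, raw, tolerance = 1e-6)
})

test_that("predictions match the published curves arithmetically", {
    fitM <- new("RegressionFit", family = "inverse", a = 4885, b = -26,
                se = c(a = 0, b = 0), p = c(a = 0, b = 0), rse = 0,
                df = 5, n = 7, weighted = FALSE)
    expect_equal(predict(fitM, 72), 4885 / 72 - 26, tolerance = 1e-12)
    expect_equal(predict(fitM, 72), 41.8472, tolerance = 1e-4)
    fitP <- new("RegressionFit", family = "inverse", a = 1237, b = -8.4,
                se = c(a = 0, b = 0), p = c(a = 0, b = 0), rse = 0,
                df = 5, n = 7, weighted = FALSE)
    expect_equal(predict(fitP, 42), 21.0524, tolerance = 1e-4)
    # inverse-family predictions strictly decrease with age when a > 0
    expect_true(all(diff(predict(fitM, 40:74)) < 0))
    fitL <- new("RegressionFit", family = "log", a = 290, b = -554,
                se = c(a = 0, b = 0), p = c(a = 0, b = 0), rse = 0,
                df = 5, n = 7, weighted = FALSE)
    expect_true(all(diff(predict(fitL, 40:74)) > 0))
})

test_that("degenerate regression inputs fail explicitly", {
    expect_error(fitAgeModel(c(50, 50, 50), c(1, 2, 3), "log"), "degenerate")
    expect_error(fitAgeModel(c(-1, 50, 60), c(1, 2, 3), "log"), "positive")
    expect_error(fitAgeModel(c(50, 60), c(1, 2), "log"), "at least 3")
    fit <- fitAgeModel(c(45, 55, 65), c(1, 2, 3), "log")
    expect_error(predict(fit, c(0, 50)), "positive")
})
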