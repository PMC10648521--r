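# Phantom fixtures, generated once per test run and memoized.

.fixtureEnv <- new.env(parent = emptyenv())

fixturePhantom <- function(name) {
    if (!is.null(.fixtureEnv[[name]])) return(.fixtureEnv[[name]])
    spec <- switch(name,
        # small, fast, geometry-only phantom (no ribs/fold, noiseless)
        mini = phantomSpec(gridShape = c(64, 64, 64),
                           breastSemiaxes = c(12, 6, 6),
                           glandVolumeTarget = 0.1, nGlandComponents = 2L,
                           pectoralDepth = 8L, includeRibs = FALSE,
                           includeSkinfold = FALSE, noiseSD = 0, seed = 11L),
        # all structures present, noiseless, with a couple of large blobs
        full = phantomSpec(gridShape = c(128, 128, 128),
                           breastSemiaxes = c(18, 8, 8),
                           glandVolumeTarget = 0.5, nGlandComponents = 2L,
                           pectoralDepth = 10L, includeRibs = TRUE,
                           includeSkinfold = TRUE, noiseSD = 0, seed = 21L),
        # the default study phantom, noiseless (acceptance conditions)
        study = phantomSpec(noiseSD = 0),
        stop("unknown fixture ", name))
    ph <- generatePhantom(spec)
    ph$spec <- spec
    .fixtureEnv[[name]] <- ph
    ph
}

fixtureLabels <- function(name) {
    key <- paste0(name, "_labels")
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- segmentAll(fixturePhantom(name)$volume)
    .fixtureEnv[[key]]
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
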