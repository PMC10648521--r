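# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Otsu's between-class variance maximizer on a fixed-bin histogram.
# Ties are broken toward the lower threshold (conservative gland class).
otsuThreshold <- function(x, nbins = 256L) {
    r <- range(x)
    if (!all(is.finite(r)) || diff(r) == 0) return(r[1])
    br <- seq(r[1], r[2], length.out = nbins + 1L)
    h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE),
                             nbins))
    mids <- (br[-1] + br[-(nbins + 1L)]) / 2
    w1 <- cumsum(h)
    w2 <- sum(h) - w1
    m1 <- cumsum(h * mids) / w1
    m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
    bcv <- w1 * w2 * (m1 - m2)^2
    bcv[!is.finite(bcv)] <- -Inf
    mids[which.max(bcv)]
}

dimOf <- function(x) as.integer(dim(x))

# Squared Euclidean distance (mm^2) to the nearest FALSE voxel; space beyond
# the image border counts as foreground, so a body cut by the image boundary
# (the chest face) is not eroded there.
sqDistToBackground <- function(mask, spacing) {
    d <- cpp_sqedt3d(as.logical(mask), dimOf(mask), as.numeric(spacing))
    array(d, dim = dim(mask))
}

erodeBall <- function(mask, spacing, radius) {
    if (radius <= 0) return(mask)
    mask & (sqDistToBackground(mask, spacing) > radius^2)
}

labelComponents <- function(mask, connectivity = 6L) {
    lab <- cpp_label3d(as.logical(mask), dimOf(mask), as.integer(connectivity))
    ncomp <- attr(lab, "ncomponents")
    lab <- array(lab, dim = dim(mask))
    attr(lab, "ncomponents") <- ncomp
    lab
}

largestComponent <- function(mask, connectivity = 6L) {
    lab <- labelComponents(mask, connectivity)
    n <- attr(lab, "ncomponents")
    if (n == 0L) return(array(FALSE, dim(mask)))
    counts <- tabulate(lab[lab > 0L], n)
    array(lab == which.max(counts), dim(mask))
}

# Fill cavities: background components not touching the image border.
fillHoles <- function(mask) {
    lab <- labelComponents(!mask, connectivity = 6L)
    n <- attr(lab, "ncomponents")
    if (n == 0L) return(mask)
    d <- dim(mask)
    border <- unique(c(
        lab[c(1L, d[1]), , ], lab[, c(1L, d[2]), ], lab[, , c(1L, d[3])]))
    filled <- mask | array(!(lab %in% c(0L, border)), d)
    filled
}
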