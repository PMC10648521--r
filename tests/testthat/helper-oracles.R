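# Independent brute-force oracles, deliberately naive.

# flood fill over 26-connected TRUE voxels starting from `starts` (matrix of
# voxel indices), pure R
floodFill26 <- function(mask, starts) {
    d <- dim(mask)
    reached <- array(FALSE, d)
    if (!nrow(starts)) return(reached)
    queue <- starts
    reached[starts] <- TRUE
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    while (nrow(queue)) {
        p <- queue[1, , drop = FALSE]
        queue <- queue[-1, , drop = FALSE]
        for (t in seq_len(nrow(offs))) {
            q <- p + offs[t, ]
            if (any(q < 1L) || any(q > d)) next
            if (mask[q[1], q[2], q[3]] && !reached[q[1], q[2], q[3]]) {
                reached[q[1], q[2], q[3]] <- TRUE
                queue <- rbind(queue, q)
            }
        }
    }
    reached
}

# threshold-at-floor components that contain a seed: the expected result of
# the adaptive growing on clean two-population inputs
glandOracle <- function(g, interior, seedFraction, floorFraction) {
    candidates <- interior & (g >= floorFraction)
    seeds <- which(interior & (g >= seedFraction), arr.ind = TRUE)
    floodFill26(candidates, seeds)
}

# weighted least squares through explicit normal equations
olsOracle <- function(x, y, w = rep(1, length(x))) {
    X <- cbind(1, x)
    XtWX <- t(X) %*% (w * X)
    beta <- solve(XtWX, t(X) %*% (w * y))
    c(b = beta[1], a = beta[2])
}
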