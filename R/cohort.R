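.AGE_BINS <- data.frame(
    bin = c("40-44", "45-49", "50-54", "55-59", "60-64", "65-69", "70-74"),
    lo = seq(40L, 70L, 5L), hi = seq(44L, 74L, 5L))

.binOf <- function(age) {
    i <- findInterval(age, .AGE_BINS$lo)
    i[age < 40L | age > 74L] <- NA_integer_
    i
}

#' Age-group summaries of breast composition
#'
#' Aggregates per-breast records into the seven 5-year age bins (40-44
#' through 70-74): counts, means and sample standard deviations (n - 1
#' denominator) of age and of every numeric feature column present.
#' Records outside 40-74 are excluded; their count is reported via the
#' `excluded` attribute and a message, never dropped silently.
#'
#' @param records data.frame with an integer `age` column and numeric
#'   feature columns (e.g. `btv`, `mgv`, `pbd`).
#' @return data.frame with one row per age bin (`bin`, `n`, then
#'   `<feature>_mean` / `<feature>_sd` for age and each feature), with
#'   attribute `excluded` giving the number of out-of-range records.
#' @export
#' @examples
#' coh <- simulateCohort(cohortSimSpec(nPatients = 200, seed = 3))
#' summarizeByAge(coh)[, c("bin", "n", "btv_mean", "pbd_mean")]
summarizeByAge <- function(records) {
    if (!nrow(records)) stop("empty cohort")
    if (!"age" %in% names(records)) stop("records need an 'age' column")
    bin <- .binOf(records$age)
    excluded <- sum(is.na(bin))
    if (excluded > 0L)
        message(sprintf("excluded %d record(s) with age outside 40-74",
                        excluded))
    keep <- !is.na(bin)
    records <- records[keep, , drop = FALSE]
    bin <- bin[keep]
    if (!nrow(records)) stop("empty cohort after age exclusions")

    feats <- names(records)[vapply(records, is.numeric, logical(1))]
    feats <- setdiff(feats, "id")
    feats <- c("age", setdiff(feats, "age"))
    out <- data.frame(bin = .AGE_BINS$bin,
                      n = as.integer(tabulate(bin, 7L)))
    for (f in feats) {
        m <- s <- rep(NA_real_, 7L)
        for (i in seq_len(7L)) {
            v <- records[[f]][bin == i]
            v <- v[!is.na(v)]
            if (length(v)) {
                m[i] <- mean(v)
                s[i] <- if (length(v) > 1L) sd(v) else 0
            }
        }
        out[[paste0(f, "_mean")]] <- m
        out[[paste0(f, "_sd")]] <- s
    }
    attr(out, "excluded") <- excluded
    out
}

#' Two-sample pooled-variance Student t-test from summary statistics
#'
#' The closed-form pooled t statistic with a two-sided p-value from the t
#' distribution on n1 + n2 - 2 degrees of freedom, computable from group
#' means, SDs and sizes alone — the form needed when only published group
#' summaries are available. Degenerate groups (zero pooled variance) give
#' p = 1 for equal means and p = 0 otherwise.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return list with `t`, `df`, `p`.
#' @export
#' @examples
#' tTestFromStats(545, 345, 62, 676, 412, 70)
tTestFromStats <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (n1 < 2L || n2 < 2L) stop("need at least two observations per group")
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    if (se == 0) {
        if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
        return(list(t = sign(mean1 - mean2) * Inf, df = df, p = 0))
    }
    tstat <- (mean1 - mean2) / se
    list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Compare a feature between two groups (Student's t)
#'
#' Pooled-variance two-sample Student t-test on raw values; a thin wrapper
#' over [tTestFromStats()] so the raw-data and summary-statistics code
#' paths agree exactly. Set `welch = TRUE` for the unequal-variance
#' (Welch) variant.
#'
#' @param x,y Numeric vectors of the feature in the two groups.
#' @param welch Use the Welch approximation instead of the pooled test.
#' @return list with `t`, `df`, `p`.
#' @export
compareGroups <- function(x, y, welch = FALSE) {
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
        stop("need at least two observations per group")
    if (!welch)
        return(tTestFromStats(mean(x), sd(x), length(x),
                              mean(y), sd(y), length(y)))
    v1 <- var(x) / length(x)
    v2 <- var(y) / length(y)
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    if (se == 0) {
        if (mean(x) == mean(y)) return(list(t = 0, df = df, p = 1))
        return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
    }
    tstat <- (mean(x) - mean(y)) / se
    list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Quadrant share table
#'
#' Averages per-record quadrant shares (percent of whole-breast BTV and
#' MGV per quadrant, and the quadrant-to-whole PBD ratio) over the cohort,
#' optionally within each age group. Records with zero whole-breast MGV
#' have undefined MGV shares and are excluded from MGV-share (and PBD
#' ratio) averaging; the exclusion count is reported as an attribute and a
#' message.
#'
#' @param records data.frame in long quadrant format: columns `id`,
#'   optional `age`, `region` (UOQ/UIQ/LOQ/LIQ), `share_btv_pct`,
#'   `share_mgv_pct`, `pbd_ratio_pct` — as produced by flattening
#'   [BreastComposition-class] tables (see [compositionLong()]).
#' @param byAge Also split by 5-year age group (requires `age`).
#' @return data.frame of means and SDs per region (and age bin), with
#'   attribute `excluded_mgv` counting records without a defined MGV share.
#' @export
quadrantShareTable <- function(records, byAge = FALSE) {
    need <- c("id", "region", "share_btv_pct", "share_mgv_pct",
              "pbd_ratio_pct")
    if (!all(need %in% names(records)))
        stop("records must have columns: ", paste(need, collapse = ", "))
    records <- records[records$region %in% c("UOQ", "UIQ", "LOQ", "LIQ"), ,
                       drop = FALSE]
    badMGV <- unique(records$id[is.na(records$share_mgv_pct)])
    if (length(badMGV))
        message(sprintf(
            "excluded %d record(s) without defined MGV shares (zero whole-breast MGV)",
            length(badMGV)))
    grp <- if (byAge) {
        if (!"age" %in% names(records)) stop("byAge = TRUE requires 'age'")
        interaction(.AGE_BINS$bin[.binOf(records$age)], records$region,
                    drop = FALSE)
    } else factor(records$region, levels = c("UOQ", "UIQ", "LOQ", "LIQ"))

    agg <- function(col) {
        m <- tapply(records[[col]], grp, function(v) mean(v, na.rm = TRUE))
        s <- tapply(records[[col]], grp, function(v) sd(v, na.rm = TRUE))
        list(mean = as.numeric(m), sd = as.numeric(s))
    }
    btv <- agg("share_btv_pct")
    mgv <- agg("share_mgv_pct")
    pbdr <- agg("pbd_ratio_pct")
    out <- data.frame(group = names(table(grp)),
                      n = as.integer(table(grp)),
                      share_btv_mean = btv$mean, share_btv_sd = btv$sd,
                      share_mgv_mean = mgv$mean, share_mgv_sd = mgv$sd,
                      pbd_ratio_mean = pbdr$mean, pbd_ratio_sd = pbdr$sd,
                      row.names = NULL)
    attr(out, "excluded_mgv") <- length(badMGV)
    out
}

#' Flatten a BreastComposition to long per-region records
#'
#' @param composition A [BreastComposition-class].
#' @param id Record identifier.
#' @param age Optional age in years.
#' @return data.frame with one row per region.
#' @export
compositionLong <- function(composition, id, age = NA_integer_) {
    tb <- compositionTable(composition)
    cbind(data.frame(id = id, age = age), tb)
}

#' @importFrom stats var
NULL
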