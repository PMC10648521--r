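#' Fit an age-regression model
#'
#' Least-squares fit of one of the two breast-composition age models:
#' logarithmic, `y = a * ln(Age) + b` (used for breast tissue volume), or
#' multiplicative inverse, `y = a / Age + b` (gland volume and percent
#' density). The regressor is transformed and the model solved as ordinary
#' (optionally weighted) linear least squares; coefficient standard errors
#' and two-sided p-values come from standard linear-model theory with
#' n - 2 degrees of freedom. With integer weights the fit is identical to
#' an unweighted fit on the correspondingly replicated rows, which is how
#' grouped published means (weights = group counts) stand in for an
#' individual-level fit.
#'
#' @param ages Ages in years (positive).
#' @param y Response values.
#' @param family `"log"` or `"inverse"`.
#' @param weights Optional non-negative observation weights.
#' @return A [RegressionFit-class].
#' @export
#' @examples
#' ref <- referenceAgeGroupStats()
#' fit <- fitAgeModel(ref$age_mean, ref$btv_mean, "log", weights = ref$n)
#' coef(fit)
fitAgeModel <- function(ages, y, family = c("log", "inverse"),
                        weights = NULL) {
    family <- match.arg(family)
    if (length(ages) != length(y)) stop("'ages' and 'y' lengths differ")
    if (length(ages) < 3L) stop("need at least 3 observations")
    if (any(ages <= 0)) stop("ages must be positive")
    if (!is.null(weights) && any(weights < 0))
        stop("weights must be non-negative")
    x <- if (family == "log") log(ages) else 1 / ages
    if (max(x) - min(x) < .Machine$double.eps * 100)
        stop("degenerate design: all ages identical")
    fit <- if (is.null(weights)) lm(y ~ x) else lm(y ~ x, weights = weights)
    sm <- suppressWarnings(summary(fit))$coefficients
    n <- length(y)
    new("RegressionFit", family = family,
        a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
        se = c(a = sm[2, 2], b = sm[1, 2]),
        p = c(a = sm[2, 4], b = sm[1, 4]),
        rse = suppressWarnings(summary(fit))$sigma, df = n - 2, n = n,
        weighted = !is.null(weights))
}

#' Predicted feature values at given ages
#'
#' @param object A [RegressionFit-class].
#' @param ages Ages in years (positive).
#' @param ... Ignored.
#' @return Numeric vector of predicted values. For `a > 0` the prediction
#'   is strictly increasing in age under the logarithmic family and
#'   strictly decreasing under the multiplicative-inverse family.
#' @export
setMethod("predict", "RegressionFit", function(object, ages, ...) {
    if (any(ages <= 0)) stop("ages must be positive")
    if (object@family == "log") object@a * log(ages) + object@b
    else object@a / ages + object@b
})

#' Residual standard error from raw data
#'
#' `RSE = sqrt(SSE / (n - p - 1))` with `SSE = sum((y - yhat)^2)` and
#' p = 1 regressor, i.e. n - 2 degrees of freedom — the goodness-of-fit
#' measure in the units of the response.
#'
#' @param fit A [RegressionFit-class].
#' @param ages Ages in years.
#' @param y Observed responses.
#' @return The residual standard error.
#' @export
residualStandardError <- function(fit, ages, y) {
    n <- length(y)
    if (n <= 2L) stop("need more than 2 observations for a residual SE")
    sse <- sum((y - predict(fit, ages))^2)
    sqrt(sse / (n - 2))
}

#' Residual standard error reconstructed from group statistics
#'
#' When only per-group counts, means and SDs are available (a published
#' summary table), the error sum of squares about the fitted curve
#' decomposes exactly as
#' `SSE = sum_g [ (n_g - 1) * SD_g^2 + n_g * (mean_g - yhat(age_g))^2 ]`
#' provided ages are constant within groups; the residual standard error
#' is then `sqrt(SSE / (sum(n_g) - 2))`.
#'
#' @param ages Group ages (e.g. group mean ages), years.
#' @param ns Group sizes (each at least 1).
#' @param means Group means of the response.
#' @param sds Group sample standard deviations.
#' @param fit A [RegressionFit-class] providing the fitted curve.
#' @return The reconstructed residual standard error.
#' @export
#' @examples
#' ref <- referenceAgeGroupStats()
#' fit <- fitAgeModel(ref$age_mean, ref$btv_mean, "log", weights = ref$n)
#' rseFromGroupStats(ref$age_mean, ref$n, ref$btv_mean, ref$btv_sd, fit)
rseFromGroupStats <- function(ages, ns, means, sds, fit) {
    k <- length(ages)
    if (length(ns) != k || length(means) != k || length(sds) != k)
        stop("group vectors have inconsistent lengths")
    if (any(ns < 1)) stop("every group must have at least one observation")
    yhat <- predict(fit, ages)
    sse <- sum((ns - 1) * sds^2 + ns * (means - yhat)^2)
    sqrt(sse / (sum(ns) - 2))
}
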