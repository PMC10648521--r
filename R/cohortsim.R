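#' Default age-regression coefficients used by the cohort simulator
#'
#' Mean curves for breast tissue volume (logarithmic), mammary gland volume
#' and percent breast density (multiplicative inverse) as published for a
#' 1027-breast screening-age spiral breast CT cohort:
#' BTV = 290 ln(Age) - 554 cm^3, MGV = 4885 / Age - 26 cm^3,
#' PBD = 1237 / Age - 8.4 %.
#'
#' @return Named list with `btv`, `mgv`, `pbd`, each `c(a = , b = )`.
#' @export
referenceAgeModels <- function() {
    list(btv = c(a = 290, b = -554),
         mgv = c(a = 4885, b = -26),
         pbd = c(a = 1237, b = -8.4))
}

#' CohortSimSpec: parameters of the tabular cohort simulator
#'
#' @slot nPatients number of simulated breasts.
#' @slot ageRange integer(2), inclusive age bounds in years.
#' @slot binCounts optional integer(7): number of records per 5-year age
#'   bin (40-44 ... 70-74); overrides uniform age sampling.
#' @slot coefficients list of `c(a, b)` for btv (logarithmic), mgv and pbd
#'   (multiplicative inverse) mean curves.
#' @slot noiseSD named numeric(3): Gaussian noise SDs for btv (cm^3),
#'   mgv (cm^3) and pbd (%).
#' @slot truncate clamp simulated values to their physical ranges
#'   (BTV >= 0, 0 <= MGV <= BTV, 0 <= PBD <= 100).
#' @slot seed RNG seed.
#' @export
setClass("CohortSimSpec", representation(
    nPatients = "integer", ageRange = "integer", binCounts = "integer",
    coefficients = "list", noiseSD = "numeric", truncate = "logical",
    seed = "integer"))

setValidity("CohortSimSpec", function(object) {
    if (object@nPatients < 1L) return("'nPatients' must be positive")
    if (length(object@ageRange) != 2L || object@ageRange[1] < 1L ||
        object@ageRange[2] < object@ageRange[1])
        return("'ageRange' must be increasing positive integers")
    if (length(object@binCounts) > 0L) {
        if (length(object@binCounts) != 7L || any(object@binCounts < 0L))
            return("'binCounts' must be 7 non-negative counts")
    }
    if (!all(c("btv", "mgv", "pbd") %in% names(object@coefficients)))
        return("'coefficients' must name btv, mgv, pbd")
    if (any(object@noiseSD < 0)) return("noise SDs must be non-negative")
    TRUE
})

#' Construct a CohortSimSpec
#'
#' Defaults follow the study conditions the simulator emulates: ages 40-74
#' (integer years, as patient ages are recorded), the published mean curves
#' from [referenceAgeModels()], and noise SDs equal to the residual standard
#' errors of those models (386 cm^3, 67 cm^3, 13%).
#'
#' @param nPatients Number of breasts to simulate.
#' @param ageRange Inclusive integer age bounds.
#' @param binCounts Optional per-5-year-bin counts (overrides `nPatients`).
#' @param coefficients Mean-curve coefficients, as [referenceAgeModels()].
#' @param noiseSD Named noise SDs for btv, mgv, pbd.
#' @param truncate Clamp to physical ranges (default TRUE).
#' @param seed RNG seed.
#' @return A [CohortSimSpec-class].
#' @export
cohortSimSpec <- function(nPatients = 1033L, ageRange = c(40L, 74L),
                          binCounts = integer(0),
                          coefficients = referenceAgeModels(),
                          noiseSD = c(btv = 386, mgv = 67, pbd = 13),
                          truncate = TRUE, seed = 1L) {
    if (length(binCounts) > 0L) nPatients <- sum(binCounts)
    new("CohortSimSpec", nPatients = as.integer(nPatients),
        ageRange = as.integer(ageRange), binCounts = as.integer(binCounts),
        coefficients = coefficients, noiseSD = noiseSD,
        truncate = truncate, seed = as.integer(seed))
}

#' Simulate a tabular cohort of breast composition records
#'
#' Draws integer ages (uniformly over `ageRange`, or per-bin when
#' `binCounts` is given: within each 5-year bin ages are uniform over its
#' five integer years), evaluates the configured mean curves at each age
#' and adds independent Gaussian noise. With `truncate = TRUE` the values
#' are clamped to their physical ranges afterwards.
#'
#' @param spec A [CohortSimSpec-class].
#' @return data.frame with columns `id`, `age`, `btv`, `mgv`, `pbd`.
#' @export
#' @examples
#' coh <- simulateCohort(cohortSimSpec(nPatients = 100, seed = 7))
#' summary(coh$pbd)
simulateCohort <- function(spec) {
    validObject(spec)
    withSeed(spec@seed, {
        if (length(spec@binCounts) > 0L) {
            starts <- seq(40L, 70L, by = 5L)
            age <- unlist(lapply(seq_len(7L), function(i) {
                if (spec@binCounts[i] == 0L) return(integer(0))
                starts[i] + sample.int(5L, spec@binCounts[i],
                                       replace = TRUE) - 1L
            }))
        } else {
            age <- sample(seq(spec@ageRange[1], spec@ageRange[2]),
                          spec@nPatients, replace = TRUE)
        }
        n <- length(age)
        cf <- spec@coefficients
        btv <- cf$btv[1] * log(age) + cf$btv[2] +
            rnorm(n, 0, spec@noiseSD[["btv"]])
        mgv <- cf$mgv[1] / age + cf$mgv[2] + rnorm(n, 0, spec@noiseSD[["mgv"]])
        pbd <- cf$pbd[1] / age + cf$pbd[2] + rnorm(n, 0, spec@noiseSD[["pbd"]])
        if (spec@truncate) {
            btv <- pmax(btv, 0)
            mgv <- clamp(mgv, 0, btv)
            pbd <- clamp(pbd, 0, 100)
        }
        data.frame(id = seq_len(n), age = as.integer(age),
                   btv = btv, mgv = mgv, pbd = pbd)
    })
}
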