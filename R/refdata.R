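#' Published reference cohort statistics by age group
#'
#' The packaged age-group summary table of a published 1027-examination
#' spiral breast CT screening cohort (517 women aged 40-74): per 5-year
#' age bin, the number of examinations and the mean and SD of age, breast
#' tissue volume (cm^3), mammary gland volume (cm^3) and percent breast
#' density (%). These summaries are the input for the grouped
#' reproduction fits (see [fitAgeModel()] and [rseFromGroupStats()]).
#'
#' Note: the published per-bin counts total 1033 while the accompanying
#' text reports 1027 examinations; the table is stored exactly as printed
#' and the discrepancy is left unresolved.
#'
#' @return data.frame with columns `bin`, `n`, `age_mean`, `age_sd`,
#'   `btv_mean`, `btv_sd`, `mgv_mean`, `mgv_sd`, `pbd_mean`, `pbd_sd`.
#' @export
#' @examples
#' ref <- referenceAgeGroupStats()
#' sum(ref$n)
referenceAgeGroupStats <- function() {
    read.csv(system.file("extdata", "age_group_reference.csv",
                         package = "bctdensity"))
}

#' Published reference quadrant composition statistics
#'
#' The packaged whole-cohort quadrant table of the same published cohort
#' as [referenceAgeGroupStats()]: mean and SD of BTV, MGV and PBD for the
#' entire breast and each quadrant, the quadrant percentage shares of BTV
#' and MGV, and the quadrant-to-whole PBD ratio.
#'
#' @return data.frame with one row per region (Entire, UOQ, UIQ, LOQ, LIQ).
#' @export
referenceQuadrantStats <- function() {
    read.csv(system.file("extdata", "quadrant_reference.csv",
                         package = "bctdensity"))
}
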