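# Published reference demographics for the dilated-RV heart-failure cohort
# that the synthetic generator is calibrated against.

#' Reference cohort demographics
#'
#' Per-patient age, NYHA class, RV end-systolic and end-diastolic volumes
#' (mL) and right-ventricular ejection fraction (%) for the ten-patient
#' dilated-RV heart-failure cohort whose summary statistics (EDV 283 +/- 38
#' mL, EF 22 +/- 7 %) calibrate the synthetic anatomy defaults.  Summary
#' dispersion uses the population (divide-by-n) SD, which reproduces the
#' published EDV and EF summary values.
#'
#' @return data.frame with columns `patient`, `age_yr`, `sex`,
#'   `nyha_class`, `esv_ml`, `edv_ml`, `ef_pct`
#' @export
reference_cohort <- function() {
  read.csv(system.file("extdata", "reference_cohort.csv",
                       package = "lpmcollide"))
}

#' Summary statistics of the reference cohort
#'
#' Means and population SDs of age, ESV, EDV and EF, plus the EF recomputed
#' from the volume columns (`100 * (EDV - ESV) / EDV`).
#'
#' @return list of named numerics
#' @export
reference_cohort_summary <- function() {
  rc <- reference_cohort()
  ef_recomputed <- 100 * (rc$edv_ml - rc$esv_ml) / rc$edv_ml
  list(mean_age = mean(rc$age_yr), sd_age = pop_sd(rc$age_yr),
       mean_esv = mean(rc$esv_ml), sd_esv = pop_sd(rc$esv_ml),
       mean_edv = mean(rc$edv_ml), sd_edv = pop_sd(rc$edv_ml),
       mean_ef = mean(rc$ef_pct), sd_ef = pop_sd(rc$ef_pct),
       ef_recomputed = ef_recomputed)
}
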