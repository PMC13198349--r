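# Cohort-level aggregation: regional prevalence tables, device-length
# trends, collision-free fractions, paired device comparisons, and summed
# prevalence maps.

# population (divide-by-n) standard deviation, matching the cohort summary
# arithmetic used throughout
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

STRUCTURE_FIELDS <- c(rv_wall = "RV_WALL", pm = "PM", tv = "TV",
                      combined = "COMBINED")

#' Regional collision-risk statistics across patients
#'
#' Per patient, the regional risk is `100 * positives / sites` in the
#' region; the table reports the mean and population SD across patients for
#' every structure category and COMBINED, in every AHA region, every LBBAP
#' region, and over the whole septum (`ALL_SEPTUM`).  Patients with no site
#' in a region are omitted from it with a warning.
#'
#' @param records row-bound [run_patient()] outputs (any number of patients,
#'   one device)
#' @param labels row-bound [septal_labels()] outputs with a `patient` column
#'   aligned to `records`
#' @return data.frame: `device`, `region_type` (`AHA`/`LBBAP`/`ALL`),
#'   `region`, `structure`, `mean_pct`, `sd_pct`, `n_patients`
#' @export
regional_stats <- function(records, labels) {
  stopifnot(length(unique(records$device)) == 1)
  df <- merge(records, labels, by = c("patient", "node"))
  regions <- c(
    lapply(c(2, 3, 8, 9, 14), function(a) list(type = "AHA", id = as.character(a),
                                               sel = df$aha == a)),
    lapply(c("LBB", "LAF", "LPF", "LSF"), function(b) list(type = "LBBAP", id = b,
                                                           sel = df$lbbap == b)),
    list(list(type = "ALL", id = "ALL_SEPTUM", sel = rep(TRUE, nrow(df)))))
  out <- list()
  for (rg in regions) {
    sub <- df[rg$sel, , drop = FALSE]
    pat <- unique(df$patient)
    present <- unique(sub$patient)
    if (length(present) < length(pat)) {
      warning(sprintf("region %s empty for %d patient(s); omitted",
                      rg$id, length(pat) - length(present)))
    }
    if (length(present) == 0) next
    for (fld in names(STRUCTURE_FIELDS)) {
      risk <- vapply(present, function(p) {
        s <- sub[sub$patient == p, fld]
        100 * mean(s)
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        device = records$device[1], region_type = rg$type, region = rg$id,
        structure = STRUCTURE_FIELDS[[fld]],
        mean_pct = mean(risk), sd_pct = pop_sd(risk),
        n_patients = length(present))
    }
  }
  do.call(rbind, out)
}

#' Linear trend of regional risk in device length
#'
#' Ordinary least squares of mean regional risk on device length, reported
#' as percent per 5 mm, with the Pearson correlation; constant risk yields a
#' zero slope and missing `r`.
#'
#' @param stats data.frame with columns `region`, `structure`, `length_mm`,
#'   `mean_pct` (one row per sweep length), e.g. row-bound
#'   [regional_stats()] outputs augmented with `length_mm`
#' @return data.frame: `region`, `structure`, `slope_per_5mm`, `pearson_r`,
#'   `n_lengths`
#' @export
length_trend <- function(stats) {
  keys <- unique(stats[, c("region", "structure")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- stats[stats$region == keys$region[i] &
                   stats$structure == keys$structure[i], ]
    sub <- sub[order(sub$length_mm), ]
    if (nrow(sub) < 3) stop("length_trend needs >= 3 lengths")
    fit <- lm(mean_pct ~ length_mm, data = sub)
    r <- if (stats::var(sub$mean_pct) < 1e-20) NA_real_ else
      cor(sub$length_mm, sub$mean_pct)
    data.frame(region = keys$region[i], structure = keys$structure[i],
               slope_per_5mm = unname(coef(fit)[2]) * 5, pearson_r = r,
               n_lengths = nrow(sub))
  })
  do.call(rbind, out)
}

#' Collision-free fraction of a region, pooled over patients
#'
#' `100 * combined-negative sites / region sites`, site-weighted across the
#' whole cohort (the complement of the pooled combined prevalence).
#'
#' @param records row-bound [run_patient()] outputs for one device
#' @param labels row-bound [septal_labels()] outputs with `patient`
#' @param region LBBAP region name, AHA id (as character), or
#'   `"ALL_SEPTUM"`
#' @return percentage in `[0, 100]`
#' @export
collision_free_fraction <- function(records, labels, region = "ALL_SEPTUM") {
  df <- merge(records, labels, by = c("patient", "node"))
  sel <- if (region == "ALL_SEPTUM") rep(TRUE, nrow(df))
  else if (region %in% c("LBB", "LAF", "LPF", "LSF")) df$lbbap == region
  else df$aha == as.integer(region)
  if (!any(sel)) stop("region ", region, " is empty")
  100 * mean(!df$combined[sel])
}

#' Paired t comparison of two devices' regional risks
#'
#' Paired t test on per-patient regional risks, Bonferroni-corrected by the
#' declared number of comparisons (p multiplied and capped at 1).  A
#' zero-variance nonzero difference is degenerate and reported with
#' `t = Inf` and `p = 0`; identical risks give `t = 0`, `p = 1`.
#'
#' @param risk_a,risk_b per-patient regional risks (%) for devices A and B,
#'   aligned by patient
#' @param n_comparisons Bonferroni family size (default 1)
#' @return list: `mean_diff`, `t`, `df`, `p`, `p_adj`, `degenerate`
#' @export
pairwise_device_compare <- function(risk_a, risk_b, n_comparisons = 1) {
  if (length(risk_a) != length(risk_b)) stop("unpaired inputs")
  if (length(risk_a) < 2) stop("need >= 2 patients for a paired t test")
  d <- risk_a - risk_b
  if (pop_sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) {
      return(list(mean_diff = 0, t = 0, df = length(d) - 1, p = 1, p_adj = 1,
                  degenerate = FALSE))
    }
    return(list(mean_diff = mean(d), t = Inf, df = length(d) - 1, p = 0,
                p_adj = 0, degenerate = TRUE))
  }
  tt <- t.test(risk_a, risk_b, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       p_adj = min(1, tt$p.value * n_comparisons), degenerate = FALSE)
}

#' Cohort prevalence map on the standardized grid
#'
#' Bins each patient's combined outcome onto the `(rho, phi)` grid (a cell
#' is positive for a patient when any of the patient's nodes in that cell
#' is positive), then counts positive patients per cell.  The proportion is
#' over patients covering the cell, thresholdable (e.g. `> 0.5`) for map
#' overlays.
#'
#' @param records row-bound [run_patient()] outputs for one device
#' @param labels row-bound [septal_labels()] outputs with `patient`
#' @param resolution grid cells per axis
#' @param field which outcome to map (default `"combined"`)
#' @return list: `count` (patients positive), `coverage` (patients with
#'   nodes in cell), `proportion`
#' @export
cohort_prevalence_map <- function(records, labels, resolution = 50,
                                  field = "combined") {
  df <- merge(records, labels, by = c("patient", "node"))
  count <- matrix(0L, resolution, resolution)
  coverage <- matrix(0L, resolution, resolution)
  for (p in unique(df$patient)) {
    sub <- df[df$patient == p, ]
    g <- grid_resample(sub[, c("rho", "phi")], sub[[field]], resolution)
    covered <- g$counts > 0
    coverage[covered] <- coverage[covered] + 1L
    positive <- covered & !is.na(g$grid) & g$grid > 0
    count[positive] <- count[positive] + 1L
  }
  proportion <- count / pmax(coverage, 1L)
  proportion[coverage == 0] <- NA_real_
  list(count = count, coverage = coverage, proportion = proportion)
}
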