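# Cohort aggregation: regional statistics, trends, collision-free
# fractions, paired comparisons, prevalence maps.

fake_records <- function(patient, combined, extra = NULL) {
  n <- length(combined)
  df <- data.frame(patient = patient, node = seq_len(n), device = "dev",
                   length_mm = 30, diameter_mm = 6.5,
                   rv_wall = combined, pm = FALSE, tv = FALSE,
                   combined = combined,
                   frames_hit_rv_wall = as.integer(combined),
                   frames_hit_pm = 0L, frames_hit_tv = 0L)
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

fake_labels <- function(patient, n, aha = 2L, lbbap = "none") {
  data.frame(node = seq_len(n), rho = 0.8, phi = 0.25, aha = aha,
             lbbap = lbbap, tv_band = FALSE, patient = patient)
}

test_that("regional statistics reproduce hand-computable cases", {
  rec <- rbind(fake_records(1, rep(TRUE, 10)), fake_records(2, rep(TRUE, 10)))
  lab <- rbind(fake_labels(1, 10), fake_labels(2, 10))
  rs <- suppressWarnings(regional_stats(rec, lab))
  all_comb <- rs[rs$region == "ALL_SEPTUM" & rs$structure == "COMBINED", ]
  expect_equal(all_comb$mean_pct, 100)
  expect_equal(all_comb$sd_pct, 0)
  expect_equal(all_comb$n_patients, 2)
  # 100% and 0% patients: mean 50, population SD 50
  rec2 <- rbind(fake_records(1, rep(TRUE, 10)), fake_records(2, rep(FALSE, 10)))
  rs2 <- suppressWarnings(regional_stats(rec2, lab))
  r2 <- rs2[rs2$region == "2" & rs2$structure == "COMBINED", ]
  expect_equal(r2$mean_pct, 50)
  expect_equal(r2$sd_pct, 50)
})

test_that("regional statistics match a brute-force tabulation on real records", {
  an <- coarse_patient()
  lab <- septal_labels(an)
  dev <- lpm_catalogue()[[1]]
  rec <- run_patient(an, dev, patient = 1L)
  lab$patient <- 1L
  rs <- regional_stats(rec, lab)
  # independent tabulation for AHA region 9, PM structure
  sel <- lab$node[lab$aha == 9]
  manual <- 100 * mean(rec$pm[rec$node %in% sel])
  got <- rs[rs$region == "9" & rs$structure == "PM", ]
  expect_equal(got$mean_pct, manual, tolerance = 1e-12)
  expect_equal(got$sd_pct, 0)  # single patient
  # ALL_SEPTUM equals the site-weighted average of AHA regional risks
  w <- table(lab$aha)
  per_region <- vapply(names(w), function(a) {
    100 * mean(rec$combined[rec$node %in% lab$node[lab$aha == as.integer(a)]])
  }, numeric(1))
  expect_equal(rs[rs$region == "ALL_SEPTUM" & rs$structure == "COMBINED", "mean_pct"],
               sum(per_region * as.numeric(w)) / sum(w), tolerance = 1e-12)
  # COMBINED >= every structure, per region
  for (rg in unique(rs$region)) {
    sub <- rs[rs$region == rg, ]
    expect_gte(sub$mean_pct[sub$structure == "COMBINED"],
               max(sub$mean_pct[sub$structure != "COMBINED"]))
  }
})

test_that("patients missing a region are omitted with a warning", {
  rec <- rbind(fake_records(1, rep(TRUE, 4)), fake_records(2, rep(FALSE, 4)))
  lab <- rbind(fake_labels(1, 4, aha = 2L), fake_labels(2, 4, aha = 3L))
  w <- capture_warnings(rs <- regional_stats(rec, lab))
  expect_true(any(grepl("omitted", w)))
  r2 <- rs[rs$region == "2" & rs$structure == "COMBINED", ]
  expect_equal(r2$n_patients, 1)
  expect_equal(r2$mean_pct, 100)
})

test_that("length trends recover exact linear and constant relationships", {
  stats <- data.frame(region = "ALL_SEPTUM", structure = "COMBINED",
                      length_mm = seq(15, 45, 5),
                      mean_pct = 10 + 0.8 * seq(15, 45, 5))
  tr <- length_trend(stats)
  expect_equal(tr$slope_per_5mm, 4, tolerance = 1e-12)
  expect_equal(tr$pearson_r, 1, tolerance = 1e-12)
  stats$mean_pct <- 42
  tr2 <- length_trend(stats)
  expect_equal(tr2$slope_per_5mm, 0, tolerance = 1e-12)
  expect_true(is.na(tr2$pearson_r))
  # hand OLS on irregular values
  y <- c(20, 31, 35, 52, 55, 70, 71)
  x <- seq(15, 45, 5)
  stats$mean_pct <- y
  tr3 <- length_trend(stats)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(tr3$slope_per_5mm, beta * 5, tolerance = 1e-12)
  expect_equal(tr3$pearson_r, cor(x, y), tolerance = 1e-12)
  expect_error(length_trend(stats[1:2, ]), ">= 3")
})

test_that("collision-free fraction is the pooled complement of prevalence", {
  rec <- rbind(fake_records(1, c(rep(TRUE, 3), rep(FALSE, 7))),
               fake_records(2, c(rep(TRUE, 8), rep(FALSE, 2))))
  lab <- rbind(fake_labels(1, 10, lbbap = "LAF"),
               fake_labels(2, 10, lbbap = "LAF"))
  cf <- collision_free_fraction(rec, lab, "LAF")
  expect_equal(cf, 100 * 9 / 20)
  # pooled (site-weighted) differs from the per-patient mean when region
  # sizes differ
  rec3 <- rbind(fake_records(1, rep(TRUE, 2)), fake_records(2, rep(FALSE, 18)))
  lab3 <- rbind(fake_labels(1, 2, lbbap = "LBB"),
                fake_labels(2, 18, lbbap = "LBB"))
  pooled <- collision_free_fraction(rec3, lab3, "LBB")
  expect_equal(pooled, 100 * 18 / 20)
  per_patient_mean <- mean(c(0, 100))
  expect_false(isTRUE(all.equal(pooled, per_patient_mean)))
  # all-negative region
  recn <- fake_records(1, rep(FALSE, 5))
  labn <- fake_labels(1, 5)
  expect_equal(collision_free_fraction(recn, labn, "ALL_SEPTUM"), 100)
})

test_that("paired device comparison matches the textbook t statistic", {
  set.seed(8)
  a <- runif(10, 40, 90)
  b <- a - rnorm(10, 5, 3)
  res <- pairwise_device_compare(a, b, n_comparisons = 4)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 9)
  expect_equal(res$p_adj, min(1, res$p * 4))
  # identical risks
  same <- pairwise_device_compare(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_adj, 1)
  # constant nonzero shift: zero variance of differences, degenerate
  shift <- pairwise_device_compare(a, a - 5)
  expect_true(shift$degenerate)
  expect_equal(shift$mean_diff, 5)
})

test_that("prevalence maps sum patients and shrink with the threshold", {
  an <- coarse_patient()
  lab <- septal_labels(an); lab$patient <- 1L
  rec <- run_patient(an, lpm_catalogue()[[2]], patient = 1L)
  m1 <- cohort_prevalence_map(rec, lab, resolution = 12)
  # single patient: count equals the patient's binary grid
  g <- grid_resample(lab[, c("rho", "phi")], rec$combined, 12)
  expect_identical(m1$count > 0, !is.na(g$grid) & g$grid > 0)
  # opposite second patient: every covered cell counts exactly one patient
  rec2 <- rec; rec2$patient <- 2L
  rec2$combined <- !rec$combined
  rec2$rv_wall <- !rec$rv_wall
  lab2 <- lab; lab2$patient <- 2L
  both <- cohort_prevalence_map(rbind(rec, rec2), rbind(lab, lab2),
                                resolution = 12)
  covered <- both$coverage == 2
  has_pos_and_neg <- covered & !is.na(g$grid) & g$grid > 0 & g$grid < 1
  # cells where patient 1 was mixed are counted for both patients; pure
  # cells for exactly one
  pure <- covered & !has_pos_and_neg
  expect_true(all(both$count[pure] == 1))
  # threshold overlay monotonicity
  area <- vapply(c(0.25, 0.5, 0.75), function(th) {
    sum(both$proportion > th, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(area) <= 0))
})
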