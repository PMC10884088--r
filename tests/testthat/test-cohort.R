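# Study-cohort fixture, summaries, correlation, virtual patients, recovery.

test_that("the cohort fixture carries the printed records", {
  fx <- load_table1_fixture()
  expect_equal(nrow(fx), 20)
  expect_equal(fx$ji[fx$id == 1], 91.5)
  expect_equal(fx$e_mpa[fx$id == 1], 6.1)
  expect_equal(fx$orifice_area[fx$id == 15], 165.2)
  expect_equal(fx$p_sys[fx$id == 1], 162.0)
  expect_equal(fx$hr[fx$id == 1], 92.0)
})

test_that("cohort summaries use the sample SD and one-decimal reporting", {
  fx <- load_table1_fixture()
  s <- cohort_summary(fx, "e_mpa")
  expect_equal(s$mean, mean(fx$e_mpa))
  expect_equal(s$sd, sd(fx$e_mpa))
  expect_equal(s$mean_1dp, 5.6)
  expect_equal(s$sd_1dp, 1.3)
  expect_equal(cohort_summary(fx, "ji")$mean_1dp, 87.0)
  expect_equal(cohort_summary(fx, "orifice_area")$mean_1dp, 114.0)
  expect_error(cohort_summary(fx, "nothere"), "Unknown column")
  expect_error(cohort_summary(fx[1, ], "e_mpa"), "2 records")
  # the shipped summary rows agree with recomputation to within one unit
  # of the printed decimal (the source summary was computed from unrounded
  # per-patient data, so the last digit can differ)
  summ <- load_table1_summary()
  for (cn in c("p_sys", "p_dias", "hr", "e_mpa", "ji", "orifice_area")) {
    expect_lt(abs(cohort_summary(fx, cn)$mean_1dp -
                    summ[[cn]][summ$statistic == "mean"]), 0.1005)
    expect_lt(abs(cohort_summary(fx, cn)$sd_1dp -
                    summ[[cn]][summ$statistic == "sd"]), 0.1005)
  }
})

test_that("Pearson correlation matches a hand-computed oracle", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  # oracle: covariance over product of SDs, p from the t transform
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_correlation(x, y)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$r, 0.98198, tolerance = 1e-4)
  tstat <- r_hand * sqrt(1 / (1 - r_hand^2))  # n - 2 = 1 df
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), df = 1),
               tolerance = 1e-10)
  expect_equal(pearson_correlation(1:5, 2 * (1:5))$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "variance")
})

test_that("virtual patients are reproducible and respect their bounds", {
  p1 <- generate_virtual_patient(seed = 7)
  p2 <- generate_virtual_patient(seed = 7)
  expect_equal(p1$E_wall, p2$E_wall)
  expect_equal(p1$measurements_noisy$strain, p2$measurements_noisy$strain)
  expect_equal(p1$measurements_noisy$orifice_area,
               p2$measurements_noisy$orifice_area)
  expect_false(isTRUE(all.equal(
    p1$E_wall, generate_virtual_patient(seed = 8)$E_wall)))
  cohort <- generate_cohort(100, seed = 31)
  tbl <- cohort_table(cohort)
  expect_true(all(tbl$p_sys > tbl$p_dias))
  expect_true(all(tbl$E_wall >= 1.5 & tbl$E_wall <= 13))
  expect_true(all(tbl$E_leaflet >= 1.5 & tbl$E_leaflet <= 13))
  expect_true(all(tbl$peak_gradient >= 15 & tbl$peak_gradient <= 80))
  expect_true(all(tbl$orifice_area >= 0))
})

test_that("noise-free measurements reproduce the forward model exactly", {
  p <- generate_virtual_patient(seed = 19)
  truth <- p$forward$run(p$E_wall, "wall_strain")
  expect_equal(as.numeric(p$measurements_clean$strain[names(truth)]),
               as.numeric(truth), tolerance = 1e-12)
  expect_equal(p$measurements_clean$orifice_area,
               p$forward$run(p$E_leaflet, "orifice_area"),
               tolerance = 1e-12)
})

test_that("cohort hemodynamics centre on the configured distribution", {
  tbl <- cohort_table(generate_cohort(500, seed = 101))
  se <- sd(tbl$p_sys) / sqrt(nrow(tbl))
  expect_lt(abs(mean(tbl$p_sys) - 129.4), 3 * se + 1)
  se_d <- sd(tbl$p_dias) / sqrt(nrow(tbl))
  expect_lt(abs(mean(tbl$p_dias) - 61.2), 3 * se_d + 2)
})

test_that("recovery error grows with measurement noise", {
  exp <- recovery_experiment(n_patients = 12, seed = 5,
                             noise_levels = c(0, 0.05))
  s <- tidy(exp)
  expect_equal(nrow(s), 2)
  expect_true(all(c("bias_rel_pct", "median_abs_rel_err_pct",
                    "rmse_rel_pct", "flag_rate", "failures") %in% names(s)))
  expect_true(all(is.finite(s$rmse_rel_pct)))
  expect_lt(s$rmse_rel_pct[s$noise_level == 0], 1)
  expect_gte(s$rmse_rel_pct[s$noise_level == 0.05],
             s$rmse_rel_pct[s$noise_level == 0])
  expect_equal(sum(s$failures), 0)
})
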