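# Inverse engine: design, surrogate fit, cost solution, calibration,
# verification and the deployment sensitivity surrogate.

test_that("the modulus design is reproducible and range-bounded", {
  d1 <- sample_design(seed = 11)
  d2 <- sample_design(seed = 11)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 15)
  expect_true(all(d1$E_mpa >= 0.8 & d1$E_mpa <= 15))
  expect_gte(length(unique(d1$E_mpa)), 3)
  expect_false(identical(d1$E_mpa, sample_design(seed = 12)$E_mpa))
  expect_error(sample_design(n = 2, seed = 1), "3")
  expect_error(sample_design(E_low = 15, E_high = 0.8, seed = 1), "E_low")
  if (requireNamespace("lhs", quietly = TRUE)) {
    dl <- sample_design(seed = 5, method = "lhs")
    expect_true(all(dl$E_mpa >= 0.8 & dl$E_mpa <= 15))
    expect_identical(dl, sample_design(seed = 5, method = "lhs"))
  }
})

test_that("exact quadratic responses are recovered to machine precision", {
  E <- sample_design(seed = 3)$E_mpa
  y <- 2 + 3 * E - 0.1 * E^2
  s <- fit_surrogate(E, y, "strain_annulus")
  expect_equal(unname(s$beta), c(2, 3, -0.1), tolerance = 1e-8)
  expect_lt(s$residual_rms, 1e-10)
  expect_equal(tidy(s)$estimate, unname(s$beta))
  expect_equal(glance(s)$n_samples, 15)
})

test_that("surrogate coefficients match the normal-equations oracle", {
  E <- sample_design(seed = 7)$E_mpa
  y <- 4.04 / E  # a 1/E response, not representable exactly
  s <- fit_surrogate(E, y)
  X <- cbind(1, E, E^2)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(max(abs(unname(s$beta) - as.numeric(beta_oracle)) /
                  abs(as.numeric(beta_oracle))), 1e-10)
  expect_error(fit_surrogate(c(1, 1, 2), c(1, 2, 3)), "distinct")
  expect_error(fit_surrogate(c(1, 2, 3), c(1, NA, 3)), "finite")
})

test_that("the cost solver picks the stiffness-decreasing root", {
  # linear identity: f(E) = E
  lin <- fit_surrogate(c(1, 5, 10, 14), c(1, 5, 10, 14))
  expect_equal(solve_cost(lin, 5)$E, 5, tolerance = 1e-9)
  # concave quadratic f(E) = -(E-3)(E-11): roots 3 and 11 at measured 0,
  # decreasing branch only at 11
  E <- c(1, 4, 7, 10, 13)
  s <- fit_surrogate(E, -(E - 3) * (E - 11))
  sol <- solve_cost(s, 0, E_range = c(0.8, 15))
  expect_equal(sol$E, 11, tolerance = 1e-9)
  expect_true("multiple_roots" %in% sol$flags)
  expect_equal(sort(sol$roots), c(3, 11), tolerance = 1e-9)
  # measured above the maximum f(7) = 16: vertex argmin, no real root
  sol2 <- solve_cost(s, 20, E_range = c(0.8, 15))
  expect_true("no_real_root" %in% sol2$flags)
  expect_equal(sol2$E, 7, tolerance = 1e-6)
  # out-of-range root on a monotone line: boundary argmin with flag
  sol3 <- solve_cost(lin, 99, E_range = c(1, 14))
  expect_true("boundary_solution" %in% sol3$flags)
  expect_equal(sol3$E, 14)
  # flat surrogate: poor fit when it happens to match, error otherwise
  flat <- fit_surrogate(c(1, 5, 10), c(5, 5, 5))
  expect_error(solve_cost(flat, 7), "Degenerate")
  solf <- solve_cost(flat, 5)
  expect_true(is.na(solf$E))
  expect_true("poor_fit" %in% solf$flags)
})

test_that("the combined minimizer matches a brute-force grid scan", {
  E <- sample_design(seed = 21)$E_mpa
  surr <- list(
    fit_surrogate(E, 5 - 0.5 * E + 0.01 * E^2),
    fit_surrogate(E, 6 - 0.6 * E + 0.012 * E^2),
    fit_surrogate(E, 4.5 - 0.45 * E + 0.011 * E^2)
  )
  targets <- c(2.1, 2.4, 1.9)
  got <- rootcalib:::minimize_combined(surr, targets, c(0.8, 15))$E
  # oracle: exhaustive 1e5-point scan of the summed squared cost
  grid <- seq(0.8, 15, length.out = 1e5)
  cost <- rep(0, length(grid))
  for (i in 1:3) {
    b <- surr[[i]]$beta
    cost <- cost + (b[1] + b[2] * grid + b[3] * grid^2 - targets[i])^2
  }
  expect_lt(abs(got - grid[which.min(cost)]), diff(grid[1:2]) * 1.5)
})

test_that("noise-free virtual truth is recovered within 1 percent", {
  geom <- default_root_geometry()
  hemo <- test_hemo()
  fwd <- reference_forward_model(geom, hemo)
  meas <- measurement_set(strain = fwd$run(6, "wall_strain"),
                          orifice_area = fwd$run(6, "orifice_area"))
  res <- calibrate_patient(meas, fwd, calibration_config(seed = 42))
  expect_lt(abs(res$E_optimal - 6) / 6, 0.01)
  expect_lt(abs(res$leaflet_E_optimal - 6) / 6, 0.01)
  # identified range brackets every per-region root
  expect_true(all(res$per_region_roots$E_root_mpa >=
                    res$E_range_identified[1] - 1e-9))
  expect_true(all(res$per_region_roots$E_root_mpa <=
                    res$E_range_identified[2] + 1e-9))
})

test_that("a zero-sensitivity forward model is flagged, not solved", {
  flatfwd <- forward_model(function(E, target) {
    if (target == "wall_strain") c(annulus = 2, sinus = 2, STJ = 2) else 100
  })
  meas <- measurement_set(strain = c(annulus = 2, sinus = 2, STJ = 2))
  res <- calibrate_patient(meas, flatfwd, calibration_config(seed = 1))
  expect_true("poor_fit" %in% res$flags)
  expect_true(is.na(res$E_optimal))
})

test_that("calibration is deterministic for fixed seed and inputs", {
  geom <- default_root_geometry()
  hemo <- test_hemo()
  fwd <- reference_forward_model(geom, hemo)
  meas <- measurement_set(strain = fwd$run(4.2, "wall_strain"))
  r1 <- calibrate_patient(meas, fwd, calibration_config(seed = 9))
  fwd2 <- reference_forward_model(geom, hemo)
  r2 <- calibrate_patient(meas, fwd2, calibration_config(seed = 9))
  expect_identical(serialize(r1[setdiff(names(r1), "surrogates")], NULL),
                   serialize(r2[setdiff(names(r2), "surrogates")], NULL))
  expect_equal(tidy(r1$surrogates$wall$annulus),
               tidy(r2$surrogates$wall$annulus))
})

test_that("verification reproduces noise-free targets and localises error", {
  geom <- default_root_geometry()
  hemo <- test_hemo()
  fwd <- reference_forward_model(geom, hemo)
  truth <- fwd$run(6, "wall_strain")
  meas <- measurement_set(strain = truth)
  res <- calibrate_patient(meas, fwd, calibration_config(seed = 2))
  v <- tidy(res)
  expect_true(all(v$rel_discrepancy_pct < 1e-4))
  # the optimum beats both range endpoints on the measured residuals
  resid <- function(E) sum((fwd$run(E, "wall_strain") - truth)^2)
  expect_lte(resid(res$E_optimal), resid(0.8))
  expect_lte(resid(res$E_optimal), resid(15))
  # perturbing one measured strain moves only that observable's discrepancy
  pert <- truth
  pert["sinus"] <- pert[["sinus"]] * 1.5
  v2 <- verify_calibration(res, fwd, measurement_set(strain = pert))
  expect_gt(v2$abs_discrepancy[v2$observable == "strain_sinus"], 0.1)
  expect_lt(max(v2$abs_discrepancy[v2$observable != "strain_sinus"]), 1e-4)
  # identical predicted/reference shapes give a perfect Jaccard entry
  arr <- array(FALSE, c(5, 5, 5)); arr[2:4, 2:4, 2:4] <- TRUE
  g <- occupancy_grid(arr)
  v3 <- verify_calibration(res, fwd, measurement_set(strain = truth),
                           shapes = list(predicted = g, reference = g))
  expect_equal(v3$predicted[v3$observable == "shape_jaccard_pct"], 100)
})

test_that("the deployment equilibrium matches its closed form and limits", {
  expect_equal(equilibrium_radius(79.89, 11.5, 79.89, 11), 11.25)
  expect_equal(equilibrium_radius(79.89, 11.5, 0, 11), 11.5)
  expect_equal(equilibrium_radius(79.89, 11.5, Inf, 11), 11)
  geom <- default_root_geometry()
  hemo <- test_hemo()
  fwd <- reference_forward_model(geom, hemo)
  meas <- measurement_set(strain = fwd$run(5, "wall_strain"))
  res <- calibrate_patient(meas, fwd, calibration_config(seed = 4))
  sens <- sensitivity_analysis(res, annulus_radius = 11)
  expect_equal(nrow(sens), 9)  # 3 levels x {min, optimal, max}
  # stiffer wall, smaller deployed diameter
  mid <- sens[sens$level == "mid", ]
  expect_true(all(diff(mid$diameter_mm[order(mid$E_mpa)]) <= 0))
  expect_true(all(sens$diameter_mm < 23))
  expect_true(all(sens$diameter_mm > 22))
  expect_error(sensitivity_analysis(res, annulus_radius = 12), "below")
})
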