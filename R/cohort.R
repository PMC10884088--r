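#' Virtual-cohort configuration
#'
#' Distribution parameters for the virtual-patient generator. Hemodynamic
#' means/SDs default to the study cohort summary (systolic pressure
#' 129.4 +/- 18.3 mmHg, diastolic 61.2 +/- 11.2 mmHg, heart rate
#' 70.6 +/- 10.9 bpm), sampled from normals truncated at +/- 3 SD with
#' physiological floors (diastolic >= 30 mmHg) and resampled until
#' systolic exceeds diastolic. The peak transvalvular gradient defaults to
#' 40 +/- 10 mmHg truncated to 15-80 mmHg, centred on the leaflet model's
#' anchor point. Ground-truth moduli are uniform over a sub-range of the
#' design range (default 1.5-13 MPa, the identifiable interior). The noisy
#' measurement model is CT-like: additive Gaussian diameter noise with SD
#' half the in-plane voxel (0.244 mm) and 3% multiplicative orifice-area
#' noise.
#'
#' @param p_sys,p_dias,hr,peak_gradient Length-2 `c(mean, sd)` in their
#'   clinical units.
#' @param E_wall_range,E_leaflet_range Uniform ground-truth modulus ranges,
#'   MPa.
#' @param calc_factor_range Uniform range for the calcification factor
#'   (>= 1).
#' @param annulus Length-2 `c(mean, sd)` diastolic annulus diameter, mm;
#'   sinus and STJ scale from it.
#' @param diameter_noise_sd_mm Additive diameter noise SD, mm.
#' @param area_noise_rel Multiplicative orifice-area noise SD.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(p_sys = c(129.4, 18.3), p_dias = c(61.2, 11.2),
                          hr = c(70.6, 10.9), peak_gradient = c(40, 10),
                          E_wall_range = c(1.5, 13),
                          E_leaflet_range = c(1.5, 13),
                          calc_factor_range = c(1, 2),
                          annulus = c(23, 1.5),
                          diameter_noise_sd_mm = 0.244,
                          area_noise_rel = 0.03) {
  if (p_dias[1] >= p_sys[1]) {
    abort("Mean diastolic pressure must be below mean systolic pressure.")
  }
  structure(as.list(environment()), class = "cohort_config")
}

# truncated-normal draw by inverse-CDF sampling
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  qnorm(runif(n, a, b), mean, sd)
}

#' Generate a seeded virtual patient
#'
#' Draws hemodynamics, a perturbed root geometry and ground-truth wall and
#' leaflet moduli from [cohort_config()] distributions, runs the reference
#' forward model at the truth to obtain the noise-free measurement set,
#' and overlays the CT-like noise model to obtain the noisy set. Fully
#' reproducible: the same seed yields an identical patient.
#'
#' @param seed Integer seed.
#' @param config A [cohort_config].
#' @return A list of class `virtual_patient`: `seed`, `E_wall`,
#'   `E_leaflet`, `calcification_factor`, `geometry`, `hemo`,
#'   `measurements_clean`, `measurements_noisy`, `forward`.
#' @export
#' @examples
#' vp <- generate_virtual_patient(seed = 7)
#' vp$E_wall
generate_virtual_patient <- function(seed, config = cohort_config()) {
  draws <- with_seed(seed, {
    ps <- NA; pd <- NA
    repeat {
      ps <- rtruncnorm1(1, config$p_sys[1], config$p_sys[2],
                        config$p_sys[1] - 3 * config$p_sys[2],
                        config$p_sys[1] + 3 * config$p_sys[2])
      pd <- rtruncnorm1(1, config$p_dias[1], config$p_dias[2],
                        max(30, config$p_dias[1] - 3 * config$p_dias[2]),
                        config$p_dias[1] + 3 * config$p_dias[2])
      if (ps > pd + 10) break
    }
    list(
      p_sys = ps, p_dias = pd,
      hr = rtruncnorm1(1, config$hr[1], config$hr[2],
                       max(30, config$hr[1] - 3 * config$hr[2]),
                       config$hr[1] + 3 * config$hr[2]),
      grad = rtruncnorm1(1, config$peak_gradient[1], config$peak_gradient[2],
                         15, 80),
      E_wall = runif(1, config$E_wall_range[1], config$E_wall_range[2]),
      E_leaflet = runif(1, config$E_leaflet_range[1],
                        config$E_leaflet_range[2]),
      kappa = runif(1, config$calc_factor_range[1],
                    config$calc_factor_range[2]),
      annulus = rtruncnorm1(1, config$annulus[1], config$annulus[2],
                            config$annulus[1] - 3 * config$annulus[2],
                            config$annulus[1] + 3 * config$annulus[2]),
      sinus_ratio = rtruncnorm1(1, 1.30, 0.05, 1.15, 1.45),
      stj_ratio = rtruncnorm1(1, 1.17, 0.04, 1.05, 1.29),
      fe_radius = rtruncnorm1(1, 4, 0.5, 2.5, 5.5),
      dia_noise = rnorm(6), area_noise = rnorm(1)
    )
  })
  geom <- default_root_geometry(
    annulus = draws$annulus,
    sinus = draws$annulus * draws$sinus_ratio,
    stj = draws$annulus * draws$stj_ratio,
    free_edge_radius = draws$fe_radius
  )
  hemo <- hemodynamic_record(draws$p_sys, draws$p_dias, draws$hr,
                             peak_gradient = draws$grad)
  fwd <- reference_forward_model(geom, hemo,
                                 calcification_factor = draws$kappa)
  wall <- wall_response(geom, draws$E_wall, 0.475, hemo)
  area <- fwd$run(draws$E_leaflet, "orifice_area")
  d_dias <- stats::setNames(wall$D_dias_mm, wall$region)
  d_sys <- stats::setNames(wall$D_sys_mm, wall$region)
  clean <- measurement_set(d_sys = d_sys, d_dias = d_dias,
                           orifice_area = area)
  noisy_dias <- d_dias + config$diameter_noise_sd_mm * draws$dia_noise[1:3]
  noisy_sys <- d_sys + config$diameter_noise_sd_mm * draws$dia_noise[4:6]
  noisy <- measurement_set(
    d_sys = noisy_sys, d_dias = noisy_dias,
    orifice_area = max(0, area * (1 + config$area_noise_rel *
                                    draws$area_noise))
  )
  structure(list(seed = seed, E_wall = draws$E_wall,
                 E_leaflet = draws$E_leaflet,
                 calcification_factor = draws$kappa,
                 geometry = geom, hemo = hemo,
                 measurements_clean = clean, measurements_noisy = noisy,
                 forward = fwd),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf(
    "<virtual_patient seed %d: E_wall %.2f MPa, E_leaflet %.2f MPa, %g/%g mmHg>\n",
    x$seed, x$E_wall, x$E_leaflet, x$hemo$p_sys, x$hemo$p_dias))
  invisible(x)
}

#' Generate a virtual cohort
#'
#' @param n Number of patients (>= 1).
#' @param seed Cohort seed; patient `i` uses a derived child seed.
#' @param config A [cohort_config].
#' @return List of [generate_virtual_patient()] results.
#' @export
generate_cohort <- function(n, seed, config = cohort_config()) {
  if (n < 1) abort("n must be >= 1.")
  purrr::map(seq_len(n),
             function(i) generate_virtual_patient(child_seed(seed, i),
                                                  config))
}

#' Cohort as a tibble
#'
#' One row per virtual patient: ground truths, hemodynamics and the noisy
#' observables.
#'
#' @param cohort List of `virtual_patient` objects.
#' @return A tibble.
#' @export
cohort_table <- function(cohort) {
  purrr::map_dfr(cohort, function(p) {
    tibble::tibble(
      seed = p$seed, E_wall = p$E_wall, E_leaflet = p$E_leaflet,
      calcification_factor = p$calcification_factor,
      p_sys = p$hemo$p_sys, p_dias = p$hemo$p_dias, hr = p$hemo$hr,
      peak_gradient = p$hemo$peak_gradient,
      annulus_mm = p$geometry$diameters[["annulus"]],
      strain_ann = p$measurements_noisy$strain[["annulus"]],
      strain_sinus = p$measurements_noisy$strain[["sinus"]],
      strain_stj = p$measurements_noisy$strain[["STJ"]],
      orifice_area = p$measurements_noisy$orifice_area
    )
  })
}

#' Load the printed study-cohort fixture
#'
#' Twenty patient records (demographics, cuff pressures, heart rate,
#' cardiac output, regional strains, orifice area, shape Jaccard index and
#' the optimised Young's modulus) shipped as printed; the printed Mean/SD
#' rows are kept separately (see [load_table1_summary()]). The file is
#' checksum-guarded against accidental edits.
#'
#' @return Tibble with 20 rows.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "rootcalib")
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (nrow(d) != 20) abort("Corrupted fixture: expected 20 records.")
  chk <- sum(as.matrix(d[vapply(d, is.numeric, logical(1))]))
  if (abs(chk - 91049) > 1e-6) {
    abort("Corrupted fixture: checksum mismatch.")
  }
  d
}

#' Load the printed cohort summary (mean/SD) rows
#'
#' @return Tibble with rows `mean` and `sd`.
#' @export
load_table1_summary <- function() {
  path <- system.file("extdata", "table1_summary.csv", package = "rootcalib")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Mean and sample SD of a cohort column
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' numeric cohort column; `rounded` additionally gives the one-decimal
#' presentation used in reports.
#'
#' @param records A data frame of cohort records (>= 2 rows).
#' @param column Column name.
#' @return One-row tibble: `column`, `n`, `mean`, `sd`, `mean_1dp`,
#'   `sd_1dp`.
#' @export
#' @examples
#' cohort_summary(load_table1_fixture(), "e_mpa")
cohort_summary <- function(records, column) {
  if (!column %in% names(records)) {
    abort(sprintf("Unknown column '%s'.", column))
  }
  x <- records[[column]]
  if (!is.numeric(x)) abort(sprintf("Column '%s' is not numeric.", column))
  if (length(x) < 2) abort("At least 2 records are required.")
  tibble::tibble(column = column, n = length(x), mean = mean(x),
                 sd = sd(x), mean_1dp = round(mean(x), 1),
                 sd_1dp = round(sd(x), 1))
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the p-value from the t transform on
#' n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
#' @examples
#' fx <- load_table1_fixture()
#' pearson_correlation(fx$e_mpa, fx$strain_ann)
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("At least 3 pairs are required.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in x or y.")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Parameter-recovery experiment
#'
#' The acceptance surface for the inverse method: generates a seeded
#' virtual cohort, perturbs the clean observables with multiplicative
#' Gaussian noise at each requested level (common standard-normal draws
#' scaled by the level, so error grows with noise by construction), runs
#' [calibrate_patient()] against each patient's own reference forward
#' model, and summarises the wall-modulus recovery per level. Calibration
#' failures are counted, not raised.
#'
#' @param n_patients Number of patients (>= 10).
#' @param seed Experiment seed.
#' @param noise_levels Relative noise SDs (e.g. `c(0, 0.02, 0.05)`).
#' @param config A [cohort_config].
#' @param calib_config A [calibration_config] template (its seed is
#'   re-derived per patient).
#' @return A list of class `recovery_experiment`: `summary` (tibble, one
#'   row per noise level: `noise_level`, `n`, `bias_rel_pct`,
#'   `median_abs_rel_err_pct`, `rmse_rel_pct`, `flag_rate`, `failures`)
#'   and `details` (per patient and level).
#' @export
recovery_experiment <- function(n_patients = 50, seed = 1,
                                noise_levels = c(0, 0.02, 0.05),
                                config = cohort_config(),
                                calib_config = calibration_config()) {
  if (n_patients < 10) abort("n_patients must be >= 10.")
  cohort <- generate_cohort(n_patients, seed, config)
  # common noise draws, scaled by the level: 3 strains + 1 area per patient
  zs <- with_seed(child_seed(seed, 999), {
    matrix(rnorm(4 * n_patients), nrow = n_patients)
  })
  details <- purrr::map_dfr(seq_along(noise_levels), function(li) {
    lev <- noise_levels[li]
    purrr::map_dfr(seq_len(n_patients), function(i) {
      p <- cohort[[i]]
      clean <- p$measurements_clean
      strain <- clean$strain * (1 + lev * zs[i, 1:3])
      area <- max(1e-6, clean$orifice_area * (1 + lev * zs[i, 4]))
      meas <- measurement_set(strain = strain, orifice_area = area)
      cc <- calib_config
      cc$seed <- child_seed(seed, 10000 + i)
      res <- tryCatch(calibrate_patient(meas, p$forward, cc),
                      error = function(e) NULL)
      if (is.null(res) || is.na(res$E_optimal)) {
        tibble::tibble(noise_level = lev, patient = i, E_true = p$E_wall,
                       E_hat = NA_real_, rel_err_pct = NA_real_,
                       flagged = TRUE, failed = TRUE)
      } else {
        tibble::tibble(noise_level = lev, patient = i, E_true = p$E_wall,
                       E_hat = res$E_optimal,
                       rel_err_pct = 100 * (res$E_optimal - p$E_wall) /
                         p$E_wall,
                       flagged = length(setdiff(res$flags,
                                                "multiple_roots")) > 0,
                       failed = FALSE)
      }
    })
  })
  summary <- details |>
    dplyr::group_by(.data$noise_level) |>
    dplyr::summarise(
      n = dplyr::n(),
      bias_rel_pct = mean(.data$rel_err_pct, na.rm = TRUE),
      median_abs_rel_err_pct = stats::median(abs(.data$rel_err_pct),
                                             na.rm = TRUE),
      rmse_rel_pct = sqrt(mean(.data$rel_err_pct^2, na.rm = TRUE)),
      flag_rate = mean(.data$flagged),
      failures = sum(.data$failed),
      .groups = "drop"
    )
  structure(list(summary = summary, details = details,
                 noise_levels = noise_levels, seed = seed),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("<recovery_experiment>\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn recovery_experiment Per-level summary tibble.
#' @param x A `recovery_experiment`.
#' @param ... Unused.
#' @export
tidy.recovery_experiment <- function(x, ...) x$summary
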