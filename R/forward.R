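#' Hemodynamic record
#'
#' Cuff pressures, heart rate and the peak transvalvular pressure gradient
#' (from Doppler echocardiography) that load the forward models. Pressures
#' in mmHg, heart rate in beats/min, optional cardiac output in ml/min.
#'
#' @param p_sys,p_dias Systolic and diastolic cuff pressure, mmHg
#'   (`p_sys > p_dias > 0`).
#' @param hr Heart rate, beats/min (> 0).
#' @param peak_gradient Peak transvalvular gradient, mmHg (>= 0).
#' @param co Optional cardiac output, ml/min.
#' @return An object of class `hemodynamic_record`.
#' @export
#' @examples
#' hemodynamic_record(162, 48, 92, peak_gradient = 40)
hemodynamic_record <- function(p_sys, p_dias, hr, peak_gradient = 0,
                               co = NA_real_) {
  stopifnot_scalar_num(p_sys, "p_sys", positive = TRUE)
  stopifnot_scalar_num(p_dias, "p_dias", positive = TRUE)
  stopifnot_scalar_num(hr, "hr", positive = TRUE)
  if (p_sys <= p_dias) abort("p_sys must exceed p_dias.")
  if (peak_gradient < 0) abort("peak_gradient must be >= 0.")
  structure(list(p_sys = p_sys, p_dias = p_dias, hr = hr,
                 peak_gradient = peak_gradient, co = co),
            class = "hemodynamic_record")
}

#' @export
print.hemodynamic_record <- function(x, ...) {
  cat(sprintf(
    "<hemodynamic_record: %g/%g mmHg, HR %g bpm, peak gradient %g mmHg>\n",
    x$p_sys, x$p_dias, x$hr, x$peak_gradient))
  invisible(x)
}

#' Reference wall forward model (Laplace closed form)
#'
#' Treats each root region as an independent thin-walled cylinder with
#' longitudinally constrained ends, loaded by the systolic-minus-diastolic
#' pressure increment (the reference configuration is end-diastole, the
#' segmentation phase). Per region with diastolic diameter `D` and wall
#' thickness `t`:
#' `d_sigma = dP * (D/2) / t` and `eps_theta = d_sigma (1 - nu^2) / E`,
#' reported as strain in percent together with the implied systolic
#' diameter `D (1 + eps_theta)`. Strains are strictly decreasing in `E`.
#'
#' @param geom A [root_geometry].
#' @param E Wall Young's modulus, MPa (> 0).
#' @param nu Poisson ratio (default 0.475).
#' @param hemo A [hemodynamic_record].
#' @return Tibble with columns `region`, `D_dias_mm`, `hoop_stress_mpa`,
#'   `strain_pct`, `D_sys_mm`.
#' @export
#' @examples
#' g <- default_root_geometry()
#' h <- hemodynamic_record(129, 61, 71)
#' wall_response(g, E = 5.6, hemo = h)
wall_response <- function(geom, E, nu = 0.475, hemo) {
  stopifnot_scalar_num(E, "E", positive = TRUE)
  if (hemo$p_sys < hemo$p_dias) abort("p_sys must be >= p_dias.")
  dp <- mmhg_to_mpa(hemo$p_sys - hemo$p_dias)
  tibble::tibble(region = names(geom$diameters),
                 D_dias_mm = as.numeric(geom$diameters)) |>
    dplyr::mutate(
      hoop_stress_mpa = dp * (.data$D_dias_mm / 2) / geom$wall_thickness,
      strain_pct = 100 * .data$hoop_stress_mpa * (1 - nu^2) / E,
      D_sys_mm = .data$D_dias_mm * (1 + .data$strain_pct / 100)
    )
}

#' Leaflet-opening constant for a reference geometry
#'
#' The simplified leaflet model opens by the fraction
#' `phi = min(1, c * dP * L^4 / (kappa * E * t^3 * L_ref))` where `L` is the
#' mean distance from the closed free edge to the annulus ring, `t` the
#' leaflet thickness, `kappa >= 1` a calcification stiffening factor and
#' `L_ref` a fixed reference length (the default geometry's `L`). The
#' default `c` is anchored so that `phi = 0.5` at `E = 5` MPa, a 40 mmHg
#' gradient and `kappa = 1` on the default geometry, centring the default
#' virtual cohort in the identifiable range.
#'
#' @param geom Geometry used as anchor (default [default_root_geometry()]).
#' @return The scalar constant `c` (dimensionless given mm/MPa units).
#' @export
leaflet_opening_constant <- function(geom = default_root_geometry()) {
  L <- free_edge_annulus_distance(geom)
  t <- geom$leaflet_thickness
  dp <- mmhg_to_mpa(40)
  0.5 * 1 * 5 * t^3 * leaflet_reference_length() / (dp * L^4)
}

# fixed reference length (mm): mean free-edge-to-annulus distance of the
# default geometry, evaluated analytically-stable via the same helper
leaflet_reference_length <- function() {
  free_edge_annulus_distance(default_root_geometry())
}

# mean distance from the free-edge points to the annulus ring (circle of
# radius D_ann/2 in the valve plane)
free_edge_annulus_distance <- function(geom) {
  pl <- geom$valve_plane
  b <- plane_basis(pl$normal)
  pts <- as.matrix(geom$free_edge_points[, c("x_mm", "y_mm", "z_mm")])
  rel <- sweep(pts, 2, pl$point)
  u <- rel %*% b$u
  v <- rel %*% b$v
  w <- rel %*% b$n
  r_ann <- geom$diameters[["annulus"]] / 2
  mean(sqrt((sqrt(u^2 + v^2) - r_ann)^2 + w^2))
}

#' Simplified leaflet-opening forward model
#'
#' Moves each closed free-edge point radially (in the valve plane, away
#' from the projected centroid) toward the maximal-orifice circle by the
#' opening fraction `phi` described in [leaflet_opening_constant()], then
#' measures the enclosed orifice area with [orifice_area()]. The area is
#' monotone non-increasing in both the leaflet modulus and the
#' calcification factor, and equals the closed-configuration area when the
#' driving gradient is zero.
#'
#' @param geom A [root_geometry].
#' @param E_leaflet Leaflet Young's modulus, MPa (> 0).
#' @param calcification_factor Stiffening multiplier `kappa >= 1`.
#' @param hemo A [hemodynamic_record]; the driving pressure is
#'   `peak_gradient`.
#' @param opening_constant The constant `c`; default anchored on the
#'   default geometry.
#' @return A list of class `leaflet_state`: `points` (tibble of displaced
#'   free-edge points), `orifice_area_mm2`, `opening_fraction`.
#' @export
leaflet_response <- function(geom, E_leaflet, calcification_factor = 1,
                             hemo,
                             opening_constant = leaflet_opening_constant()) {
  stopifnot_scalar_num(E_leaflet, "E_leaflet", positive = TRUE)
  if (calcification_factor < 1) abort("calcification_factor must be >= 1.")
  if (hemo$peak_gradient < 0) abort("peak_gradient must be >= 0.")
  pts <- as.matrix(geom$free_edge_points[, c("x_mm", "y_mm", "z_mm")])
  if (nrow(pts) < 3) abort("Need at least 3 free-edge points.")
  dp <- mmhg_to_mpa(hemo$peak_gradient)
  L <- free_edge_annulus_distance(geom)
  phi <- opening_constant * dp * L^4 /
    (calcification_factor * E_leaflet * geom$leaflet_thickness^3 *
       leaflet_reference_length())
  phi <- min(1, phi)

  pl <- geom$valve_plane
  b <- plane_basis(pl$normal)
  rel <- sweep(pts, 2, pl$point)
  u <- as.numeric(rel %*% b$u)
  v <- as.numeric(rel %*% b$v)
  w <- as.numeric(rel %*% b$n)
  cu <- mean(u); cv <- mean(v)
  ang <- atan2(v - cv, u - cu)
  # fully-open target: the maximal-orifice circle in the valve plane,
  # centred on the projected free-edge centroid, at in-plane height 0
  tu <- cu + geom$max_orifice_radius * cos(ang)
  tv <- cv + geom$max_orifice_radius * sin(ang)
  nu_ <- u + phi * (tu - u)
  nv <- v + phi * (tv - v)
  nw <- w * (1 - phi)
  xyz <- sweep(outer(nu_, b$u) + outer(nv, b$v) + outer(nw, b$n),
               2, pl$point, `+`)
  out_pts <- tibble::tibble(x_mm = xyz[, 1], y_mm = xyz[, 2],
                            z_mm = xyz[, 3])
  area <- orifice_area(out_pts, pl)
  structure(list(points = out_pts, orifice_area_mm2 = area,
                 opening_fraction = phi),
            class = "leaflet_state")
}

#' @export
print.leaflet_state <- function(x, ...) {
  cat(sprintf("<leaflet_state: orifice area %.1f mm^2, opening %.2f>\n",
              x$orifice_area_mm2, x$opening_fraction))
  invisible(x)
}

#' Scaled physiological pressure waveform
#'
#' A fixed normalized beat shape (a systolic bump over the first 30% of
#' the period followed by a small decaying dicrotic wave) scaled affinely
#' so the sampled maximum equals `p_sys` and the minimum `p_dias`; the
#' period is `60 / hr` seconds. The shape is cosmetic: the inverse loop
#' consumes only the peak values.
#'
#' @param hemo A [hemodynamic_record].
#' @param n_samples Number of samples over one beat (>= 8).
#' @return Tibble with columns `t_s`, `p_mmhg`.
#' @export
pressure_waveform <- function(hemo, n_samples = 100) {
  if (n_samples < 8) abort("n_samples must be >= 8.")
  if (hemo$p_sys <= hemo$p_dias) abort("p_sys must exceed p_dias.")
  period <- 60 / hemo$hr
  tau <- seq(0, 1, length.out = n_samples)
  s <- ifelse(tau <= 0.3,
              sin(pi * tau / 0.3),
              0.15 * sin(pi * (tau - 0.3) / 0.7) * exp(-4 * (tau - 0.3)))
  s <- (s - min(s)) / (max(s) - min(s))
  tibble::tibble(t_s = tau * period,
                 p_mmhg = hemo$p_dias + (hemo$p_sys - hemo$p_dias) * s)
}

# --- forward-model contract -----------------------------------------------

#' Forward-model contract
#'
#' The inverse engine talks to any forward model through this contract: a
#' deterministic function `run(E, target)` returning, for
#' `target = "wall_strain"`, a named numeric vector of regional strains in
#' percent, and for `target = "orifice_area"`, the orifice area in mm^2,
#' plus a declared modulus validity range. Evaluations are memoized per
#' `(E, target)`.
#'
#' @param run Function of `(E, target)`.
#' @param E_range Length-2 numeric, declared validity range in MPa.
#' @param label Free-text model description.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(run, E_range = c(0.8, 15), label = "forward model") {
  if (!is.function(run)) abort("`run` must be a function(E, target).")
  if (length(E_range) != 2 || E_range[1] >= E_range[2]) {
    abort("`E_range` must be an increasing pair.")
  }
  cache <- new.env(parent = emptyenv())
  memo_run <- function(E, target) {
    key <- paste(target, format(E, digits = 15))
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- run(E, target)
    if (any(!is.finite(unlist(val)))) {
      abort("Forward model returned non-finite output.")
    }
    cache[[key]] <- val
    val
  }
  structure(list(run = memo_run, E_range = as.numeric(E_range),
                 label = label),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model: %s, E in [%g, %g] MPa>\n",
              x$label, x$E_range[1], x$E_range[2]))
  invisible(x)
}

#' Reference (desk-scale) forward model
#'
#' Bundles [wall_response()] and [leaflet_response()] for a fixed geometry
#' and hemodynamic record into a [forward_model] the calibration engine can
#' drive. `run(E, "wall_strain")` returns the named regional strain vector
#' (percent); `run(E, "orifice_area")` the orifice area (mm^2).
#'
#' @param geom A [root_geometry].
#' @param hemo A [hemodynamic_record].
#' @param nu Wall Poisson ratio.
#' @param calcification_factor Leaflet stiffening factor `kappa >= 1`.
#' @param opening_constant Leaflet model constant.
#' @param E_range Declared validity range, MPa.
#' @return A [forward_model].
#' @export
reference_forward_model <- function(geom, hemo, nu = 0.475,
                                    calcification_factor = 1,
                                    opening_constant =
                                      leaflet_opening_constant(),
                                    E_range = c(0.8, 15)) {
  force(geom); force(hemo); force(nu)
  force(calcification_factor); force(opening_constant)
  run <- function(E, target) {
    if (target == "wall_strain") {
      w <- wall_response(geom, E, nu, hemo)
      stats::setNames(w$strain_pct, w$region)
    } else if (target == "orifice_area") {
      leaflet_response(geom, E, calcification_factor, hemo,
                       opening_constant)$orifice_area_mm2
    } else {
      abort(sprintf("Unknown target '%s'.", target))
    }
  }
  forward_model(run, E_range = E_range,
                label = "Laplace wall + radial leaflet opening")
}
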