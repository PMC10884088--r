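#' Diameter strain between cardiac phases
#'
#' The relative systolic expansion `100 * (D_sys - D_dias) / D_dias` in
#' percent. Negative values (systolic diameter below diastolic) are
#' physiologically unexpected but returned with their sign so callers can
#' flag them.
#'
#' @param d_sys,d_dias Systolic and diastolic diameters, mm (vectorised;
#'   `d_dias > 0`).
#' @return Strain in percent.
#' @export
#' @examples
#' diameter_strain(26, 25) # 4
diameter_strain <- function(d_sys, d_dias) {
  if (any(d_dias <= 0)) abort("d_dias must be > 0.")
  100 * (d_sys - d_dias) / d_dias
}

#' Relative error in percent
#'
#' `100 * |predicted - reference| / |reference|`.
#'
#' @param predicted,reference Numeric (vectorised; `reference != 0`).
#' @return Relative error, percent.
#' @export
relative_error <- function(predicted, reference) {
  if (any(reference == 0)) abort("reference must be nonzero.")
  100 * abs(predicted - reference) / abs(reference)
}

#' Orifice area from leaflet free-edge points
#'
#' Projects the free-edge points onto the valve plane, orders them by polar
#' angle about their projected centroid (points sharing an angle within
#' 1e-9 rad are averaged), interpolates a closed periodic cubic spline
#' through them, samples the spline densely and returns the shoelace
#' polygon area. Invariant to rigid motion of points and plane; scales
#' quadratically under isotropic scaling.
#'
#' @param points Data frame/tibble with columns `x_mm`, `y_mm`, `z_mm` (or
#'   an n x 3 matrix), >= 3 non-collinear points.
#' @param valve_plane List with `point` and unit `normal`.
#' @param n_samples Spline sampling density (>= 512 recommended).
#' @return Area in mm^2.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 25)[-25]
#' pts <- tibble::tibble(x_mm = 6 * cos(th), y_mm = 6 * sin(th), z_mm = 0)
#' orifice_area(pts) # ~ pi * 36
orifice_area <- function(points,
                         valve_plane = list(point = c(0, 0, 0),
                                            normal = c(0, 0, 1)),
                         n_samples = 512) {
  pts <- if (is.matrix(points)) points else
    as.matrix(as.data.frame(points)[, c("x_mm", "y_mm", "z_mm")])
  if (nrow(pts) < 3) abort("At least 3 points are required.")
  uv <- project_to_plane(pts, valve_plane)
  ctr <- colMeans(uv)
  du <- uv[, 1] - ctr[1]
  dv <- uv[, 2] - ctr[2]
  if (max(abs(du * dv[c(2:length(dv), 1)] -
                dv * du[c(2:length(du), 1)])) < 1e-12) {
    abort("Points are collinear; no enclosed area.")
  }
  ang <- atan2(dv, du)
  o <- order(ang)
  ang <- ang[o]; du <- du[o]; dv <- dv[o]
  # average points that share a polar angle
  grp <- cumsum(c(TRUE, diff(ang) > 1e-9))
  du <- tapply(du, grp, mean)
  dv <- tapply(dv, grp, mean)
  ang <- tapply(ang, grp, mean)
  m <- length(du)
  if (m < 3) abort("Fewer than 3 distinct angular positions.")
  # periodic parameterisation by cumulative chord length
  dx <- diff(c(du, du[1]))
  dy <- diff(c(dv, dv[1]))
  chord <- sqrt(dx^2 + dy^2)
  t <- c(0, cumsum(chord))
  tt <- seq(0, t[m + 1], length.out = n_samples + 1)[-(n_samples + 1)]
  sx <- spline(t, c(du, du[1]), method = "periodic", xout = tt)$y
  sy <- spline(t, c(dv, dv[1]), method = "periodic", xout = tt)$y
  # gross self-intersection guard: sampled angle must wind monotonically
  sang <- atan2(sy, sx)
  dw <- diff(c(sang, sang[1]))
  dw <- (dw + pi) %% (2 * pi) - pi
  if (abs(sum(dw)) < 1.5 * pi) {
    abort("Interpolated spline self-intersects (winding != 1).")
  }
  abs(sum(sx * c(sy[-1], sy[1]) - c(sx[-1], sx[1]) * sy)) / 2
}

#' Stent-frame outer diameters at three levels
#'
#' Slices a band of the point cloud at each requested level along the
#' device axis (levels at fixed fractions of the axial extent, 1 mm band),
#' projects the band to the cross-section plane, takes the convex hull and
#' measures chords through the hull centroid over a fine fan of directions.
#' `d_max` / `d_min` are the longest and shortest such chords.
#'
#' @param points Data frame/matrix of 3-D points (columns `x_mm`, `y_mm`,
#'   `z_mm` or n x 3), >= 50 points.
#' @param axis List with `point` and `direction` (need not be unit).
#' @param levels Character subset of `c("inflow", "mid", "outflow")`.
#' @param level_fractions Axial positions of the levels as fractions of the
#'   extent.
#' @param band_mm Band thickness in mm (default 1).
#' @param n_directions Directions in the chord fan.
#' @return Tibble with columns `level`, `d_max_mm`, `d_min_mm`, `n_points`.
#' @export
device_diameters <- function(points,
                             axis = list(point = c(0, 0, 0),
                                         direction = c(0, 0, 1)),
                             levels = c("inflow", "mid", "outflow"),
                             level_fractions = c(inflow = 0.1, mid = 0.5,
                                                 outflow = 0.9),
                             band_mm = 1, n_directions = 360) {
  pts <- if (is.matrix(points)) points else
    as.matrix(as.data.frame(points)[, c("x_mm", "y_mm", "z_mm")])
  if (nrow(pts) < 50) abort("At least 50 stent points are required.")
  levels <- match.arg(levels, c("inflow", "mid", "outflow"),
                      several.ok = TRUE)
  dirn <- axis$direction / sqrt(sum(axis$direction^2))
  b <- plane_basis(dirn)
  rel <- sweep(pts, 2, as.numeric(axis$point))
  z <- as.numeric(rel %*% dirn)
  u <- as.numeric(rel %*% b$u)
  v <- as.numeric(rel %*% b$v)
  zr <- range(z)
  purrr::map_dfr(levels, function(lv) {
    z0 <- zr[1] + level_fractions[[lv]] * diff(zr)
    sel <- abs(z - z0) <= band_mm / 2
    if (sum(sel) < 3) {
      abort(sprintf("Empty band at level '%s' (z = %.2f mm).", lv, z0))
    }
    ch <- chord_extremes(u[sel], v[sel], n_directions)
    tibble::tibble(level = lv, d_max_mm = ch[1], d_min_mm = ch[2],
                   n_points = sum(sel))
  })
}

# max/min chord through the convex-hull centroid of 2-D points
chord_extremes <- function(u, v, n_directions = 360) {
  h <- grDevices::chull(u, v)
  hu <- u[h]; hv <- v[h]
  cx <- mean(hu); cy <- mean(hv)
  m <- length(hu)
  j <- c(2:m, 1)
  # hull edges as segments (hu,hv) -> (hu[j],hv[j])
  ex <- hu[j] - hu; ey <- hv[j] - hv
  ray_dist <- function(dx, dy) {
    # centroid + s*(dx,dy) crossing edge k at parameter r in [0,1]
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-12
    sx <- hu - cx; sy <- hv - cy
    s <- (sx * ey - sy * ex) / den
    r <- (sx * dy - sy * dx) / den
    s[!ok | r < -1e-9 | r > 1 + 1e-9 | s <= 0] <- NA
    min(s, na.rm = TRUE)
  }
  th <- seq(0, pi, length.out = n_directions + 1)[-(n_directions + 1)]
  chords <- vapply(th, function(a) {
    ray_dist(cos(a), sin(a)) + ray_dist(-cos(a), -sin(a))
  }, numeric(1))
  c(max(chords), min(chords))
}

#' Image-derived measurement set for one patient
#'
#' Bundles the calibration observables: per-region diastolic/systolic
#' diameters (mm) and/or regional strains (%), and the peak-systolic
#' orifice area (mm^2). When both diameters and strains are supplied they
#' must be consistent (strain = 100 (D_sys - D_dias)/D_dias within 1e-9);
#' when only diameters are supplied the strains are derived. Negative
#' strains are kept but flagged in `nonphysiological`.
#'
#' @param d_sys,d_dias Optional named numeric (regions `annulus`, `sinus`,
#'   `STJ`), mm.
#' @param strain Optional named numeric of regional strains, percent.
#' @param orifice_area Optional orifice area, mm^2 (>= 0).
#' @param shape_dias,shape_sys Optional [occupancy_grid] masks for the two
#'   phases.
#' @param stent_points Optional stent point cloud (tibble `x_mm`, `y_mm`,
#'   `z_mm`).
#' @return An object of class `measurement_set`.
#' @export
#' @examples
#' measurement_set(strain = c(annulus = 3.4, sinus = 1.4, STJ = 4.8),
#'                 orifice_area = 140.2)
measurement_set <- function(d_sys = NULL, d_dias = NULL, strain = NULL,
                            orifice_area = NULL,
                            shape_dias = NULL, shape_sys = NULL,
                            stent_points = NULL) {
  if (!is.null(d_sys) && !is.null(d_dias)) {
    regions <- intersect(names(d_sys), names(d_dias))
    derived <- diameter_strain(unlist(d_sys)[regions],
                               unlist(d_dias)[regions])
    if (!is.null(strain)) {
      common <- intersect(names(strain), regions)
      if (length(common) &&
          max(abs(unlist(strain)[common] - derived[common])) > 1e-9) {
        abort("Supplied strains are inconsistent with the diameters.")
      }
    } else {
      strain <- derived
    }
  }
  if (!is.null(orifice_area) && orifice_area < 0) {
    abort("orifice_area must be >= 0.")
  }
  if (is.null(strain) && is.null(orifice_area)) {
    abort("At least one observable (strain or orifice area) is required.")
  }
  structure(list(
    d_sys = d_sys, d_dias = d_dias, strain = strain,
    orifice_area = orifice_area,
    shape_dias = shape_dias, shape_sys = shape_sys,
    stent_points = stent_points,
    nonphysiological = names(strain)[!is.na(strain) & strain < 0]
  ), class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set>\n")
  if (!is.null(x$strain)) {
    cat("  strain (%):",
        paste(sprintf("%s %.2f", names(x$strain), x$strain),
              collapse = ", "), "\n")
  }
  if (!is.null(x$orifice_area)) {
    cat(sprintf("  orifice area: %.1f mm^2\n", x$orifice_area))
  }
  if (length(x$nonphysiological)) {
    cat("  non-physiological strain in:",
        paste(x$nonphysiological, collapse = ", "), "\n")
  }
  invisible(x)
}
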